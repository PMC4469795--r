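# core ratio-difference decomposition from the five reduced-form /
# first-stage slopes; shared by the point estimator, the bootstrap and
# mediation_from_coefficients()
decompose_from_slopes <- function(b_y_gx, b_x_gx, b_z_gx, b_y_gz, b_z_gz) {
  total <- b_y_gx / b_x_gx
  x_to_z <- b_z_gx / b_x_gx
  z_to_y <- b_y_gz / b_z_gz
  indirect <- x_to_z * z_to_y
  c(total = total, direct = total - indirect, indirect = indirect,
    x_to_z = x_to_z, z_to_y = z_to_y)
}

eq_paths <- c("total", "direct", "indirect")

# whole pipeline on one dataset: optional covariate residualization, five
# simple regressions, weak-instrument guards on the two first stages
ratio_difference_statistic <- function(dataset, adjust = NULL) {
  if (length(adjust)) dataset <- residualize(dataset, adjust)
  gx <- dataset$g_x; gz <- dataset$g_z
  den_x <- tryCatch(ols_slope(dataset$x, gx), error = function(e) NULL)
  if (is.null(den_x) || !is.finite(den_x$t) || abs(den_x$t) < 1e-6) {
    stop("weak instrument on the exposure path (g_x -> x)", call. = FALSE)
  }
  den_z <- tryCatch(ols_slope(dataset$z, gz), error = function(e) NULL)
  if (is.null(den_z) || !is.finite(den_z$t) || abs(den_z$t) < 1e-6) {
    stop("weak instrument on the mediator path (g_z -> z)", call. = FALSE)
  }
  decompose_from_slopes(ols_slope(dataset$y, gx)$slope, den_x$slope,
                        ols_slope(dataset$z, gx)$slope,
                        ols_slope(dataset$y, gz)$slope, den_z$slope)
}

#' Ratio-difference mediation decomposition
#'
#' Regression-based estimation of total, direct and indirect effects with
#' two instruments. The total effect of the exposure on the outcome and
#' the constituent effects (exposure on mediator, mediator on outcome)
#' are each estimated by the ratio method with their own instrument; the
#' indirect effect is the product of the two constituent effects and the
#' direct effect is total minus indirect, so the decomposition identity
#' `total = direct + indirect` holds exactly by construction.
#'
#' Standard errors are obtained by nonparametric bootstrap of
#' individuals, re-running the whole pipeline (including any covariate
#' residualization) on each resample.
#'
#' @param dataset an [iv_dataset()].
#' @param bootstrap a [bootstrap_settings()], or `NULL` to skip standard
#'   errors (point estimates only).
#' @param adjust optional character vector of covariate names; the named
#'   columns are residualized out of x, z and y inside the pipeline.
#' @param level confidence level.
#' @return a [mediation_result()] with method `"regression_mediation"`;
#'   `$info` carries the constituent path estimates (`x_to_z`, `z_to_y`)
#'   and bootstrap metadata.
#' @export
mediation_ratio_difference <- function(dataset,
                                       bootstrap = bootstrap_settings(),
                                       adjust = NULL, level = 0.95) {
  theta <- ratio_difference_statistic(dataset, adjust)
  se <- setNames(rep(NA_real_, length(theta)), names(theta))
  info <- list(x_to_z = theta[["x_to_z"]], z_to_y = theta[["z_to_y"]],
               adjust = adjust)
  if (!is.null(bootstrap)) {
    bs <- bootstrap_statistic(function(d) ratio_difference_statistic(d, adjust),
                              dataset, bootstrap, level = level)
    se <- bs$se
    info$bootstrap <- list(n_resamples = bs$n_resamples,
                           n_failed = bs$n_failed,
                           seed = bootstrap$seed,
                           ci_type = bs$ci_type)
    info$bootstrap_result <- bs
  }
  ests <- lapply(eq_paths, function(nm) {
    causal_estimate(theta[[nm]], se[[nm]],
                    method = "regression_mediation", level = level)
  })
  names(ests) <- eq_paths
  mediation_result(ests$total, ests$direct, ests$indirect,
                   method = "regression_mediation", info = info)
}

#' Mediation decomposition from summary regression coefficients
#'
#' Applies the ratio-difference decomposition arithmetic directly to five
#' reported regression coefficients, e.g. from a published table of
#' allele-score regressions: the coefficients of the outcome, exposure
#' and mediator on the exposure's score, and of the outcome and mediator
#' on the mediator's score. When the scores are calibrated so that the
#' instrumented-variable coefficients equal 1 (see
#' [weighted_allele_score()]), the remaining coefficients are themselves
#' the causal effect estimates.
#'
#' @param b_y_gx,b_x_gx,b_z_gx coefficients of outcome, exposure and
#'   mediator on the exposure's instrument/score.
#' @param b_y_gz,b_z_gz coefficients of outcome and mediator on the
#'   mediator's instrument/score.
#' @return a [mediation_result()] with `NA` standard errors (summary
#'   coefficients carry no resampling information).
#' @examples
#' # allele-score coefficients: total 0.05, x->z 0.08, z->y -0.01
#' mediation_from_coefficients(0.05, 1.00, 0.08, -0.01, 1.00)
#' @export
mediation_from_coefficients <- function(b_y_gx, b_x_gx, b_z_gx,
                                        b_y_gz, b_z_gz) {
  if (b_x_gx == 0 || b_z_gz == 0) {
    stop("instrumented-variable coefficients must be nonzero", call. = FALSE)
  }
  theta <- decompose_from_slopes(b_y_gx, b_x_gx, b_z_gx, b_y_gz, b_z_gz)
  ests <- lapply(eq_paths, function(nm) {
    causal_estimate(theta[[nm]], NA_real_, method = "regression_mediation")
  })
  names(ests) <- eq_paths
  mediation_result(ests$total, ests$direct, ests$indirect,
                   method = "regression_mediation",
                   info = list(x_to_z = theta[["x_to_z"]],
                               z_to_y = theta[["z_to_y"]]))
}

# three sequential fitted-value regressions
msls_statistic <- function(dataset, adjust = NULL) {
  if (length(adjust)) dataset <- residualize(dataset, adjust)
  fs <- ols_slope(dataset$x, dataset$g_x)
  if (!is.finite(fs$t) || abs(fs$t) < 1e-6) {
    stop("weak instrument on the exposure path (g_x -> x)", call. = FALSE)
  }
  xhat <- mean(dataset$x) + fs$slope * (dataset$g_x - mean(dataset$g_x))
  s2 <- stats::lm.fit(cbind(1, dataset$g_z, xhat), dataset$z)
  zhat <- s2$fitted.values
  if (anyNA(s2$coefficients) || abs(cor(xhat, zhat)) > 0.999) {
    stop("fitted exposure and mediator are collinear; ",
         "instruments do not separate exposure and mediator", call. = FALSE)
  }
  b_xz <- s2$coefficients[3]
  s3 <- stats::lm.fit(cbind(1, xhat, zhat), dataset$y)
  direct <- s3$coefficients[2]
  indirect <- unname(b_xz * s3$coefficients[3])
  c(total = unname(direct + indirect), direct = unname(direct),
    indirect = indirect)
}

#' Multiple-stage least squares mediation estimator
#'
#' Sequential fitted-value regressions: (1) fitted exposure from its
#' instrument; (2) fitted mediator from its instrument and the fitted
#' exposure; (3) outcome on the fitted exposure and fitted mediator. The
#' stage-3 coefficient on the fitted exposure is the direct effect; the
#' indirect effect is the stage-2 coefficient of the fitted exposure
#' times the stage-3 coefficient of the fitted mediator; the total effect
#' is their sum.
#'
#' Naive stage-3 regression standard errors ignore that the regressors
#' are themselves estimated, so standard errors come from a
#' whole-pipeline bootstrap only.
#'
#' @inheritParams mediation_ratio_difference
#' @return a [mediation_result()] with method `"msls"`.
#' @export
multi_stage_least_squares <- function(dataset,
                                      bootstrap = bootstrap_settings(),
                                      adjust = NULL, level = 0.95) {
  theta <- msls_statistic(dataset, adjust)
  se <- setNames(rep(NA_real_, length(theta)), names(theta))
  info <- list(adjust = adjust)
  if (!is.null(bootstrap)) {
    bs <- bootstrap_statistic(function(d) msls_statistic(d, adjust),
                              dataset, bootstrap, level = level)
    se <- bs$se
    info$bootstrap <- list(n_resamples = bs$n_resamples,
                           n_failed = bs$n_failed,
                           seed = bootstrap$seed,
                           ci_type = bs$ci_type)
    info$bootstrap_result <- bs
  }
  ests <- lapply(eq_paths, function(nm) {
    causal_estimate(theta[[nm]], se[[nm]], method = "msls", level = level)
  })
  names(ests) <- eq_paths
  mediation_result(ests$total, ests$direct, ests$indirect,
                   method = "msls", info = info)
}
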