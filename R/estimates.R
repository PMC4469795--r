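#' Construct a causal effect estimate
#'
#' Container for a single causal-path estimate: point estimate, standard
#' error, normal-approximation (Wald) confidence interval and two-sided
#' p-value.
#'
#' @param estimate effect per unit change of the predictor.
#' @param se standard error (may be `NA` when no SE was requested).
#' @param method estimator tag, one of `"ratio"`, `"tsls"`,
#'   `"regression_mediation"`, `"msls"`, `"sem"`.
#' @param level confidence level, default 0.95.
#' @return an object of class `causal_estimate`.
#' @export
causal_estimate <- function(estimate, se = NA_real_, method = "ratio",
                            level = 0.95) {
  stopifnot(level > 0, level < 1)
  z <- qnorm(1 - (1 - level) / 2)
  se <- as.numeric(se)
  if (!is.na(se) && se < 0) stop("se must be nonnegative", call. = FALSE)
  p <- if (is.na(se) || se == 0) NA_real_ else 2 * pnorm(-abs(estimate / se))
  structure(list(estimate = as.numeric(estimate), se = se,
                 ci_low = estimate - z * se, ci_high = estimate + z * se,
                 level = level, method = method, p_value = p),
            class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("<causal_estimate:%s> %s (SE %s), %d%% CI [%s, %s], p = %s\n",
              x$method, format(x$estimate, digits = digits),
              format(x$se, digits = digits), round(100 * x$level),
              format(x$ci_low, digits = digits),
              format(x$ci_high, digits = digits),
              format(x$p_value, digits = 2)))
  invisible(x)
}

#' Assemble a mediation decomposition result
#'
#' @param total,direct,indirect [causal_estimate()] objects for the three
#'   estimands.
#' @param method estimator family label.
#' @param info optional named list of estimator metadata (bootstrap
#'   settings, constituent path estimates, ...).
#' @return an object of class `mediation_result`.
#' @export
mediation_result <- function(total, direct, indirect, method,
                             info = list()) {
  structure(list(total = total, direct = direct, indirect = indirect,
                 method = method, info = info),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, digits = 3, ...) {
  cat("Mediation decomposition (", x$method, ")\n", sep = "")
  fmt <- function(ce) {
    sprintf("%8s (SE %s)  p = %s", format(ce$estimate, digits = digits),
            format(ce$se, digits = digits), format(ce$p_value, digits = 2))
  }
  cat("  total:    ", fmt(x$total), "\n")
  cat("  direct:   ", fmt(x$direct), "\n")
  cat("  indirect: ", fmt(x$indirect), "\n")
  invisible(x)
}
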