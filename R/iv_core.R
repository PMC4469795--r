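# closed-form simple regression with intercept (fast path used everywhere;
# cross-checked against stats::lm in the unit tests)
ols_slope <- function(y, g) {
  n <- length(g)
  gm <- mean(g); ym <- mean(y)
  gc <- g - gm
  sxx <- sum(gc * gc)
  if (sxx <= 0) stop("regressor has zero variance", call. = FALSE)
  sxy <- sum(gc * y)
  b <- sxy / sxx
  r <- y - ym - b * gc
  s2 <- sum(r * r) / (n - 2)
  se <- sqrt(s2 / sxx)
  tt <- b / se
  list(slope = b, se = se, t = tt, df = n - 2L,
       p = 2 * pt(-abs(tt), n - 2L),
       r_squared = b * sxy / sum((y - ym)^2))
}

check_first_stage <- function(fs, label, warn_weak = TRUE) {
  if (!is.finite(fs$t) || abs(fs$t) < 1e-6) {
    stop("weak instrument: first-stage slope for ", label,
         " is indistinguishable from zero", call. = FALSE)
  }
  if (warn_weak && fs$t^2 < 10) {
    warning("weak instrument for ", label, ": first-stage F = ",
            format(fs$t^2, digits = 3), " < 10", call. = FALSE)
  }
  invisible(fs)
}

#' Ratio (Wald) instrumental-variable estimate
#'
#' Estimates the causal effect of an exposure on an outcome with a single
#' instrument as the ratio of two least-squares slopes: outcome on
#' instrument divided by exposure on instrument.
#'
#' The default standard error is the first-order delta approximation
#' `se(numerator) / |denominator|`, which ignores first-stage uncertainty
#' and is standard with strong instruments; `se_type = "delta"` adds the
#' second-order term for the estimated denominator (treating the two
#' slopes as independent).
#'
#' @param outcome,exposure,instrument numeric vectors of equal length.
#' @param se_type `"first_order"` (default) or `"delta"`.
#' @param level confidence level.
#' @param warn_weak warn when the first-stage F statistic is below 10.
#' @return a [causal_estimate()] with method `"ratio"`. The reduced-form
#'   and first-stage slope fits are attached as attribute `components`.
#' @examples
#' g <- rbinom(500, 2, 0.3); u <- rnorm(500)
#' x <- 0.5 * g + u + rnorm(500)
#' y <- 1.5 * x + u + rnorm(500)
#' ratio_estimate(y, x, g)
#' @export
ratio_estimate <- function(outcome, exposure, instrument,
                           se_type = c("first_order", "delta"),
                           level = 0.95, warn_weak = TRUE) {
  se_type <- match.arg(se_type)
  num <- ols_slope(outcome, instrument)
  den <- check_first_stage(ols_slope(exposure, instrument),
                           "exposure", warn_weak)
  est <- num$slope / den$slope
  se <- if (se_type == "first_order") {
    num$se / abs(den$slope)
  } else {
    sqrt(num$se^2 / den$slope^2 +
           num$slope^2 * den$se^2 / den$slope^4)
  }
  out <- causal_estimate(est, se, method = "ratio", level = level)
  attr(out, "components") <- list(numerator = num, denominator = den)
  out
}

#' Two-stage least squares
#'
#' Regresses each exposure on all instruments (plus covariates) to obtain
#' fitted values, then regresses the outcome on the fitted exposures
#' (plus covariates). Standard errors use the 2SLS convention: residuals
#' are computed from the observed, not fitted, exposures.
#'
#' @param outcome numeric vector.
#' @param exposures numeric vector or matrix (one column per instrumented
#'   exposure).
#' @param instruments numeric vector or matrix; at least as many
#'   instruments as exposures.
#' @param covariates optional data.frame/matrix entering both stages.
#' @param level confidence level.
#' @param robust use a heteroskedasticity-robust (sandwich) covariance.
#' @param warn_weak warn when a first-stage partial F is below 10.
#' @return a [causal_estimate()] (method `"tsls"`) for a single exposure,
#'   or a named list of them for several.
#' @export
two_stage_least_squares <- function(outcome, exposures, instruments,
                                    covariates = NULL, level = 0.95,
                                    robust = FALSE, warn_weak = TRUE) {
  X <- as.matrix(exposures)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  Zm <- as.matrix(instruments)
  if (ncol(Zm) < ncol(X)) {
    stop("under-identified: ", ncol(Zm), " instrument(s) for ",
         ncol(X), " exposure(s)", call. = FALSE)
  }
  n <- length(outcome)
  C <- NULL
  if (!is.null(covariates)) {
    C <- model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
  }
  W <- cbind(1, Zm, C)
  qw <- qr(W)
  if (qw$rank < ncol(W)) {
    stop("collinear instruments/covariates in the first stage", call. = FALSE)
  }
  Xhat <- qr.fitted(qw, X)
  if (warn_weak) {
    for (j in seq_len(ncol(X))) {
      fsF <- first_stage_partial_f(X[, j], Zm, C)
      if (fsF < 10) {
        warning("weak instrument(s) for exposure '", colnames(X)[j],
                "': first-stage F = ", format(fsF, digits = 3),
                call. = FALSE)
      }
    }
  }
  D <- cbind(`(Intercept)` = 1, Xhat, C)
  qd <- qr(D)
  if (qd$rank < ncol(D)) {
    stop("second-stage design is collinear", call. = FALSE)
  }
  beta <- qr.coef(qd, outcome)
  # residuals from observed exposures
  Dobs <- cbind(1, X, C)
  r <- outcome - drop(Dobs %*% beta)
  DtDinv <- chol2inv(qr.R(qd))
  if (robust) {
    meat <- crossprod(D * r)
    V <- DtDinv %*% meat %*% DtDinv
  } else {
    s2 <- sum(r^2) / (n - ncol(D))
    V <- s2 * DtDinv
  }
  idx <- 1 + seq_len(ncol(X))
  ests <- lapply(seq_along(idx), function(j) {
    causal_estimate(beta[idx[j]], sqrt(V[idx[j], idx[j]]),
                    method = "tsls", level = level)
  })
  names(ests) <- colnames(X)
  if (length(ests) == 1L) ests[[1L]] else ests
}

first_stage_partial_f <- function(x, Zm, C) {
  n <- length(x)
  X0 <- cbind(rep(1, n), C)
  X1 <- cbind(rep(1, n), C, Zm)
  rss0 <- sum(qr.resid(qr(X0), x)^2)
  q1 <- qr(X1)
  rss1 <- sum(qr.resid(q1, x)^2)
  k <- ncol(as.matrix(Zm))
  ((rss0 - rss1) / k) / (rss1 / (n - q1$rank))
}

#' First-stage instrument strength diagnostics
#'
#' Computes the proportion of variance of the instrumented variable
#' explained by its instrument and the corresponding first-stage F
#' statistic; with covariates, the partial R-squared and partial F for
#' the instrument are returned. For a single instrument without
#' covariates the identity `F = R^2 (n - 2) / (1 - R^2)` holds exactly.
#'
#' @param variable the instrumented variable (numeric vector).
#' @param instrument numeric vector or matrix of instruments.
#' @param covariates optional data.frame/matrix of covariates.
#' @return list of class `instrument_diagnostics` with elements
#'   `r_squared`, `f_statistic`, `n`.
#' @export
instrument_strength <- function(variable, instrument, covariates = NULL) {
  Zm <- as.matrix(instrument)
  n <- length(variable)
  C <- NULL
  if (!is.null(covariates)) {
    C <- model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
  }
  if (n <= ncol(Zm) + ifelse(is.null(C), 0, ncol(C)) + 1) {
    stop("too few observations for first-stage diagnostics", call. = FALSE)
  }
  rss0 <- sum(qr.resid(qr(cbind(rep(1, n), C)), variable)^2)
  q1 <- qr(cbind(rep(1, n), C, Zm))
  rss1 <- sum(qr.resid(q1, variable)^2)
  r2 <- (rss0 - rss1) / rss0
  k <- ncol(Zm)
  f <- ((rss0 - rss1) / k) / (rss1 / (n - q1$rank))
  structure(list(r_squared = r2, f_statistic = f, n = n),
            class = "instrument_diagnostics")
}

#' @export
print.instrument_diagnostics <- function(x, ...) {
  cat(sprintf("Instrument strength: R^2 = %.4f (%.2f%%), F = %.1f, n = %d\n",
              x$r_squared, 100 * x$r_squared, x$f_statistic, x$n))
  invisible(x)
}
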