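#' Reciprocal Mendelian randomization: orient the exposure-mediator effect
#'
#' Estimates the causal effect of X on Z using X's instrument and of Z on
#' X using Z's instrument, and classifies the direction of effect from
#' the two significance tests at level `alpha`.
#'
#' By default significance is judged by the two-sided t-test on the
#' instrument-outcome regression coefficient (the numerator of the
#' ratio), which is equivalent to the ratio test for a strong instrument
#' and does not depend on the ratio standard-error convention;
#' `test = "ratio"` uses the Wald test on the ratio estimate instead.
#' The ratio point estimates are reported either way.
#'
#' @param dataset an [iv_dataset()].
#' @param alpha significance level for each test (default 0.05).
#' @param test `"reduced_form"` (default) or `"ratio"`.
#' @return list of class `direction_result` with elements `x_to_z` and
#'   `z_to_x` ([causal_estimate()]s), `p_x_to_z`, `p_z_to_x` (per the
#'   chosen test), `alpha`, `test`, `verdict` (one of `x_causes_z`,
#'   `z_causes_x`, `bidirectional`, `undetermined`) and an interpretive
#'   `note`.
#' @export
reciprocal_mr <- function(dataset, alpha = 0.05,
                          test = c("reduced_form", "ratio")) {
  test <- match.arg(test)
  stopifnot(alpha > 0, alpha < 1)
  x_to_z <- ratio_estimate(dataset$z, dataset$x, dataset$g_x,
                           warn_weak = FALSE)
  z_to_x <- ratio_estimate(dataset$x, dataset$z, dataset$g_z,
                           warn_weak = FALSE)
  if (test == "reduced_form") {
    p_xz <- attr(x_to_z, "components")$numerator$p
    p_zx <- attr(z_to_x, "components")$numerator$p
  } else {
    p_xz <- x_to_z$p_value
    p_zx <- z_to_x$p_value
  }
  sig_xz <- p_xz < alpha
  sig_zx <- p_zx < alpha
  verdict <- if (sig_xz && sig_zx) "bidirectional"
    else if (sig_xz) "x_causes_z"
    else if (sig_zx) "z_causes_x"
    else "undetermined"
  structure(list(
    x_to_z = x_to_z, z_to_x = z_to_x,
    p_x_to_z = p_xz, p_z_to_x = p_zx,
    alpha = alpha, test = test, verdict = verdict,
    note = paste("Verdicts describe the significance pattern only; an",
                 "apparently bidirectional relationship may reflect",
                 "effects operating in different directions at different",
                 "times of life, which instrument-based estimates of",
                 "long-term effects cannot separate.")),
    class = "direction_result")
}

#' @export
print.direction_result <- function(x, digits = 3, ...) {
  cat("Reciprocal Mendelian randomization (alpha =", x$alpha,
      ", test =", x$test, ")\n")
  cat(sprintf("  x -> z: %s, p = %s\n",
              format(x$x_to_z$estimate, digits = digits),
              format(x$p_x_to_z, digits = 2)))
  cat(sprintf("  z -> x: %s, p = %s\n",
              format(x$z_to_x$estimate, digits = digits),
              format(x$p_z_to_x, digits = 2)))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
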