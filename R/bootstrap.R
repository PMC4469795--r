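#' Bootstrap settings
#'
#' @param n_resamples number of nonparametric bootstrap resamples
#'   (default 1000, the usual convention for reported standard errors; a
#'   warning is issued below 100).
#' @param seed optional RNG seed making the resampling reproducible.
#' @param ci_type `"normal"` (Wald interval using the bootstrap SE,
#'   default) or `"percentile"`.
#' @return list of class `bootstrap_settings`.
#' @export
bootstrap_settings <- function(n_resamples = 1000, seed = NULL,
                               ci_type = c("normal", "percentile")) {
  ci_type <- match.arg(ci_type)
  n_resamples <- as.integer(n_resamples)
  stopifnot(n_resamples >= 1L)
  if (n_resamples < 100L) {
    warning("fewer than 100 bootstrap resamples; reported SEs will be noisy",
            call. = FALSE)
  }
  structure(list(n_resamples = n_resamples, seed = seed, ci_type = ci_type),
            class = "bootstrap_settings")
}

#' Nonparametric bootstrap of a dataset statistic
#'
#' Resamples individuals (rows) with replacement and re-evaluates the
#' whole statistic pipeline on every resample. Resamples on which the
#' statistic fails (e.g. a weak-instrument guard fires) are dropped and
#' counted: a warning is raised above 1% failures and an error above 10%.
#'
#' @param statistic function mapping an [iv_dataset()] to a numeric
#'   vector (possibly named, possibly length > 1).
#' @param dataset an [iv_dataset()].
#' @param settings a [bootstrap_settings()].
#' @param level confidence level for the intervals.
#' @return list of class `bootstrap_result` with elements `estimate`
#'   (statistic on the original data), `se`, `ci_low`, `ci_high`,
#'   `n_failed`, `n_resamples`, `replicates` (matrix of resample values).
#' @export
bootstrap_statistic <- function(statistic, dataset,
                                settings = bootstrap_settings(),
                                level = 0.95) {
  theta <- statistic(dataset)
  p <- length(theta)
  n <- nrow(dataset)
  if (!is.null(settings$seed)) set.seed(settings$seed)
  B <- settings$n_resamples
  reps <- matrix(NA_real_, B, p)
  colnames(reps) <- names(theta)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch(statistic(subset_rows(dataset, idx)),
                    error = function(e) NULL)
    if (!is.null(val)) reps[b, ] <- val
  }
  ok <- stats::complete.cases(reps)
  n_failed <- sum(!ok)
  if (n_failed > 0.10 * B) {
    stop("bootstrap unstable: ", n_failed, "/", B, " resamples failed",
         call. = FALSE)
  }
  if (n_failed > 0.01 * B) {
    warning(n_failed, "/", B, " bootstrap resamples failed and were dropped",
            call. = FALSE)
  }
  keep <- reps[ok, , drop = FALSE]
  se <- apply(keep, 2, sd)
  if (settings$ci_type == "normal") {
    z <- qnorm(1 - (1 - level) / 2)
    ci_low <- theta - z * se
    ci_high <- theta + z * se
  } else {
    qs <- apply(keep, 2, quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                names = FALSE)
    ci_low <- qs[1, ]
    ci_high <- qs[2, ]
  }
  structure(list(estimate = theta, se = se, ci_low = ci_low,
                 ci_high = ci_high, n_failed = n_failed,
                 n_resamples = B, ci_type = settings$ci_type,
                 replicates = keep),
            class = "bootstrap_result")
}
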