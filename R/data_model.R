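#' Construct an instrumental-variable dataset
#'
#' Bundles per-individual measurements of two genetic instruments, an
#' exposure, a mediator and an outcome (plus optional covariates) into a
#' validated `iv_dataset`, the common input of all estimators in the
#' package. Rows with missing values in any of the five primary columns
#' are dropped with a message; instruments must have nonzero sample
#' variance.
#'
#' @param data a data.frame containing the mapped columns.
#' @param g_x,g_z,x,z,y names of the columns holding the exposure
#'   instrument, mediator instrument, exposure, mediator and outcome.
#'   Instrument columns may be genotype counts (0/1/2) or continuous
#'   allele scores / dosages.
#' @param covariates optional character vector of covariate column names
#'   (numeric or factor) carried along for adjustment.
#' @param validate set to `FALSE` to skip checks (internal use).
#' @return an object of class `iv_dataset`: a data.frame with canonical
#'   columns `g_x, g_z, x, z, y` followed by any covariates, with
#'   attributes `covariates` (names) and `n_dropped` (rows removed for
#'   missingness).
#' @examples
#' d <- data.frame(gx = rbinom(50, 2, 0.3), gz = rbinom(50, 2, 0.3),
#'                 bmi = rnorm(50), crp = rnorm(50), urate = rnorm(50))
#' ds <- iv_dataset(d, g_x = "gx", g_z = "gz", x = "bmi", z = "crp", y = "urate")
#' @export
iv_dataset <- function(data, g_x = "g_x", g_z = "g_z", x = "x", z = "z",
                       y = "y", covariates = NULL, validate = TRUE) {
  stopifnot(is.data.frame(data))
  map <- c(g_x = g_x, g_z = g_z, x = x, z = z, y = y)
  missing_cols <- setdiff(c(map, covariates), names(data))
  if (length(missing_cols)) {
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- data[, unname(map), drop = FALSE]
  names(out) <- names(map)
  for (cv in covariates) out[[cv]] <- data[[cv]]

  n_dropped <- 0L
  if (validate) {
    keep <- complete.cases(out[, c("g_x", "g_z", "x", "z", "y")])
    n_dropped <- sum(!keep)
    if (n_dropped > 0L) {
      out <- out[keep, , drop = FALSE]
      rownames(out) <- NULL
      message("iv_dataset: dropped ", n_dropped,
              " row(s) with missing values in primary columns")
    }
    if (nrow(out) < 3L) stop("need at least 3 complete rows", call. = FALSE)
    for (ins in c("g_x", "g_z")) {
      if (!is.numeric(out[[ins]])) stop(ins, " must be numeric", call. = FALSE)
      if (var(out[[ins]]) <= 0) {
        stop("instrument '", ins, "' has zero sample variance", call. = FALSE)
      }
    }
    for (v in c("x", "z", "y")) {
      if (!is.numeric(out[[v]])) stop(v, " must be numeric", call. = FALSE)
    }
  }
  structure(out,
            covariates = covariates %||% character(),
            n_dropped = n_dropped,
            class = c("iv_dataset", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.iv_dataset <- function(x, ...) {
  cat("<iv_dataset> n =", nrow(x), "individuals")
  cv <- attr(x, "covariates")
  if (length(cv)) cat("; covariates:", paste(cv, collapse = ", "))
  if (attr(x, "n_dropped") > 0) cat("; dropped:", attr(x, "n_dropped"))
  cat("\n")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

# fast row subset preserving class/attributes, no re-validation
# (used by the bootstrap; an i.i.d. resample of a valid dataset is valid
# with probability 1 apart from pathological zero-variance draws, which the
# estimators guard against themselves)
subset_rows <- function(dataset, idx) {
  out <- as.data.frame(dataset)[idx, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out) <- c(attributes(out)[c("names", "row.names")],
                       list(covariates = attr(dataset, "covariates"),
                            n_dropped = 0L,
                            class = c("iv_dataset", "data.frame")))
  out
}

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = ",", tsv = "\t", txt = "\t", "\t")
}

#' Read an instrumental-variable dataset from a delimited text file
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param g_x,g_z,x,z,y,covariates column mapping, as in [iv_dataset()].
#' @param delim field delimiter; by default inferred from the file
#'   extension (`.csv` is comma, anything else tab).
#' @return a validated [iv_dataset()]; the number of rows dropped for
#'   missingness is reported via a message.
#' @export
read_iv_dataset <- function(path, g_x = "g_x", g_z = "g_z", x = "x",
                            z = "z", y = "y", covariates = NULL,
                            delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.table(path, header = TRUE, sep = infer_delim(path, delim),
                    stringsAsFactors = FALSE, check.names = FALSE)
  iv_dataset(raw, g_x = g_x, g_z = g_z, x = x, z = z, y = y,
             covariates = covariates)
}

#' Write an instrumental-variable dataset to a delimited text file
#'
#' Numeric columns are written with 17 significant digits so that reading
#' the file back reproduces the doubles bit-for-bit.
#'
#' @param dataset an [iv_dataset()].
#' @param path output path; delimiter inferred from the extension unless
#'   `delim` is given.
#' @param delim optional field delimiter.
#' @return `path`, invisibly.
#' @export
write_iv_dataset <- function(dataset, path, delim = NULL) {
  df <- as.data.frame(dataset)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  write.table(df, path, sep = infer_delim(path, delim), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

covariate_design <- function(dataset, covariate_names) {
  cdf <- as.data.frame(dataset)[, covariate_names, drop = FALSE]
  for (j in seq_along(cdf)) {
    if (is.character(cdf[[j]])) cdf[[j]] <- factor(cdf[[j]])
  }
  # reference-level indicator coding for factors, intercept included
  model.matrix(~ ., data = cdf)
}

#' Residualize dataset columns on covariates
#'
#' Replaces the exposure, mediator and outcome (and optionally the
#' instruments) by their residuals from a least-squares regression on the
#' requested covariates, with categorical covariates expanded to
#' reference-level indicators. This mirrors the usual pre-adjustment of
#' biomarker measurements for age, sex and centre before an
#' instrumental-variable analysis. The operation is idempotent.
#'
#' @param dataset an [iv_dataset()].
#' @param covariates covariate names to adjust for; defaults to all
#'   covariates present in the dataset. With no covariates the input is
#'   returned unchanged.
#' @param columns which columns to residualize (default `x`, `z`, `y`).
#' @param include_instruments also residualize `g_x` and `g_z`.
#' @return the dataset with the selected columns replaced by residuals
#'   (mean zero by construction).
#' @export
residualize <- function(dataset, covariates = NULL,
                        columns = c("x", "z", "y"),
                        include_instruments = FALSE) {
  covariates <- covariates %||% attr(dataset, "covariates")
  if (!length(covariates)) return(dataset)
  missing_cv <- setdiff(covariates, names(dataset))
  if (length(missing_cv)) {
    stop("covariate(s) not in dataset: ", paste(missing_cv, collapse = ", "),
         call. = FALSE)
  }
  X <- covariate_design(dataset, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (include_instruments) columns <- union(columns, c("g_x", "g_z"))
  for (v in columns) dataset[[v]] <- as.numeric(qr.resid(qx, dataset[[v]]))
  dataset
}

#' Read a variant-weights table
#'
#' Expects a delimited text file with a header and columns `variant_id`,
#' `trait` and `weight` (per-allele effect used in allele-score
#' construction).
#'
#' @param path file path; delimiter inferred from extension unless given.
#' @param delim optional delimiter.
#' @return a data.frame with columns `variant_id`, `trait`, `weight`.
#' @export
read_variant_weights <- function(path, delim = NULL) {
  w <- read.table(path, header = TRUE, sep = infer_delim(path, delim),
                  stringsAsFactors = FALSE)
  need <- c("variant_id", "trait", "weight")
  miss <- setdiff(need, names(w))
  if (length(miss)) {
    stop("weights file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(w$weight))) stop("non-finite weights", call. = FALSE)
  if (!nrow(w)) stop("empty weights table", call. = FALSE)
  w[, need]
}

#' Construct a calibrated weighted allele score
#'
#' Computes the weighted sum of per-variant genotypes and rescales it so
#' that the regression of the instrumented variable on the returned score
#' (optionally adjusting for covariates) has slope exactly 1. On that
#' scale the reduced-form coefficients of downstream variables on the
#' score are directly interpretable as per-unit causal effect estimates.
#'
#' @param genotypes numeric matrix or data.frame, individuals x variants,
#'   column names matching `weights$variant_id`. Dosages are accepted.
#' @param weights a data.frame as returned by [read_variant_weights()];
#'   use `trait` to select the relevant rows if it covers several traits.
#' @param calibrate_to numeric vector of the instrumented variable, used
#'   to fix the scaling constant.
#' @param covariates optional data.frame of covariates adjusted for in the
#'   calibration regression (the default, matching routine practice of
#'   adjusting every regression for the same covariates); pass `NULL` for
#'   an unadjusted calibration.
#' @param trait optional trait label selecting rows of `weights`.
#' @return the scaled score vector, with attribute `scaling` holding the
#'   multiplier applied to the raw weighted score.
#' @export
weighted_allele_score <- function(genotypes, weights, calibrate_to,
                                  covariates = NULL, trait = NULL) {
  if (!is.null(trait)) weights <- weights[weights$trait == trait, , drop = FALSE]
  if (!nrow(weights)) stop("no weights for requested trait", call. = FALSE)
  G <- as.matrix(as.data.frame(genotypes)[, weights$variant_id, drop = FALSE])
  raw <- drop(G %*% weights$weight)
  D <- cbind(`(Intercept)` = 1, score = raw)
  if (!is.null(covariates)) {
    cd <- model.matrix(~ ., data = as.data.frame(covariates))
    D <- cbind(D, cd[, -1, drop = FALSE])
  }
  fit <- stats::lm.fit(D, calibrate_to)
  b <- coef(fit)["score"]
  r <- fit$residuals
  s2 <- sum(r^2) / fit$df.residual
  XtXinv <- chol2inv(chol(crossprod(D)))
  se_b <- sqrt(s2 * XtXinv[2, 2])
  tval <- b / se_b
  if (!is.finite(tval) || abs(tval) < 1) {
    stop("raw allele score does not predict the calibration variable ",
         "(|t| < 1); not a usable instrument", call. = FALSE)
  }
  structure(raw * b, scaling = unname(b))
}
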