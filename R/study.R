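#' Run one Monte Carlo scenario
#'
#' Simulates `replicates` datasets from `config` (replicate r uses seed
#' `base_seed + r`, so any replicate is individually reproducible), runs
#' the regression-based mediation decomposition, the path-model ML fit
#' and the reciprocal direction test on each, and summarizes the direct
#' and indirect effect estimates per estimator: mean estimate, mean
#' standard error, standard deviation of estimates over replicates, and
#' the Monte Carlo standard error of the mean (SD / sqrt(replicates)).
#'
#' @param config a [sim_config()].
#' @param replicates number of datasets (>= 2).
#' @param bootstrap [bootstrap_settings()] for the regression-based
#'   standard errors, or `NULL` to skip them (point estimates are still
#'   summarized).
#' @param alpha significance level for the direction tests.
#' @param base_seed base of the per-replicate seed stream.
#' @param estimators any subset of `c("regression", "sem")`.
#' @return list of class `scenario_summary`: `scenario` (the defining
#'   parameters), `summary` (long data.frame: estimator, estimand, mean,
#'   mean_se, sd, mc_se), `detection` (rates of significant forward and
#'   reverse effects under the reduced-form and ratio tests),
#'   `replicates`, `estimates` (per-replicate draws), `failed_seeds`.
#' @export
run_scenario <- function(config, replicates = 1000,
                         bootstrap = bootstrap_settings(),
                         alpha = 0.05, base_seed = 1,
                         estimators = c("regression", "sem")) {
  stopifnot(replicates >= 2)
  estimators <- match.arg(estimators, several.ok = TRUE)
  cols <- c("reg_direct", "reg_indirect", "reg_direct_se", "reg_indirect_se",
            "sem_direct", "sem_indirect", "sem_direct_se", "sem_indirect_se",
            "det_xz_rf", "det_zx_rf", "det_xz_ratio", "det_zx_ratio")
  est <- matrix(NA_real_, replicates, length(cols),
                dimnames = list(NULL, cols))
  failed <- integer()
  for (r in seq_len(replicates)) {
    seed_r <- base_seed + r
    res <- tryCatch({
      d <- simulate_dataset(config, seed = seed_r)
      row <- setNames(rep(NA_real_, length(cols)), cols)
      if ("regression" %in% estimators) {
        bs <- if (is.null(bootstrap)) NULL else {
          bootstrap_settings(bootstrap$n_resamples,
                             seed = (bootstrap$seed %||% 0) + seed_r,
                             ci_type = bootstrap$ci_type)
        }
        mr <- suppressWarnings(mediation_ratio_difference(d, bootstrap = bs))
        row["reg_direct"] <- mr$direct$estimate
        row["reg_indirect"] <- mr$indirect$estimate
        row["reg_direct_se"] <- mr$direct$se
        row["reg_indirect_se"] <- mr$indirect$se
      }
      if ("sem" %in% estimators) {
        sf <- sem_effects(fit_sem(d))
        row["sem_direct"] <- sf$direct$estimate
        row["sem_indirect"] <- sf$indirect$estimate
        row["sem_direct_se"] <- sf$direct$se
        row["sem_indirect_se"] <- sf$indirect$se
      }
      dir_rf <- reciprocal_mr(d, alpha = alpha, test = "reduced_form")
      dir_ratio <- reciprocal_mr(d, alpha = alpha, test = "ratio")
      row["det_xz_rf"] <- as.numeric(dir_rf$p_x_to_z < alpha)
      row["det_zx_rf"] <- as.numeric(dir_rf$p_z_to_x < alpha)
      row["det_xz_ratio"] <- as.numeric(dir_ratio$p_x_to_z < alpha)
      row["det_zx_ratio"] <- as.numeric(dir_ratio$p_z_to_x < alpha)
      row
    }, error = function(e) NULL)
    if (is.null(res)) failed <- c(failed, seed_r) else est[r, ] <- res
  }
  if (length(failed) > 0.01 * replicates) {
    stop("more than 1% of replicates failed; seeds: ",
         paste(failed, collapse = ", "), call. = FALSE)
  }
  ok <- !is.na(est[, "det_xz_rf"])
  est <- est[ok, , drop = FALSE]
  nrep <- nrow(est)

  summarize <- function(prefix, estimand) {
    v <- est[, paste0(prefix, "_", estimand)]
    s <- est[, paste0(prefix, "_", estimand, "_se")]
    data.frame(
      estimator = if (prefix == "reg") "regression" else "sem",
      estimand = estimand,
      mean = mean(v), mean_se = mean(s), sd = sd(v),
      mc_se = sd(v) / sqrt(nrep), stringsAsFactors = FALSE)
  }
  blocks <- list()
  if ("regression" %in% estimators) {
    blocks <- c(blocks, list(summarize("reg", "direct"),
                             summarize("reg", "indirect")))
  }
  if ("sem" %in% estimators) {
    blocks <- c(blocks, list(summarize("sem", "direct"),
                             summarize("sem", "indirect")))
  }
  summary_df <- do.call(rbind, blocks)
  detection <- data.frame(
    test = c("x_to_z", "z_to_x"),
    reduced_form = c(mean(est[, "det_xz_rf"]), mean(est[, "det_zx_rf"])),
    ratio = c(mean(est[, "det_xz_ratio"]), mean(est[, "det_zx_ratio"])),
    stringsAsFactors = FALSE)

  structure(list(
    scenario = c(mu_betaX = config$mu_betaX, mu_gammaZ = config$mu_gammaZ,
                 tau2 = config$tau2),
    config = config,
    summary = summary_df,
    detection = detection,
    replicates = nrep,
    alpha = alpha,
    base_seed = base_seed,
    estimates = as.data.frame(est),
    failed_seeds = failed),
    class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf("Scenario mu_betaX = %g, mu_gammaZ = %g, tau2 = %g (%d replicates)\n",
              x$scenario["mu_betaX"], x$scenario["mu_gammaZ"],
              x$scenario["tau2"], x$replicates))
  s <- x$summary
  s[, c("mean", "mean_se", "sd")] <-
    round(s[, c("mean", "mean_se", "sd")], 2)  # table-style rounding
  s$mc_se <- signif(s$mc_se, 2)
  print(s, row.names = FALSE)
  cat(sprintf("Detection at alpha = %g (reduced form): x->z %.1f%%, z->x %.1f%%\n",
              x$alpha, 100 * x$detection$reduced_form[1],
              100 * x$detection$reduced_form[2]))
  invisible(x)
}

#' Run the full twelve-scenario Monte Carlo study
#'
#' Maps [run_scenario()] over [scenario_grid()], giving each scenario a
#' disjoint seed stream, and binds the per-scenario summaries into one
#' long table (one row per scenario x estimator x estimand). Optionally
#' writes the full-precision table as TSV, the summaries as JSON (when
#' the jsonlite package is available) and a fixed-width text rendering
#' rounded to 2 decimals.
#'
#' @param replicates datasets per scenario (1000 in the reference study;
#'   smaller values are appropriate for desk-scale runs).
#' @param bootstrap [bootstrap_settings()] or `NULL`.
#' @param alpha significance level for direction tests.
#' @param base_seed study-level base seed; scenario s uses
#'   `base_seed + (s - 1) * 10^6` as its replicate-seed base.
#' @param n individuals per dataset.
#' @param out_dir optional output directory.
#' @param estimators subset of `c("regression", "sem")`.
#' @return list of class `study_result`: `table` (long data.frame),
#'   `detection` (per scenario), `scenarios` (the 12 summaries).
#' @export
run_table1 <- function(replicates = 1000, bootstrap = bootstrap_settings(),
                       alpha = 0.05, base_seed = 1, n = 5000,
                       out_dir = NULL,
                       estimators = c("regression", "sem")) {
  grid <- scenario_grid(n = n)
  scenarios <- vector("list", length(grid))
  names(scenarios) <- names(grid)
  rows <- list()
  det_rows <- list()
  for (s in seq_along(grid)) {
    sc <- run_scenario(grid[[s]], replicates = replicates,
                       bootstrap = bootstrap, alpha = alpha,
                       base_seed = base_seed + (s - 1L) * 1000000L,
                       estimators = estimators)
    scenarios[[s]] <- sc
    tab <- sc$summary
    tab <- cbind(data.frame(scenario = names(grid)[s],
                            mu_betaX = sc$scenario[["mu_betaX"]],
                            mu_gammaZ = sc$scenario[["mu_gammaZ"]],
                            tau2 = sc$scenario[["tau2"]]),
                 tab, replicates = sc$replicates)
    rows[[s]] <- tab
    det_rows[[s]] <- cbind(data.frame(scenario = names(grid)[s]),
                           sc$detection)
  }
  table_long <- do.call(rbind, rows)
  rownames(table_long) <- NULL
  detection <- do.call(rbind, det_rows)
  rownames(detection) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(table_long, file.path(out_dir, "study_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(detection, file.path(out_dir, "detection_rates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(list(table = table_long, detection = detection),
                           file.path(out_dir, "study_summary.json"),
                           dataframe = "rows", digits = NA)
    }
    txt <- utils::capture.output(print_study_table(table_long))
    writeLines(txt, file.path(out_dir, "study_table.txt"))
  }
  structure(list(table = table_long, detection = detection,
                 scenarios = scenarios, replicates = replicates,
                 base_seed = base_seed),
            class = "study_result")
}

print_study_table <- function(table_long) {
  disp <- table_long
  disp[, c("mean", "mean_se", "sd")] <-
    round(disp[, c("mean", "mean_se", "sd")], 2)
  disp$mc_se <- signif(disp$mc_se, 2)
  print(disp, row.names = FALSE)
  invisible(disp)
}

#' @export
print.study_result <- function(x, ...) {
  cat("Monte Carlo study:", length(x$scenarios), "scenarios x",
      x$replicates, "replicates\n")
  print_study_table(x$table)
  invisible(x)
}
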