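test_that("decomposition identity total = direct + indirect is exact", {
  d <- toy_dataset(n = 2000, seed = 31)
  m <- mediation_ratio_difference(d, bootstrap = NULL)
  expect_lt(abs(m$total$estimate - m$direct$estimate - m$indirect$estimate),
            1e-12)
  ms <- multi_stage_least_squares(d, bootstrap = NULL)
  expect_lt(abs(ms$total$estimate - ms$direct$estimate -
                  ms$indirect$estimate), 1e-12)
})

test_that("zero mediated path gives indirect 0 and direct = total exactly", {
  m <- mediation_from_coefficients(0.4, 1.0, 0, -0.2, 1.0)
  expect_identical(m$indirect$estimate, 0)
  expect_identical(m$direct$estimate, m$total$estimate)
  expect_error(mediation_from_coefficients(0.4, 0, 0.1, -0.2, 1.0),
               "nonzero")
})

test_that("both mediation estimators are invariant to affine instrument recoding", {
  d <- toy_dataset(n = 1500, seed = 32)
  d2 <- d
  d2$g_x <- 2.5 * d$g_x - 1
  d2$g_z <- -0.7 * d$g_z + 3
  for (est in list(mediation_ratio_difference, multi_stage_least_squares)) {
    a <- est(d, bootstrap = NULL)
    b <- est(d2, bootstrap = NULL)
    expect_equal(b$total$estimate, a$total$estimate, tolerance = 1e-10)
    expect_equal(b$direct$estimate, a$direct$estimate, tolerance = 1e-10)
    expect_equal(b$indirect$estimate, a$indirect$estimate, tolerance = 1e-10)
  }
})

test_that("bootstrap is seed-deterministic and matches closed forms", {
  d <- toy_dataset(n = 400, seed = 33)
  st <- bootstrap_settings(300, seed = 7)
  b1 <- bootstrap_statistic(function(dd) c(m = mean(dd$y)), d, st)
  b2 <- bootstrap_statistic(function(dd) c(m = mean(dd$y)), d, st)
  expect_identical(b1$se, b2$se)
  expect_identical(b1$replicates, b2$replicates)
  # bootstrap SE of the mean ~ s / sqrt(n)
  expect_estimate_close(b1$se, sd(d$y) / sqrt(nrow(d)), 0.1 * b1$se)
  # percentile CIs are ordered around the estimate
  bp <- bootstrap_statistic(function(dd) c(m = mean(dd$y)), d,
                            bootstrap_settings(300, seed = 7,
                                               ci_type = "percentile"))
  expect_lt(bp$ci_low, bp$ci_high)

  # whole mediation pipeline is reproducible under a fixed seed
  m1 <- mediation_ratio_difference(d, bootstrap_settings(150, seed = 11))
  m2 <- mediation_ratio_difference(d, bootstrap_settings(150, seed = 11))
  expect_identical(m1$direct$se, m2$direct$se)
})

test_that("failing resamples are counted, warned about and capped", {
  d <- toy_dataset(n = 200, seed = 34)
  # statistic that succeeds on the original data but fails on roughly half
  # of the resamples -> unstable -> error
  y_bar <- mean(d$y)
  flaky <- function(dd) if (mean(dd$y) > y_bar) stop("boom") else 1
  expect_error(
    suppressWarnings(bootstrap_statistic(function(dd) c(s = flaky(dd)), d,
                                         bootstrap_settings(200, seed = 5))),
    "unstable")
  expect_warning(bootstrap_settings(50), "fewer than 100")
})

test_that("ratio-difference and multi-stage least squares agree on common data", {
  d <- toy_dataset(n = 3000, seed = 35)
  st <- bootstrap_settings(200, seed = 9)
  a <- mediation_ratio_difference(d, st)
  b <- multi_stage_least_squares(d, st)
  for (comp in c("direct", "indirect")) {
    se <- sqrt(a[[comp]]$se^2 + b[[comp]]$se^2)
    expect_estimate_close(a[[comp]]$estimate, b[[comp]]$estimate, 3 * se)
  }
})

test_that("mediation estimators recover generating values without confounding", {
  cfg <- sim_config(n = 2000, confounder_sd = 0)
  reps <- 200
  est <- matrix(NA_real_, reps, 4)
  for (r in seq_len(reps)) {
    d <- simulate_dataset(cfg, seed = 5000 + r)
    m <- mediation_ratio_difference(d, bootstrap = NULL)
    ms <- msls <- multi_stage_least_squares(d, bootstrap = NULL)
    est[r, ] <- c(m$direct$estimate, m$indirect$estimate,
                  msls$direct$estimate, msls$indirect$estimate)
  }
  mc_se <- apply(est, 2, sd) / sqrt(reps)
  truth <- c(1, 1, 1, 1)  # mu_gammaX and mu_betaX * mu_gammaZ
  for (j in 1:4) expect_estimate_close(mean(est[, j]), truth[j], 3 * mc_se[j])
})

test_that("instruments that cannot separate exposure and mediator are refused", {
  set.seed(36)
  n <- 1000
  g_x <- rbinom(n, 2, 0.3)
  x <- 0.5 * g_x + rnorm(n)
  z <- 2 * x + rnorm(n)
  y <- x + z + rnorm(n)
  # the mediator's "instrument" is the exposure's: fitted mediator and
  # fitted exposure are then exact linear functions of each other
  d <- iv_dataset(data.frame(g_x = g_x, g_z = g_x, x = x, z = z, y = y))
  expect_error(multi_stage_least_squares(d, bootstrap = NULL),
               "do not separate")
})

test_that("covariate adjustment is redone inside each bootstrap resample", {
  set.seed(37)
  base <- toy_dataset(n = 600, seed = 38)
  df <- as.data.frame(base)
  df$age <- rnorm(600)
  df$y <- df$y + 3 * df$age
  d <- iv_dataset(df, covariates = "age")
  m_adj <- mediation_ratio_difference(d, bootstrap_settings(150, seed = 2),
                                      adjust = "age")
  m_raw <- mediation_ratio_difference(base, bootstrap = NULL)
  # adjusting away the added covariate noise restores the clean estimate
  expect_estimate_close(m_adj$total$estimate, m_raw$total$estimate,
                        3 * m_adj$total$se)
  expect_true(is.finite(m_adj$direct$se))
})
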