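test_that("implied moments reproduce closed-form special cases", {
  pm <- path_model()
  null_par <- list(paths = setNames(numeric(5), netmr:::sem_path_names),
                   psi_g = diag(2), psi_err = diag(3))
  mom <- implied_moments(pm, null_par)
  expect_equal(mom$cov, diag(5), ignore_attr = TRUE)
  expect_equal(mom$mean, setNames(numeric(5), netmr:::sem_vars))

  # one path g_x -> x = 0.3 with var(g_x) = 0.42: cov(g_x, x) = 0.126
  par1 <- null_par
  par1$paths["gx_x"] <- 0.3
  par1$psi_g <- diag(c(0.42, 0.42))
  mom1 <- implied_moments(pm, par1)
  expect_equal(mom1$cov["g_x", "x"], 0.126, tolerance = 1e-12)
  expect_equal(mom1$cov["x", "x"], 1 + 0.3^2 * 0.42, tolerance = 1e-12)

  # non-PD error covariance is a domain error
  bad <- null_par
  bad$psi_err <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)
  expect_error(implied_moments(pm, bad), "positive definite")
})

test_that("implied covariance matches brute-force ancestral simulation", {
  pm <- path_model()
  par <- list(paths = c(gx_x = 0.4, gz_z = 0.6, x_z = 0.8, x_y = -0.5,
                        z_y = 0.7),
              psi_g = matrix(c(0.42, 0.05, 0.05, 0.42), 2),
              psi_err = matrix(c(1.5, 0.4, 0.3,
                                 0.4, 1.2, 0.5,
                                 0.3, 0.5, 2.0), 3))
  mom <- implied_moments(pm, par)

  # oracle: simulate the recursive system directly at large n
  set.seed(41)
  n <- 400000
  Lg <- chol(par$psi_g); Le <- chol(par$psi_err)
  G <- matrix(rnorm(2 * n), n, 2) %*% Lg
  E <- matrix(rnorm(3 * n), n, 3) %*% Le
  x <- par$paths["gx_x"] * G[, 1] + E[, 1]
  z <- par$paths["gz_z"] * G[, 2] + par$paths["x_z"] * x + E[, 2]
  y <- par$paths["x_y"] * x + par$paths["z_y"] * z + E[, 3]
  S_emp <- cov(cbind(G, x, z, y))
  expect_equal(unname(mom$cov), unname(S_emp), tolerance = 0.03)
})

test_that("with uncorrelated errors the ML fit reduces to sequential OLS", {
  cfg <- sim_config(n = 4000, confounder_sd = 0, seed = 42)
  d <- simulate_dataset(cfg)
  fit <- fit_sem(d, path_model(correlated_errors = FALSE))
  expect_true(fit$converged)
  ols <- coef(lm(y ~ x + z, data = as.data.frame(d)))
  expect_equal(unname(fit$paths["x_y"]), unname(ols["x"]), tolerance = 1e-4)
  expect_equal(unname(fit$paths["z_y"]), unname(ols["z"]), tolerance = 1e-4)
  ols_z <- coef(lm(z ~ g_z + x, data = as.data.frame(d)))
  expect_equal(unname(fit$paths["x_z"]), unname(ols_z["x"]), tolerance = 1e-4)
})

test_that("path-model fit is permutation-invariant and instrument-recoding equivariant", {
  d <- simulate_dataset(sim_config(n = 2000, seed = 43))
  fit <- fit_sem(d)
  perm <- netmr:::subset_rows(d, sample(nrow(d)))
  fit_p <- fit_sem(perm)
  expect_equal(fit_p$paths, fit$paths, tolerance = 1e-7)
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-6)

  # recoding g_x -> 2 g_x + 1 halves the g_x -> x path, leaves the rest
  # (up to optimizer tolerance: the recoded problem is optimized afresh)
  d2 <- d; d2$g_x <- 2 * d$g_x + 1
  fit_r <- fit_sem(d2)
  expect_equal(unname(fit_r$paths["gx_x"]), unname(fit$paths["gx_x"]) / 2,
               tolerance = 1e-3)
  for (nm in c("x_z", "x_y", "z_y")) {
    expect_equal(unname(fit_r$paths[nm]), unname(fit$paths[nm]),
                 tolerance = 1e-3)
  }
})

test_that("fit quality: saturated bound, LR statistic and vcov structure", {
  d <- simulate_dataset(sim_config(n = 3000, seed = 44))
  fit <- fit_sem(d)
  expect_true(fit$converged)
  expect_gte(fit$lr_saturated, -1e-8)
  expect_equal(fit$df, 1L)

  # saturated log-likelihood computed directly bounds the fitted one
  m <- as.matrix(as.data.frame(d)[, netmr:::sem_vars])
  n <- nrow(m); S <- cov(m) * (n - 1) / n
  ll_sat <- -(n / 2) * (5 * log(2 * pi) +
                          as.numeric(determinant(S)$modulus) + 5)
  expect_lte(fit$loglik, ll_sat + 1e-8)
  expect_equal(n * 2 * (ll_sat - fit$loglik) / n, fit$lr_saturated,
               tolerance = 1e-6)

  V <- fit$vcov
  expect_equal(V, t(V), tolerance = 1e-8)
  expect_true(all(diag(V) > 0))

  # zero-instrument-covariance variant has one fewer parameter
  fit0 <- fit_sem(d, path_model(instrument_covariance = "zero"))
  expect_equal(fit0$df, 2L)
  expect_gte(fit0$lr_saturated, fit$lr_saturated - 1e-6)
})

test_that("delta-method effects follow the stated formulas", {
  d <- simulate_dataset(sim_config(n = 3000, seed = 45))
  fit <- fit_sem(d)
  eff <- sem_effects(fit)
  cc <- fit$paths[["x_z"]]; ee <- fit$paths[["z_y"]]
  V <- fit$vcov[c("x_z", "z_y"), c("x_z", "z_y")]
  se_ind <- sqrt(ee^2 * V[1, 1] + cc^2 * V[2, 2] + 2 * cc * ee * V[1, 2])
  expect_equal(eff$indirect$se, se_ind, tolerance = 1e-10)
  expect_equal(eff$indirect$estimate, cc * ee, tolerance = 1e-12)
  expect_equal(eff$direct$estimate, fit$paths[["x_y"]], tolerance = 1e-12)
  expect_equal(eff$total$estimate,
               eff$direct$estimate + eff$indirect$estimate,
               tolerance = 1e-12)

  # worked example: var = e^2 0.01 + c^2 0.01 = 0.02 at c = e = 1
  fake <- fit
  fake$paths[c("x_z", "z_y")] <- c(1, 1)
  fake$vcov["x_z", "x_z"] <- 0.01
  fake$vcov["z_y", "z_y"] <- 0.01
  fake$vcov["x_z", "z_y"] <- fake$vcov["z_y", "x_z"] <- 0
  expect_equal(sem_effects(fake)$indirect$se, sqrt(0.02), tolerance = 1e-12)

  # degenerate point of the delta method is flagged
  fake0 <- fake
  fake0$paths[c("x_z", "z_y")] <- c(0, 0)
  expect_warning(sem_effects(fake0), "degenerates")
})

test_that("SEM and ratio-difference agree within combined uncertainty", {
  d <- simulate_dataset(sim_config(n = 5000, seed = 46))
  sem <- sem_effects(fit_sem(d))
  reg <- mediation_ratio_difference(d, bootstrap_settings(200, seed = 3))
  for (comp in c("direct", "indirect")) {
    se <- sqrt(sem[[comp]]$se^2 + reg[[comp]]$se^2)
    expect_estimate_close(sem[[comp]]$estimate, reg[[comp]]$estimate, 3 * se)
  }
})
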