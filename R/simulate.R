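#' Simulation configuration for the network-MR data-generating model
#'
#' Parameters of the data-generating model used throughout the package's
#' simulation study. Two biallelic instruments G_X, G_Z ~ Binomial(2,
#' `maf`) act on exposure and mediator; unmeasured confounding of each
#' pair of (X, Z, Y) is induced by three shared standard-normal
#' confounders (U_XZ, U_XY, U_ZY) with unit loadings; residual errors are
#' standard normal. Structural equations (per individual i):
#'
#' \preformatted{
#'   x = alpha_Gi g_x + u_xz + u_xy + e_x
#'   z = beta_Gi g_z + beta_Xi x + u_xz + u_zy + e_z
#'   y = gamma_Xi x + gamma_Zi z + delta_i x z + u_xy + u_zy + e_y
#' }
#'
#' The causal effects (beta_Xi, gamma_Xi, gamma_Zi) vary between
#' individuals: multivariate normal with means (`mu_betaX`, `mu_gammaX`,
#' `mu_gammaZ`), common variance `tau2` and common pairwise correlation
#' `effect_corr`. `tau2 = 0` is complete homogeneity. At the defaults
#' (`alpha_G = 0.3`, `maf = 0.3`, unit confounder/error scales) the
#' instrument explains about 1.3% of exposure variance, an average
#' first-stage F of about 65 at n = 5000; `beta_G` defaults to 0.5 when
#' `mu_betaX` is positive and 0.36 when negative, keeping the mediator
#' instrument's explained variance at the same level.
#'
#' @param n individuals per dataset (default 5000).
#' @param maf minor allele frequency in (0, 0.5), default 0.3.
#' @param alpha_G mean effect of G_X on X (default 0.3).
#' @param beta_G mean effect of G_Z on Z; default 0.5 for
#'   `mu_betaX >= 0`, 0.36 otherwise.
#' @param mu_betaX,mu_gammaX,mu_gammaZ mean causal effects of X on Z, X
#'   on Y (direct) and Z on Y (defaults 1, 1, 1).
#' @param tau2 variance of each individual-level causal effect
#'   (0, 0.2^2 or 0.4^2 in the reference scenarios; default 0).
#' @param effect_corr common pairwise correlation of the three
#'   individual-level effects (default 0).
#' @param interaction_mean,interaction_sd mean and SD of the
#'   individual-level X.Z interaction coefficient in the outcome equation
#'   (defaults 0, 0: no interaction).
#' @param genetic_effect_sd per-individual SD of the genetic effects
#'   alpha_Gi and beta_Gi around their means (default 0: fixed effects).
#' @param confounder_sd SD of each of the three shared confounders
#'   (default 1); set to 0 as a diagnostic switch that removes all
#'   confounding.
#' @param sigma_x,sigma_z,sigma_y residual error SDs (defaults 1).
#' @param seed optional RNG seed attached to the configuration.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n = 5000, maf = 0.3, alpha_G = 0.3, beta_G = NULL,
                       mu_betaX = 1, mu_gammaX = 1, mu_gammaZ = 1,
                       tau2 = 0, effect_corr = 0,
                       interaction_mean = 0, interaction_sd = 0,
                       genetic_effect_sd = 0, confounder_sd = 1,
                       sigma_x = 1, sigma_z = 1, sigma_y = 1,
                       seed = NULL) {
  beta_G <- beta_G %||% if (mu_betaX < 0) 0.36 else 0.5
  cfg <- list(n = as.integer(n), maf = maf, alpha_G = alpha_G,
              beta_G = beta_G, mu_betaX = mu_betaX, mu_gammaX = mu_gammaX,
              mu_gammaZ = mu_gammaZ, tau2 = tau2,
              effect_corr = effect_corr,
              interaction_mean = interaction_mean,
              interaction_sd = interaction_sd,
              genetic_effect_sd = genetic_effect_sd,
              confounder_sd = confounder_sd,
              sigma_x = sigma_x, sigma_z = sigma_z, sigma_y = sigma_y,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n < 10) stop("n must be at least 10", call. = FALSE)
  if (cfg$maf <= 0 || cfg$maf >= 0.5) {
    stop("maf must lie strictly between 0 and 0.5", call. = FALSE)
  }
  if (cfg$tau2 < 0) stop("tau2 must be nonnegative", call. = FALSE)
  if (abs(cfg$effect_corr) >= 1) {
    stop("effect_corr must lie strictly between -1 and 1", call. = FALSE)
  }
  for (nm in c("interaction_sd", "genetic_effect_sd", "confounder_sd",
               "sigma_x", "sigma_z", "sigma_y")) {
    if (cfg[[nm]] < 0) stop(nm, " must be nonnegative", call. = FALSE)
  }
  invisible(cfg)
}

# trivariate normal effects with equicorrelation, via Cholesky
draw_effects <- function(n, means, tau2, rho) {
  if (tau2 == 0) {
    return(matrix(means, n, 3, byrow = TRUE,
                  dimnames = list(NULL, c("beta_x", "gamma_x", "gamma_z"))))
  }
  R <- matrix(rho, 3, 3); diag(R) <- 1
  L <- chol(R * tau2)
  E <- matrix(rnorm(3 * n), n, 3) %*% L
  E <- sweep(E, 2, means, `+`)
  colnames(E) <- c("beta_x", "gamma_x", "gamma_z")
  E
}

#' Simulate a dataset from the network-MR generating model
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed` (if both are `NULL`
#'   the current RNG state is used).
#' @param x_intervention a diagnostic do-operator: a constant added
#'   exogenously to every individual's exposure after its structural
#'   equation is evaluated, propagated to the mediator and outcome.
#'   Contrasting mean outcomes at `x_intervention = 1` vs `0` under a
#'   common seed measures the average interventional total effect.
#' @return a `sim_dataset`: an [iv_dataset()] whose latent truth (the
#'   three confounders and the per-individual effect coefficients) is
#'   available via [sim_truth()].
#' @examples
#' d <- simulate_dataset(sim_config(n = 1000, seed = 7))
#' head(sim_truth(d))
#' @export
simulate_dataset <- function(config = sim_config(), seed = config$seed,
                             x_intervention = 0) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  g_x <- rbinom(n, 2, config$maf)
  g_z <- rbinom(n, 2, config$maf)
  u_xz <- rnorm(n, 0, config$confounder_sd)
  u_xy <- rnorm(n, 0, config$confounder_sd)
  u_zy <- rnorm(n, 0, config$confounder_sd)
  eff <- draw_effects(n, c(config$mu_betaX, config$mu_gammaX,
                           config$mu_gammaZ),
                      config$tau2, config$effect_corr)
  alpha_i <- if (config$genetic_effect_sd > 0) {
    rnorm(n, config$alpha_G, config$genetic_effect_sd)
  } else rep(config$alpha_G, n)
  beta_g_i <- if (config$genetic_effect_sd > 0) {
    rnorm(n, config$beta_G, config$genetic_effect_sd)
  } else rep(config$beta_G, n)
  delta_i <- if (config$interaction_sd > 0 || config$interaction_mean != 0) {
    rnorm(n, config$interaction_mean, config$interaction_sd)
  } else rep(0, n)

  x <- alpha_i * g_x + u_xz + u_xy + rnorm(n, 0, config$sigma_x) +
    x_intervention
  z <- beta_g_i * g_z + eff[, "beta_x"] * x + u_xz + u_zy +
    rnorm(n, 0, config$sigma_z)
  y <- eff[, "gamma_x"] * x + eff[, "gamma_z"] * z + delta_i * x * z +
    u_xy + u_zy + rnorm(n, 0, config$sigma_y)

  out <- iv_dataset(data.frame(g_x = g_x, g_z = g_z, x = x, z = z, y = y),
                    validate = FALSE)
  attr(out, "truth") <- data.frame(u_xz = u_xz, u_xy = u_xy, u_zy = u_zy,
                                   beta_x_i = eff[, "beta_x"],
                                   gamma_x_i = eff[, "gamma_x"],
                                   gamma_z_i = eff[, "gamma_z"],
                                   delta_i = delta_i)
  attr(out, "config") <- config
  class(out) <- c("sim_dataset", class(out))
  out
}

#' Latent truth of a simulated dataset
#'
#' @param dataset a `sim_dataset` from [simulate_dataset()].
#' @return data.frame with the three confounders and the per-individual
#'   effect coefficients.
#' @export
sim_truth <- function(dataset) {
  tr <- attr(dataset, "truth")
  if (is.null(tr)) stop("dataset carries no latent truth", call. = FALSE)
  tr
}

#' The twelve reference simulation scenarios
#'
#' The cross of `mu_betaX` in (1, -1), `mu_gammaZ` in (1, -1) and `tau2`
#' in (0, 0.2^2, 0.4^2), with `mu_gammaX = 1` throughout and `beta_G`
#' switched with the sign of `mu_betaX` (0.5 / 0.36). Ordering is
#' deterministic: the four sign pairs in the order (1,1), (1,-1), (-1,1),
#' (-1,-1), each with ascending `tau2`.
#'
#' @param n individuals per dataset (default 5000).
#' @param ... further arguments passed to [sim_config()] (not the
#'   scenario-defining ones).
#' @return list of 12 [sim_config()] objects, named
#'   `"bX<mu_betaX>_gZ<mu_gammaZ>_tau2<tau2>"`.
#' @export
scenario_grid <- function(n = 5000, ...) {
  pairs <- list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  taus <- c(0, 0.2^2, 0.4^2)
  out <- list()
  for (pr in pairs) {
    for (t2 in taus) {
      cfg <- sim_config(n = n, mu_betaX = pr[1], mu_gammaZ = pr[2],
                        mu_gammaX = 1, tau2 = t2, ...)
      out[[sprintf("bX%g_gZ%g_tau2%g", pr[1], pr[2], t2)]] <- cfg
    }
  }
  out
}
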