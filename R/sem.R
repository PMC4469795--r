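sem_vars <- c("g_x", "g_z", "x", "z", "y")
sem_path_names <- c("gx_x", "gz_z", "x_z", "x_y", "z_y")

#' Define the five-variable instrumental path model
#'
#' The model over the ordered variables (G_X, G_Z, X, Z, Y) has five free
#' directed paths (G_X -> X, G_Z -> Z, X -> Z, X -> Y, Z -> Y); the paths
#' G_X -> Z, G_X -> Y, G_Z -> X and G_Z -> Y are structurally zero -- this
#' exclusion set is the identifying instrumental-variable assumption.
#' Unmeasured confounding between exposure, mediator and outcome is
#' represented by a freely correlated 3x3 covariance matrix of the error
#' terms of X, Z and Y.
#'
#' @param correlated_errors allow the error terms of X, Z and Y to
#'   covary (default `TRUE`, the confounded model). With `FALSE` the
#'   error covariance is diagonal and the maximum-likelihood fit reduces
#'   to equation-by-equation least squares -- appropriate only when the
#'   structural equations are unconfounded.
#' @param instrument_covariance `"free"` (default; robust to correlation
#'   between the two instruments) or `"zero"`.
#' @return list of class `path_model`.
#' @export
path_model <- function(correlated_errors = TRUE,
                       instrument_covariance = c("free", "zero")) {
  structure(list(variables = sem_vars,
                 free_paths = sem_path_names,
                 correlated_errors = isTRUE(correlated_errors),
                 instrument_covariance = match.arg(instrument_covariance)),
            class = "path_model")
}

path_B <- function(paths) {
  B <- matrix(0, 5, 5, dimnames = list(sem_vars, sem_vars))
  B[3, 1] <- paths[["gx_x"]]
  B[4, 2] <- paths[["gz_z"]]
  B[4, 3] <- paths[["x_z"]]
  B[5, 3] <- paths[["x_y"]]
  B[5, 4] <- paths[["z_y"]]
  B
}

#' Model-implied moments of the path model
#'
#' Computes the mean vector and covariance matrix of (G_X, G_Z, X, Z, Y)
#' implied by path coefficients and exogenous/error (co)variances, using
#' the standard linear-SEM form `Sigma = (I - B)^-1 Psi (I - B)^-T`. The
#' coefficient matrix B is strictly lower triangular in the variable
#' order, so the inverse always exists.
#'
#' @param model a [path_model()].
#' @param parameters list with elements `paths` (named vector over
#'   `gx_x, gz_z, x_z, x_y, z_y`), `psi_g` (2x2 covariance of the
#'   instruments), `psi_err` (3x3 error covariance of X, Z, Y; must be
#'   positive definite), and optionally `g_means` (length 2) and
#'   `intercepts` (length 3, for X, Z, Y).
#' @return list with `mean` (length 5) and `cov` (5x5), named by
#'   variable.
#' @export
implied_moments <- function(model, parameters) {
  stopifnot(inherits(model, "path_model"))
  paths <- parameters$paths
  psi_g <- parameters$psi_g
  psi_err <- parameters$psi_err
  stopifnot(length(paths) == 5, all(dim(psi_g) == 2), all(dim(psi_err) == 3))
  if (!model$correlated_errors &&
      any(abs(psi_err[lower.tri(psi_err)]) > 0)) {
    stop("model has uncorrelated errors but psi_err is not diagonal",
         call. = FALSE)
  }
  ev <- eigen(psi_err, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("psi_err is not positive definite", call. = FALSE)
  }
  Psi <- matrix(0, 5, 5, dimnames = list(sem_vars, sem_vars))
  Psi[1:2, 1:2] <- psi_g
  Psi[3:5, 3:5] <- psi_err
  IB <- diag(5) - path_B(paths)
  A <- solve(IB)
  Sigma <- A %*% Psi %*% t(A)
  dimnames(Sigma) <- list(sem_vars, sem_vars)
  nu <- c(parameters$g_means %||% c(0, 0),
          parameters$intercepts %||% c(0, 0, 0))
  mu <- drop(A %*% nu)
  names(mu) <- sem_vars
  list(mean = mu, cov = Sigma)
}

# ML discrepancy profile over the five paths: for fixed B the optimal
# block-diagonal Psi is the corresponding block of M = (I-B) S (I-B)^T,
# so the concentrated objective is the sum of block log-determinants
# (diagonal blocks replaced by log of diagonal entries when a block is
# restricted to be diagonal).
profile_objective <- function(S, model) {
  I5 <- diag(5)
  function(p) {
    IB <- I5 - path_B(setNames(p, sem_path_names))
    M <- IB %*% S %*% t(IB)
    Mg <- M[1:2, 1:2]
    Me <- M[3:5, 3:5]
    lg <- if (model$instrument_covariance == "free") {
      d <- determinant(Mg)
      if (d$sign <= 0) return(1e10)
      as.numeric(d$modulus)
    } else {
      if (any(diag(Mg) <= 0)) return(1e10)
      sum(log(diag(Mg)))
    }
    le <- if (model$correlated_errors) {
      d <- determinant(Me)
      if (d$sign <= 0) return(1e10)
      as.numeric(d$modulus)
    } else {
      if (any(diag(Me) <= 0)) return(1e10)
      sum(log(diag(Me)))
    }
    lg + le
  }
}

# natural covariance-structure parameter vector <-> matrices
sem_theta_names <- function(model) {
  c(sem_path_names,
    if (model$correlated_errors) {
      c("psi_xx", "psi_zx", "psi_zz", "psi_yx", "psi_yz", "psi_yy")
    } else c("psi_xx", "psi_zz", "psi_yy"),
    if (model$instrument_covariance == "free") {
      c("phi_gxgx", "phi_gzgx", "phi_gzgz")
    } else c("phi_gxgx", "phi_gzgz"))
}

sem_theta_pack <- function(paths, psi_err, psi_g, model) {
  th <- c(paths,
          if (model$correlated_errors) {
            psi_err[lower.tri(psi_err, diag = TRUE)]
          } else diag(psi_err),
          if (model$instrument_covariance == "free") {
            psi_g[lower.tri(psi_g, diag = TRUE)]
          } else diag(psi_g))
  setNames(th, sem_theta_names(model))
}

sem_theta_unpack <- function(theta, model) {
  paths <- setNames(theta[1:5], sem_path_names)
  i <- 5
  psi_err <- matrix(0, 3, 3)
  if (model$correlated_errors) {
    psi_err[lower.tri(psi_err, diag = TRUE)] <- theta[i + 1:6]
    psi_err <- psi_err + t(psi_err) - diag(diag(psi_err))
    i <- i + 6
  } else {
    diag(psi_err) <- theta[i + 1:3]
    i <- i + 3
  }
  psi_g <- matrix(0, 2, 2)
  if (model$instrument_covariance == "free") {
    psi_g[lower.tri(psi_g, diag = TRUE)] <- theta[i + 1:3]
    psi_g <- psi_g + t(psi_g) - diag(diag(psi_g))
  } else {
    diag(psi_g) <- theta[i + 1:2]
  }
  list(paths = paths, psi_err = psi_err, psi_g = psi_g)
}

# -n/2 (log det Sigma + tr(S Sigma^-1)) as a function of the natural
# covariance-structure parameters; used for the observed-information vcov
sem_negloglik_factory <- function(S, n, model) {
  I5 <- diag(5)
  function(theta) {
    pr <- sem_theta_unpack(theta, model)
    Psi <- matrix(0, 5, 5)
    Psi[1:2, 1:2] <- pr$psi_g
    Psi[3:5, 3:5] <- pr$psi_err
    IB <- I5 - path_B(pr$paths)
    A <- solve(IB)
    Sigma <- A %*% Psi %*% t(A)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ld <- 2 * sum(log(diag(ch)))
    tr <- sum(diag(chol2inv(ch) %*% S))
    (n / 2) * (ld + tr)
  }
}

#' Fit the path model by Gaussian maximum likelihood
#'
#' Maximizes the multivariate-normal log-likelihood of the observed five
#' variables under the structure of [path_model()]. The mean structure is
#' saturated (one intercept per variable), so the fit operates on the
#' sample covariance matrix; on complete data this coincides with full
#' information maximum likelihood. The five path coefficients are
#' optimized by quasi-Newton descent on the concentrated discrepancy (the
#' exogenous and error covariance blocks have closed-form optima given
#' the paths), with start values from sequential least-squares
#' regressions. The parameter covariance matrix is the inverse observed
#' information of the covariance-structure likelihood.
#'
#' Genotypic instruments are discrete and hence non-normal; the point
#' estimates remain consistent (pseudo-ML) and this is accepted.
#'
#' @param dataset an [iv_dataset()].
#' @param model a [path_model()].
#' @return object of class `path_model_fit` with elements `paths`
#'   (named coefficient vector), `psi_err`, `psi_g`, `intercepts`,
#'   `coefficients` (all covariance-structure parameters), `loglik`,
#'   `vcov`, `converged`, `n_iterations`, `gradient_norm`,
#'   `lr_saturated`, `df`, `n`, `model`.
#' @export
fit_sem <- function(dataset, model = path_model()) {
  stopifnot(inherits(model, "path_model"))
  m <- as.matrix(as.data.frame(dataset)[, sem_vars])
  n <- nrow(m)
  S <- cov(m) * (n - 1) / n
  if (n <= 15) stop("too few observations to fit the path model", call. = FALSE)
  det_S <- determinant(S)
  if (det_S$sign <= 0) {
    stop("sample covariance of the five variables is singular", call. = FALSE)
  }
  mbar <- colMeans(m)

  # start values from sequential OLS
  st_a <- ols_slope(m[, "x"], m[, "g_x"])$slope
  s2 <- stats::lm.fit(cbind(1, m[, "g_z"], m[, "x"]), m[, "z"])
  s3 <- stats::lm.fit(cbind(1, m[, "x"], m[, "z"]), m[, "y"])
  start <- c(st_a, s2$coefficients[2], s2$coefficients[3],
             s3$coefficients[2], s3$coefficients[3])

  obj <- profile_objective(S, model)
  opt <- optim(start, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  paths <- setNames(opt$par, sem_path_names)

  IB <- diag(5) - path_B(paths)
  M <- IB %*% S %*% t(IB)
  psi_g <- M[1:2, 1:2]
  if (model$instrument_covariance == "zero") psi_g <- diag(diag(psi_g))
  psi_err <- M[3:5, 3:5]
  if (!model$correlated_errors) psi_err <- diag(diag(psi_err))
  dimnames(psi_g) <- list(sem_vars[1:2], sem_vars[1:2])
  dimnames(psi_err) <- list(sem_vars[3:5], sem_vars[3:5])
  if (any(diag(psi_err) < 1e-8 * diag(S)[3:5])) {
    warning("error variance at the boundary (Heywood-type solution)",
            call. = FALSE)
  }

  theta <- sem_theta_pack(paths, psi_err, psi_g, model)
  negll <- sem_negloglik_factory(S, n, model)

  # numeric gradient of the profile objective at the optimum
  gr <- vapply(seq_along(opt$par), function(j) {
    h <- 1e-6 * max(1, abs(opt$par[j]))
    e <- replace(numeric(5), j, h)
    (obj(opt$par + e) - obj(opt$par - e)) / (2 * h)
  }, numeric(1))
  gradient_norm <- sqrt(sum(gr^2))
  converged <- opt$convergence == 0 && gradient_norm < 1e-4

  H <- optimHess(theta, negll)
  vc <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(vc)) {
    warning("observed information is singular; no parameter covariance",
            call. = FALSE)
    vc <- matrix(NA_real_, length(theta), length(theta))
  }
  dimnames(vc) <- list(names(theta), names(theta))

  f_min <- obj(opt$par) - as.numeric(det_S$modulus)
  loglik <- -(n / 2) * (5 * log(2 * pi) + as.numeric(det_S$modulus) + f_min + 5)
  lr_saturated <- n * f_min
  df <- 15L - length(theta)
  nu <- drop(IB %*% mbar)

  if (!converged) {
    warning("path-model fit did not converge (gradient norm ",
            format(gradient_norm, digits = 3), ")", call. = FALSE)
  }

  structure(list(paths = paths, psi_err = psi_err, psi_g = psi_g,
                 intercepts = setNames(nu, sem_vars),
                 coefficients = theta, loglik = loglik, vcov = vc,
                 converged = converged,
                 n_iterations = unname(opt$counts["function"]),
                 gradient_norm = gradient_norm,
                 lr_saturated = lr_saturated, df = df, n = n,
                 model = model),
            class = "path_model_fit")
}

#' @export
print.path_model_fit <- function(x, digits = 3, ...) {
  cat("Path model fit (Gaussian ML), n =", x$n, "\n")
  cat("  paths:\n")
  lbl <- c(gx_x = "g_x -> x", gz_z = "g_z -> z", x_z = "x -> z",
           x_y = "x -> y", z_y = "z -> y")
  for (nm in names(x$paths)) {
    cat(sprintf("    %-9s %8.4f (SE %.4f)\n", lbl[[nm]], x$paths[[nm]],
                sqrt(x$vcov[nm, nm])))
  }
  cat(sprintf("  logLik %.2f | LR vs saturated %.3f on %d df | %s\n",
              x$loglik, x$lr_saturated, x$df,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Direct and indirect effects from a fitted path model
#'
#' The direct effect is the X -> Y path coefficient; the indirect effect
#' is the product of the X -> Z and Z -> Y coefficients, with a
#' delta-method standard error
#' `e^2 var(c) + c^2 var(e) + 2 c e cov(c, e)` (c = X -> Z, e = Z -> Y);
#' the total effect is their sum, also with a delta-method SE.
#'
#' @param fit a [fit_sem()] result.
#' @param level confidence level.
#' @return a [mediation_result()] with method `"sem"`.
#' @export
sem_effects <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "path_model_fit"))
  if (!fit$converged) {
    warning("effects computed from an unconverged fit", call. = FALSE)
  }
  cc <- fit$paths[["x_z"]]
  dd <- fit$paths[["x_y"]]
  ee <- fit$paths[["z_y"]]
  V <- fit$vcov[c("x_z", "x_y", "z_y"), c("x_z", "x_y", "z_y")]
  if (cc == 0 && ee == 0) {
    warning("delta method degenerates at x_z = z_y = 0; ",
            "indirect-effect SE is not trustworthy", call. = FALSE)
  }
  se_direct <- sqrt(V["x_y", "x_y"])
  g_ind <- c(ee, 0, cc)                      # d(c e)/d(c, d, e)
  se_indirect <- sqrt(drop(g_ind %*% V %*% g_ind))
  g_tot <- c(ee, 1, cc)                      # d(d + c e)/d(c, d, e)
  se_total <- sqrt(drop(g_tot %*% V %*% g_tot))
  mediation_result(
    total = causal_estimate(dd + cc * ee, se_total, "sem", level),
    direct = causal_estimate(dd, se_direct, "sem", level),
    indirect = causal_estimate(cc * ee, se_indirect, "sem", level),
    method = "sem",
    info = list(paths = fit$paths, loglik = fit$loglik,
                lr_saturated = fit$lr_saturated, df = fit$df))
}
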