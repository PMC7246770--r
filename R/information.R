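#' Marginal-likelihood information matrix and standard errors
#'
#' Computes the covariance of the parameter estimates as the inverse of the
#' negative numerical Hessian of the observed-data log-likelihood at
#' `psi_hat`.  Differentiation is done in unconstrained coordinates
#' (`atanh(g)`, `log(v)`, `log(theta)`, raw basis coefficients) with central
#' finite differences of step `1e-4 * (1 + |parameter|)`; the covariance is
#' mapped back to the natural scale by the delta method.  A non-invertible
#' Hessian falls back to a pseudo-inverse with a warning.
#'
#' @param cube a [panel_cube()].
#' @param spec an [stfm_spec()].
#' @param psi_hat a [parameter_set()] near the optimum.
#' @return list with `Sigma` (natural scale), `Sigma_trans` (unconstrained
#'   scale), `se`, `se_trans` (named), `hessian`, and `loglik_fn` (the
#'   marginal log-likelihood as a function of the unconstrained vector).
#' @export
observed_information <- function(cube, spec, psi_hat) {
  sys <- assemble_system(cube, spec, psi_hat)
  template <- psi_hat

  loglik_fn <- function(x) {
    psi <- vector_to_psi(x, template, transformed = TRUE)
    s <- update_system(sys, psi, refresh_P0 = TRUE)
    kalman_run(s, smooth = FALSE, moments = FALSE)$loglik
  }

  x0 <- psi_to_vector(psi_hat, transformed = TRUE)
  H <- numerical_hessian(loglik_fn, x0)
  nm <- psi_names(psi_hat)
  dimnames(H) <- list(nm, nm)

  negH <- -H
  Sigma_trans <- tryCatch(solve(negH), error = function(e) NULL)
  if (is.null(Sigma_trans) || any(!is.finite(Sigma_trans)) ||
      any(diag(Sigma_trans) < 0)) {
    warning("information matrix not positive definite; using pseudo-inverse")
    Sigma_trans <- pseudo_solve(negH)
  }
  dimnames(Sigma_trans) <- list(nm, nm)

  # delta method back to the natural scale
  p <- length(psi_hat$g)
  n_ce <- length(psi_hat$c_eps); n_cb <- length(psi_hat$c_beta)
  jac <- c(rep(1, n_ce + n_cb),
           1 - psi_hat$g^2,   # d tanh(u)/du
           psi_hat$v,         # d exp(u)/du
           psi_hat$theta)
  Sigma <- Sigma_trans * tcrossprod(jac)
  dimnames(Sigma) <- list(nm, nm)

  list(Sigma = Sigma, Sigma_trans = Sigma_trans,
       se = setNames(sqrt(pmax(diag(Sigma), 0)), nm),
       se_trans = setNames(sqrt(pmax(diag(Sigma_trans), 0)), nm),
       hessian = H, loglik_fn = loglik_fn)
}

# central-difference Hessian with per-coordinate steps
numerical_hessian <- function(f, x, rel_step = 1e-4) {
  d <- length(x)
  h <- rel_step * (1 + abs(x))
  H <- matrix(NA_real_, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1L) for (j in seq_len(i - 1L)) {
      ej <- replace(numeric(d), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' Coefficient covariance block for one effect curve
#'
#' Extracts the `p_beta x p_beta` covariance of the basis coefficients of a
#' named effect from a fit's parameter covariance (basis coefficients are
#' unconstrained, so natural and transformed scales agree).
#'
#' @param fit an [fit_em()] result with standard errors computed.
#' @param effect effect name (e.g. `"(Intercept)"` or a covariate).
#' @return list with `coefs` and `Sigma`.
#' @export
effect_block <- function(fit, effect) {
  if (is.null(fit$Sigma)) {
    stop("fit has no parameter covariance; rerun with compute_se = TRUE ",
         "or call observed_information()")
  }
  enames <- colnames(fit$psi_hat$c_beta)
  j <- match(effect, enames)
  if (is.na(j)) stop("unknown effect: ", effect)
  idx <- length(fit$psi_hat$c_eps) +
    (j - 1L) * nrow(fit$psi_hat$c_beta) + seq_len(nrow(fit$psi_hat$c_beta))
  list(coefs = fit$psi_hat$c_beta[, j], Sigma = fit$Sigma[idx, idx])
}
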