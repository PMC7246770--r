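#' Assemble the daily state-space system
#'
#' Rewrites the model in its per-day state-space form.  The day-`t`
#' observation vector stacks stations station-major, hours innermost; the
#' latent state stacks the `p_z` components component-major (each component's
#' `n` station values contiguous) so the transition matrix is the Kronecker
#' product of the diagonal transition with the station identity and the
#' innovation covariance is block-diagonal across components.
#'
#' Cells with a missing response, or a missing covariate where the response
#' is observed, are treated as missing observations (their rows are dropped
#' by exact Gaussian marginalization inside the filter).
#'
#' The initial state is `N(0, S0)` with `S0` the stationary covariance of the
#' latent process at `psi` when all `|g| < 1`, and a diffuse-like `1e7 * I`
#' otherwise.
#'
#' @param cube a [panel_cube()].
#' @param spec an [stfm_spec()]; its covariates must exist in `cube`.
#' @param psi a [parameter_set()] conforming to `spec`.
#' @return object of class `statespace_system` holding the stacked
#'   observation matrix, design matrices, error variances, transition and
#'   innovation covariance, and the initial state law.
#' @export
assemble_system <- function(cube, spec, psi) {
  stopifnot(inherits(cube, "panel_cube"), inherits(spec, "stfm_spec"),
            inherits(psi, "parameter_set"))
  d3 <- dim(cube$y); n <- d3[1]; T_ <- d3[2]; q <- d3[3]
  hours <- cube$hours
  bad <- setdiff(spec$covariates, cube$covariate_names)
  if (length(bad)) stop("covariates not in cube: ", paste(bad, collapse = ", "))
  b <- n_effects(spec)
  stopifnot(nrow(psi$c_beta) == spec$p_beta, ncol(psi$c_beta) == b,
            length(psi$c_eps) == spec$p_eps, length(psi$g) == spec$p_z)

  basis_beta <- fourier_basis(spec$p_beta, period = q)
  basis_eps <- fourier_basis(spec$p_eps, period = q)

  # stacked observation matrix (nq x T), row (i-1)q + h; NA = missing
  ymat <- matrix(aperm(cube$y, c(3, 1, 2)), n * q, T_)
  mmat <- matrix(aperm(cube$missing, c(3, 1, 2)), n * q, T_)
  ymat[mmat] <- NA_real_

  # full fixed-effects design, rows ordered (t-1)nq + (i-1)q + h,
  # columns effect-major then basis-function
  Phi_b <- eval_basis(basis_beta, hours)
  Phi_rep <- Phi_b[rep(seq_len(q), n * T_), , drop = FALSE]
  Xbig <- matrix(0, n * q * T_, b * spec$p_beta)
  enames <- effect_names(spec)
  for (j in seq_len(b)) {
    ev <- if (spec$intercept && j == 1L) {
      rep(1, n * q * T_)
    } else {
      jc <- match(enames[j], cube$covariate_names)
      as.vector(aperm(cube$X[, , , jc, drop = FALSE], c(3, 1, 2, 4)))
    }
    Xbig[, (j - 1L) * spec$p_beta + seq_len(spec$p_beta)] <- ev * Phi_rep
  }

  rdiag <- rep(sigma_eps_curve(psi$c_eps, basis_eps, hours), times = n)

  p <- spec$p_z
  if (p > 0L) {
    basis_z <- fourier_basis(p, period = q, allow_even = TRUE)
    Phi_zq <- eval_basis(basis_z, hours)
    Z <- matrix(0, n * q, n * p)
    row_i <- rep(seq_len(n), each = q)
    row_h <- rep(seq_len(q), times = n)
    for (j in seq_len(p)) {
      Z[cbind(seq_len(n * q), (j - 1L) * n + row_i)] <- Phi_zq[row_h, j]
    }
    D <- distance_matrix_km(cube$locations)
    blocks <- gamma_blocks(D, psi$v, psi$theta)
    Q <- block_diag(blocks)
    P0 <- if (all(abs(psi$g) < 1)) {
      block_diag(stationary_state_cov(psi$g, blocks))
    } else {
      warning("nonstationary 'g'; using diffuse-like initial covariance")
      diag(1e7, n * p)
    }
    gdiag <- rep(psi$g, each = n)
  } else {
    basis_z <- NULL; Phi_zq <- matrix(0, q, 0)
    Z <- matrix(0, n * q, 0); D <- distance_matrix_km(cube$locations)
    Q <- matrix(0, 0, 0); P0 <- matrix(0, 0, 0); gdiag <- numeric()
  }

  structure(
    list(y = ymat, Z = Z, Xbig = Xbig,
         d = matrix(drop(Xbig %*% as.numeric(psi$c_beta)), n * q, T_),
         rdiag = rdiag, gdiag = gdiag, Q = Q, P0 = P0,
         a0 = numeric(n * p), n = n, T = T_, q = q, p_z = p, b = b,
         hours = hours, D = D,
         basis_beta = basis_beta, basis_eps = basis_eps, basis_z = basis_z,
         Phi_zq = Phi_zq, spec = spec, psi = psi,
         locations = cube$locations),
    class = "statespace_system"
  )
}

#' @export
print.statespace_system <- function(x, ...) {
  cat(sprintf(
    "statespace_system: obs dim %d x %d days, state dim %d (n=%d, p_z=%d)\n",
    nrow(x$y), x$T, length(x$gdiag), x$n, x$p_z))
  invisible(x)
}

# refresh the psi-dependent pieces of a system without touching the frozen
# initial state law (used inside the EM loop)
update_system <- function(sys, psi, refresh_P0 = FALSE) {
  sys$psi <- psi
  sys$d <- matrix(drop(sys$Xbig %*% as.numeric(psi$c_beta)),
                  nrow(sys$y), sys$T)
  sys$rdiag <- rep(sigma_eps_curve(psi$c_eps, sys$basis_eps, sys$hours),
                   times = sys$n)
  if (sys$p_z > 0L) {
    blocks <- gamma_blocks(sys$D, psi$v, psi$theta)
    sys$Q <- block_diag(blocks)
    sys$gdiag <- rep(psi$g, each = sys$n)
    if (refresh_P0 && all(abs(psi$g) < 1)) {
      sys$P0 <- block_diag(stationary_state_cov(psi$g, blocks))
    }
  }
  sys
}

kalman_run <- function(sys, smooth, moments = TRUE) {
  if (sys$p_z == 0L) {
    # no latent state: independent heteroskedastic Gaussian observations
    obs <- !is.na(sys$y)
    r <- rep(sys$rdiag, sys$T)[obs]
    e <- (sys$y - sys$d)[obs]
    ll <- -0.5 * sum(log(2 * pi * r) + e^2 / r)
    m <- 0L
    zeros <- matrix(0, 0, sys$T + 1L)
    cube0 <- array(0, c(0, 0, sys$T + 1L))
    out <- list(loglik = ll, a_filt = zeros, P_filt = cube0,
                a_pred = zeros[, seq_len(sys$T), drop = FALSE],
                P_pred = array(0, c(0, 0, sys$T)))
    if (smooth) {
      out$a_sm <- zeros; out$P_sm <- cube0
      out$P_lag <- array(0, c(0, 0, sys$T))
    }
    return(out)
  }
  .kalman_core(sys$y, sys$d, sys$rdiag, sys$Phi_zq, sys$gdiag, sys$Q,
               sys$a0, sys$P0, sys$n, smooth, moments)
}

#' Kalman filter for an assembled system
#'
#' Runs the exact Gaussian filter over days, processing the within-day
#' observations sequentially (the measurement-error covariance is diagonal)
#' and skipping missing entries, which is exact marginalization.  The
#' returned log-likelihood sums the per-observation predictive log-densities
#' over observed entries only; with every observation missing it is 0 and
#' the state moments follow the prior recursion.
#'
#' @param sys a [assemble_system()] result.
#' @return object of class `kalman_output` with `loglik`, filtered state
#'   means `a_filt` (state x (T+1), day 0 = the initial law) and covariances
#'   `P_filt`, and one-day-ahead predicted moments `a_pred`, `P_pred`.
#' @export
kalman_filter <- function(sys) {
  out <- kalman_run(sys, smooth = FALSE)
  structure(out, class = "kalman_output")
}

#' Kalman fixed-interval smoother
#'
#' Runs the filter and the backward Rauch-Tung-Striebel recursion, returning
#' in addition the smoothed moments `a_sm`, `P_sm` (day 0..T) and the
#' lag-one cross-covariances `P_lag` (slice `t` holds
#' `Cov(z_t, z_{t-1} | Y)`), which the EM algorithm requires.
#'
#' @param sys a [assemble_system()] result.
#' @return object of class `kalman_output`.
#' @export
kalman_smoother <- function(sys) {
  out <- kalman_run(sys, smooth = TRUE)
  structure(out, class = "kalman_output")
}

#' @export
print.kalman_output <- function(x, ...) {
  cat(sprintf("kalman_output: loglik %.4f, state dim %d, %d day(s)%s\n",
              x$loglik, nrow(x$a_filt), ncol(x$a_pred),
              if (!is.null(x$a_sm)) ", smoothed" else ""))
  invisible(x)
}
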