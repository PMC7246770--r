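#' EM configuration
#'
#' @param tol relative convergence tolerance for the two stopping rules (the
#'   relative change in the parameter vector, or the relative change in the
#'   observed-data log-likelihood; the algorithm stops when either falls
#'   below `tol`).
#' @param max_iter maximum number of EM iterations.
#' @param seed optional seed for any stochastic initialization.
#' @param psi0 optional [parameter_set()] starting value; default is a
#'   moment-based initialization from the data.
#' @param compute_se compute the marginal-likelihood information matrix after
#'   convergence?
#' @param verbose print per-iteration log-likelihoods?
#' @return object of class `em_config`.
#' @export
em_config <- function(tol = 1e-3, max_iter = 200L, seed = NULL, psi0 = NULL,
                      compute_se = FALSE, verbose = FALSE) {
  stopifnot(tol > 0, max_iter >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter), seed = seed,
                 psi0 = psi0, compute_se = isTRUE(compute_se),
                 verbose = isTRUE(verbose)),
            class = "em_config")
}

#' Moment-based starting values
#'
#' Hour-wise ordinary least squares of the response on the effects gives
#' per-hour coefficient vectors that are projected on the effect basis for
#' `c_beta`; the log of the per-hour residual variances is projected on the
#' error basis for `c_eps`; transition diagonals start at 0.5, ranges at the
#' median inter-station distance, and the residual variance is split equally
#' across latent components for `v`.
#'
#' @param cube a [panel_cube()].
#' @param spec an [stfm_spec()].
#' @return a [parameter_set()].
#' @export
init_psi <- function(cube, spec) {
  d3 <- dim(cube$y); n <- d3[1]; T_ <- d3[2]; q <- d3[3]
  b <- n_effects(spec)
  enames <- effect_names(spec)
  basis_beta <- fourier_basis(spec$p_beta, period = q)
  basis_eps <- fourier_basis(spec$p_eps, period = q)

  beta_h <- matrix(0, q, b)
  res_var <- numeric(q)
  for (h in seq_len(q)) {
    yv <- as.vector(cube$y[, , h])
    Xh <- matrix(1, n * T_, b)
    for (j in seq_len(b)) {
      if (!(spec$intercept && j == 1L)) {
        jc <- match(enames[j], cube$covariate_names)
        Xh[, j] <- as.vector(cube$X[, , h, jc])
      }
    }
    keep <- !as.vector(cube$missing[, , h]) & is.finite(yv) &
      apply(is.finite(Xh), 1, all)
    if (sum(keep) > b + 1L) {
      fit <- stats::lm.fit(Xh[keep, , drop = FALSE], yv[keep])
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      beta_h[h, ] <- cf
      res_var[h] <- mean(fit$residuals^2)
    } else {
      res_var[h] <- stats::var(yv[keep]) %||% 1
    }
  }
  res_var[!is.finite(res_var) | res_var <= 0] <- mean(res_var[res_var > 0]) %||% 1

  hours <- cube$hours
  c_beta <- vapply(seq_len(b), function(j)
    fit_basis_ls(beta_h[, j], hours, basis_beta)$coefs,
    numeric(spec$p_beta))
  c_beta <- matrix(c_beta, spec$p_beta, b, dimnames = list(NULL, enames))
  c_eps <- fit_basis_ls(log(res_var), hours, basis_eps)$coefs

  p <- spec$p_z
  if (p > 0L) {
    D <- distance_matrix_km(cube$locations)
    theta0 <- stats::median(D[upper.tri(D)])
    if (!is.finite(theta0) || theta0 <= 0) theta0 <- 10
    v0 <- mean(res_var) / p
    # most residual structure belongs to the latent field, not the noise:
    # start the noise curve below the raw residual variance
    c_eps[1] <- c_eps[1] - log(2)
    parameter_set(c_eps, c_beta, g = rep(0.5, p), v = rep(v0, p),
                  theta = rep(theta0, p))
  } else {
    parameter_set(c_eps, c_beta)
  }
}

#' E-step: smoothed moments and expected residuals
#'
#' Runs the Kalman smoother at the system's current parameters and returns
#' the expected sufficient statistics of the complete-data log-likelihood:
#' smoothed state means, the per-component summed second-moment matrices
#' (`A` over days 0..T-1, `B` the lag-one cross moments, `C` over days
#' 1..T), and the expected squared residual for every cell.  For an
#' unobserved cell the expected squared residual is the prediction variance
#' `phi(h)' P_t phi(h) + sigma_eps^2(h)`.
#'
#' @param sys an assembled [assemble_system()].
#' @return list with elements `loglik`, `zhat`, `A`, `B`, `C`, `resid2`,
#'   `qform`, `obs`.
#' @export
estep <- function(sys) {
  ks <- kalman_smoother(sys)
  n <- sys$n; T_ <- sys$T; q <- sys$q; p <- sys$p_z
  obs <- !is.na(sys$y)

  if (p == 0L) {
    resid2 <- (sys$y - sys$d)^2
    resid2[!obs] <- rep(sys$rdiag, T_)[!obs]
    return(list(loglik = ks$loglik, zhat = ks$a_sm,
                A = list(), B = list(), C = list(),
                resid2 = resid2, qform = matrix(0, nrow(sys$y), T_),
                obs = obs, kalman = ks))
  }

  zhat <- ks$a_sm                       # m x (T+1), day 0 first
  A <- B <- C <- vector("list", p)
  for (j in seq_len(p)) {
    idx <- (j - 1L) * n + seq_len(n)
    Aj <- Bj <- Cj <- matrix(0, n, n)
    for (t in seq_len(T_)) {
      z_prev <- zhat[idx, t]; z_cur <- zhat[idx, t + 1L]
      Aj <- Aj + ks$P_sm[idx, idx, t] + tcrossprod(z_prev)
      Cj <- Cj + ks$P_sm[idx, idx, t + 1L] + tcrossprod(z_cur)
      Bj <- Bj + ks$P_lag[idx, idx, t] + tcrossprod(z_cur, z_prev)
    }
    A[[j]] <- Aj; B[[j]] <- Bj; C[[j]] <- Cj
  }

  # quadratic form phi(h)' P_sm[station block] phi(h) per cell
  qform <- matrix(0, n * q, T_)
  Phi <- sys$Phi_zq
  for (t in seq_len(T_)) {
    Pt <- ks$P_sm[, , t + 1L]
    for (i in seq_len(n)) {
      idx <- (seq_len(p) - 1L) * n + i
      Psub <- Pt[idx, idx, drop = FALSE]
      qform[(i - 1L) * q + seq_len(q), t] <-
        rowSums((Phi %*% Psub) * Phi)
    }
  }

  fitted_lat <- sys$Z %*% zhat[, -1L, drop = FALSE]
  resid2 <- (sys$y - sys$d - fitted_lat)^2 + qform
  resid2[!obs] <- qform[!obs] + rep(sys$rdiag, T_)[!obs]

  list(loglik = ks$loglik, zhat = zhat, A = A, B = B, C = C,
       resid2 = resid2, qform = qform, obs = obs, kalman = ks)
}

# expected complete-data objective pieces used by the M-step guards ---------

# latent component j's contribution given (g, v, theta)
latent_obj_j <- function(g, v, theta, Aj, Bj, Cj, D, T_) {
  n <- nrow(Aj)
  Ct <- correlation_matrix(D, theta)
  ch <- tryCatch(chol(Ct), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  Minv <- chol2inv(ch)
  M <- Cj - g * Bj - g * t(Bj) + g^2 * Aj
  -0.5 * T_ * (n * log(v) + logdet) - 0.5 * sum(Minv * M) / v
}

# measurement-noise objective for the hour-aggregated statistics
eps_obj <- function(c_eps, Phi, n_h, m_h) {
  u <- drop(Phi %*% c_eps)
  -0.5 * sum(n_h * (u + m_h * exp(-u)))
}

#' M-step: closed-form and profiled parameter updates
#'
#' Conditional maximizations of the expected complete-data log-likelihood:
#' `c_beta` by weighted least squares against the latent-adjusted response
#' with weights `1/sigma_eps^2(h)`; `c_eps` by Newton iterations on the
#' (concave) expected objective, with step-halving and a projection fallback;
#' `g_j` by its trace-ratio closed form; `(v_j, theta_j)` by a bounded 1-D
#' search over `theta` with `v_j(theta)` profiled out in closed form.  Every
#' update is guarded never to decrease the expected objective, so the EM
#' log-likelihood trace is monotone.
#'
#' @param stats an [estep()] result.
#' @param sys the system the statistics were computed from.
#' @param theta_bounds search interval for the spatial range (km).
#' @return an updated [parameter_set()].
#' @export
mstep <- function(stats, sys, theta_bounds = c(1, 1e4)) {
  n <- sys$n; T_ <- sys$T; q <- sys$q; p <- sys$p_z
  psi <- sys$psi
  obs_vec <- as.vector(stats$obs)

  # --- c_beta: weighted least squares on the latent-adjusted response ------
  lat <- if (p > 0L) sys$Z %*% stats$zhat[, -1L, drop = FALSE] else 0
  target <- as.vector(sys$y - lat)[obs_vec]
  w <- rep(rep(1 / sys$rdiag, sys$T), 1)[obs_vec]
  Xo <- sys$Xbig[obs_vec, , drop = FALSE]
  Xw <- Xo * sqrt(w)
  XtWX <- crossprod(Xw)
  XtWy <- crossprod(Xo, w * target)
  c_beta_vec <- tryCatch(solve(XtWX, XtWy), error = function(e) {
    warning("singular fixed-effects design; using pseudo-inverse")
    pseudo_solve(XtWX) %*% XtWy
  })
  c_beta <- matrix(drop(c_beta_vec), nrow(psi$c_beta), ncol(psi$c_beta),
                   dimnames = dimnames(psi$c_beta))

  # --- c_eps: Newton on the hour-aggregated expected objective -------------
  # residuals recomputed at the new c_beta; the latent variance term rides
  # along unchanged (qform)
  dnew <- matrix(drop(sys$Xbig %*% drop(c_beta_vec)), nrow(sys$y), sys$T)
  e2 <- (sys$y - dnew - lat)^2 + stats$qform
  hour_of_row <- rep(rep(seq_len(q), sys$n), sys$T)
  e2o <- as.vector(e2)[obs_vec]
  ho <- hour_of_row[obs_vec]
  n_h <- tabulate(ho, nbins = q)
  m_h <- rep(0, q)
  m_h[n_h > 0] <- vapply(which(n_h > 0), function(h) mean(e2o[ho == h]),
                         numeric(1))
  Phi_e <- eval_basis(sys$basis_eps, sys$hours)
  c_eps <- newton_c_eps(psi$c_eps, Phi_e, n_h, m_h)

  if (p == 0L) return(parameter_set(c_eps, c_beta))

  # --- latent components ---------------------------------------------------
  g_new <- v_new <- th_new <- numeric(p)
  for (j in seq_len(p)) {
    Aj <- stats$A[[j]]; Bj <- stats$B[[j]]; Cj <- stats$C[[j]]
    Ct_old <- correlation_matrix(sys$D, psi$theta[j])
    Cinv_old <- chol2inv(chol(Ct_old))
    g <- sum(Cinv_old * Bj) / sum(Cinv_old * Aj)   # tr(C^-1 B)/tr(C^-1 A)
    g <- max(min(g, 0.9999), -0.9999)

    Mj <- Cj - g * Bj - g * t(Bj) + g^2 * Aj
    prof <- function(theta) {
      Ct <- correlation_matrix(sys$D, theta)
      ch <- tryCatch(chol(Ct), error = function(e) NULL)
      if (is.null(ch)) return(-Inf)
      vj <- sum(chol2inv(ch) * Mj) / (n * T_)
      if (!is.finite(vj) || vj <= 0) return(-Inf)
      -0.5 * T_ * (n * log(vj) + 2 * sum(log(diag(ch)))) - 0.5 * n * T_
    }
    opt <- stats::optimize(prof, interval = theta_bounds, maximum = TRUE,
                           tol = 1e-2)
    theta <- opt$maximum
    if (min(abs(theta - theta_bounds)) < 1e-1) {
      warning(sprintf("theta search hit its bounds for component %d", j))
    }
    Ct <- correlation_matrix(sys$D, theta)
    v <- sum(chol2inv(chol(Ct)) * Mj) / (n * T_)
    v <- max(v, 1e-12)
    # guard: never move below the previous (g, v, theta) on the expected
    # objective (protects monotonicity against 1-D search quirks)
    if (latent_obj_j(g, v, theta, Aj, Bj, Cj, sys$D, T_) <
        latent_obj_j(psi$g[j], psi$v[j], psi$theta[j], Aj, Bj, Cj, sys$D, T_)) {
      g <- psi$g[j]; v <- psi$v[j]; theta <- psi$theta[j]
    }
    g_new[j] <- g; v_new[j] <- v; th_new[j] <- theta
  }

  parameter_set(c_eps, c_beta, g_new, v_new, th_new)
}

# damped Newton maximization of the concave c_eps objective; falls back to a
# weighted projection of the per-hour log moments if it cannot improve
newton_c_eps <- function(c0, Phi, n_h, m_h, max_iter = 50L) {
  keep <- n_h > 0
  obj <- function(cc) eps_obj(cc, Phi, n_h, m_h)
  cc <- c0
  f <- obj(cc)
  for (it in seq_len(max_iter)) {
    u <- drop(Phi %*% cc)
    w <- n_h * m_h * exp(-u)
    grad <- 0.5 * drop(crossprod(Phi, w - n_h))
    H <- -0.5 * crossprod(Phi * sqrt(pmax(w, 0)))
    step <- tryCatch(-solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      cand <- cc + lam * step
      fc <- obj(cand)
      if (is.finite(fc) && fc >= f) break
      lam <- lam / 2
      if (lam < 1e-8) { cand <- cc; fc <- f; break }
    }
    moved <- sqrt(sum((cand - cc)^2)) < 1e-10 * (1 + sqrt(sum(cc^2)))
    cc <- cand; f <- fc
    if (moved) break
  }
  # fallback: projection of log per-hour moments (never used when Newton
  # behaves, which it does on this strictly concave objective)
  proj <- tryCatch({
    lw <- n_h[keep]
    Pk <- Phi[keep, , drop = FALSE]
    drop(solve(crossprod(Pk * sqrt(lw)),
               crossprod(Pk, lw * log(pmax(m_h[keep], 1e-12)))))
  }, error = function(e) NULL)
  if (!is.null(proj) && obj(proj) > f) {
    cc <- proj
  }
  as.numeric(cc)
}

pseudo_solve <- function(A, tol = 1e-10) {
  eg <- eigen(0.5 * (A + t(A)), symmetric = TRUE)
  keep <- eg$values > tol * max(abs(eg$values))
  if (!any(keep)) return(matrix(0, nrow(A), ncol(A)))
  eg$vectors[, keep, drop = FALSE] %*%
    (t(eg$vectors[, keep, drop = FALSE]) / eg$values[keep])
}

#' Fit the functional spatio-temporal model by EM
#'
#' Alternates the Kalman-smoother E-step and the closed-form/profiled M-step
#' until the relative change in the parameter vector or in the observed-data
#' log-likelihood falls below `config$tol` (whichever happens first), or
#' `max_iter` is reached (with a warning).  The initial-state law is frozen
#' at the stationary covariance implied by the starting parameters, which
#' makes each M-step an exact conditional maximization and the log-likelihood
#' trace provably non-decreasing.
#'
#' @param cube a [panel_cube()].
#' @param spec an [stfm_spec()].
#' @param config an [em_config()].
#' @return object of class `stfm_fit` with elements `psi_hat`, `loglik`,
#'   `loglik_trace`, `npar`, `ic` (log-likelihood minus twice the parameter
#'   count; larger is better), smoothed latent states `zhat`, the stopping
#'   rule that fired, and (if requested) `Sigma`/`se` from
#'   [observed_information()].
#' @export
fit_em <- function(cube, spec, config = em_config()) {
  stopifnot(inherits(config, "em_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (dim(cube$y)[1] < 2L || dim(cube$y)[2] < 2L) {
    stop("need at least 2 stations and 2 days to fit")
  }
  psi <- config$psi0 %||% init_psi(cube, spec)
  sys <- assemble_system(cube, spec, psi)

  trace <- numeric(0)
  stop_rule <- "max_iter"
  st <- NULL
  for (iter in seq_len(config$max_iter)) {
    st <- estep(sys)
    if (!is.finite(st$loglik)) {
      stop("non-finite log-likelihood at EM iteration ", iter)
    }
    trace <- c(trace, st$loglik)
    if (config$verbose) {
      message(sprintf("EM iter %3d: loglik %.6f", iter - 1L, st$loglik))
    }
    if (iter > 1L) {
      v_new <- psi_to_vector(psi, transformed = FALSE)
      v_old <- psi_to_vector(psi_prev, transformed = FALSE)
      rel_psi <- sqrt(sum((v_new - v_old)^2)) / max(sqrt(sum(v_new^2)), 1e-12)
      rel_ll <- abs(trace[iter] - trace[iter - 1L]) /
        max(abs(trace[iter]), 1e-12)
      if (rel_psi < config$tol) { stop_rule <- "psi"; break }
      if (rel_ll < config$tol) { stop_rule <- "loglik"; break }
    }
    psi_prev <- psi
    psi <- mstep(st, sys)
    sys <- update_system(sys, psi)
  }
  if (stop_rule == "max_iter") {
    warning("EM reached max_iter without satisfying a stopping rule")
  }

  fit <- structure(
    list(psi_hat = psi, loglik = trace[length(trace)], loglik_trace = trace,
         npar = npar(spec), ic = model_aic(trace[length(trace)], npar(spec)),
         zhat = st$zhat, spec = spec, config = config,
         stop_rule = stop_rule, n_iter = length(trace) - 1L,
         P0 = sys$P0, locations = sys$locations, hours = sys$hours,
         Sigma = NULL, se = NULL),
    class = "stfm_fit"
  )
  if (config$compute_se) {
    info <- observed_information(cube, spec, psi)
    fit$Sigma <- info$Sigma
    fit$Sigma_trans <- info$Sigma_trans
    fit$se <- info$se
    fit$se_trans <- info$se_trans
  }
  fit
}

#' @export
print.stfm_fit <- function(x, ...) {
  cat(sprintf(
    "stfm_fit: loglik %.3f, npar %d, IC %.3f, %d EM iteration(s), stop: %s\n",
    x$loglik, x$npar, x$ic, x$n_iter, x$stop_rule))
  print(x$psi_hat)
  invisible(x)
}
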