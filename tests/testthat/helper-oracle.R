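# Brute-force joint-Gaussian oracle for tiny instances.
#
# Builds the exact joint normal distribution of the stacked observations and
# all latent states implied by an assembled state-space system, then computes
# the log-likelihood, smoothed moments and conditional predictions by direct
# matrix conditioning.  Deliberately independent of the Kalman recursions it
# is used to check.

dense_gaussian_oracle <- function(sys) {
  m <- length(sys$gdiag); T_ <- sys$T; nq <- nrow(sys$y)
  G <- diag(sys$gdiag, m, m)

  # Cov(z_t, z_u) for t, u in 0..T
  P <- vector("list", T_ + 1L)
  P[[1]] <- sys$P0
  for (t in seq_len(T_)) P[[t + 1L]] <- G %*% P[[t]] %*% G + sys$Q
  Cz <- matrix(0, (T_ + 1L) * m, (T_ + 1L) * m)
  blk <- function(t) (t * m) + seq_len(m)   # t in 0..T
  for (u in 0:T_) for (t in u:T_) {
    Gpow <- diag(sys$gdiag^(t - u), m, m)
    Cz[blk(t), blk(u)] <- Gpow %*% P[[u + 1L]]
    Cz[blk(u), blk(t)] <- t(Cz[blk(t), blk(u)])
  }

  # stacked y over days 1..T (all cells, observed or not)
  Zfull <- matrix(0, nq * T_, (T_ + 1L) * m)
  for (t in seq_len(T_)) {
    Zfull[(t - 1L) * nq + seq_len(nq), blk(t)] <- sys$Z
  }
  mu_y <- as.vector(sys$d)
  Sig_y <- Zfull %*% Cz %*% t(Zfull) + diag(rep(sys$rdiag, T_))
  Czy <- Cz %*% t(Zfull)               # Cov(z_all, y_all)

  obs <- which(!is.na(as.vector(sys$y)))
  list(mu_y = mu_y, Sig_y = Sig_y, Czy = Czy, Cz = Cz, obs = obs,
       yvec = as.vector(sys$y), m = m, T_ = T_, nq = nq, blk = blk)
}

oracle_loglik <- function(or) {
  o <- or$obs
  S <- or$Sig_y[o, o, drop = FALSE]
  r <- or$yvec[o] - or$mu_y[o]
  ch <- chol(S)
  -0.5 * (length(o) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, r, transpose = TRUE)^2))
}

# conditional moments of all states given the observed cells
oracle_smooth <- function(or) {
  o <- or$obs
  S <- or$Sig_y[o, o, drop = FALSE]
  r <- or$yvec[o] - or$mu_y[o]
  K <- or$Czy[, o, drop = FALSE] %*% solve(S)
  mean_all <- K %*% r
  cov_all <- or$Cz - K %*% t(or$Czy[, o, drop = FALSE])
  zhat <- matrix(mean_all, or$m, or$T_ + 1L)
  P_sm <- lapply(0:or$T_, function(t) cov_all[or$blk(t), or$blk(t)])
  P_lag <- lapply(seq_len(or$T_), function(t)
    cov_all[or$blk(t), or$blk(t - 1L)])
  list(zhat = zhat, P_sm = P_sm, P_lag = P_lag, cov_all = cov_all)
}

# conditional mean of unobserved cells given observed ones (prediction oracle)
oracle_predict_cells <- function(or, cells) {
  o <- or$obs
  S <- or$Sig_y[o, o, drop = FALSE]
  r <- or$yvec[o] - or$mu_y[o]
  or$mu_y[cells] +
    drop(or$Sig_y[cells, o, drop = FALSE] %*% solve(S, r))
}

# small complete simulated panel for oracle-scale tests
tiny_system <- function(n = 2, T_ = 3, q = 4, p_z = 2, seed = 42,
                        covariates = "NO2", drop_cells = 0) {
  psi <- parameter_set(
    c_eps = c(log(9), 0.3, -0.2)[seq_len(3)],
    c_beta = matrix(c(30, 5, 8, -0.4, 0.1, 0.05), 3, 2,
                    dimnames = list(NULL, c("(Intercept)", covariates))),
    g = c(0.7, -0.3, 0.4, 0.1)[seq_len(p_z)],
    v = c(40, 25, 15, 10)[seq_len(p_z)],
    theta = c(50, 30, 40, 35)[seq_len(p_z)]
  )
  sc <- sim_scenario(n = n, n_days = T_, q = q, covariates = covariates,
                     p_z = p_z, p_beta = 3, p_eps = 3, psi = psi, seed = seed)
  sim <- simulate_panel(sc)
  cube <- sim$cube
  if (drop_cells > 0) {
    set.seed(seed + 1)
    idx <- sample(length(cube$y), drop_cells)
    cube$y[idx] <- NA_real_
    cube$missing[idx] <- TRUE
  }
  spec <- stfm_spec(covariates = covariates, p_z = p_z, p_beta = 3, p_eps = 3)
  list(sys = assemble_system(cube, spec, psi), cube = cube, spec = spec,
       psi = psi, sim = sim)
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), 1e-12)
}
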