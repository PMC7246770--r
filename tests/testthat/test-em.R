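test_that("E-step moments match brute-force Gaussian conditioning", {
  tk <- tiny_system(n = 2, T_ = 3, q = 4, p_z = 2, seed = 30, drop_cells = 3)
  st <- estep(tk$sys)
  or <- dense_gaussian_oracle(tk$sys)
  osm <- oracle_smooth(or)
  expect_lt(rel_err(st$zhat, osm$zhat), 1e-10)
  # summed second moments per component
  n <- tk$sys$n; T_ <- tk$sys$T
  for (j in 1:2) {
    idx <- (j - 1) * n + 1:n
    A <- B <- C <- matrix(0, n, n)
    for (t in 1:T_) {
      A <- A + osm$P_sm[[t]][idx, idx] + tcrossprod(osm$zhat[idx, t])
      C <- C + osm$P_sm[[t + 1]][idx, idx] + tcrossprod(osm$zhat[idx, t + 1])
      B <- B + osm$P_lag[[t]][idx, idx] +
        tcrossprod(osm$zhat[idx, t + 1], osm$zhat[idx, t])
    }
    expect_lt(rel_err(st$A[[j]], A), 1e-9)
    expect_lt(rel_err(st$B[[j]], B), 1e-9)
    expect_lt(rel_err(st$C[[j]], C), 1e-9)
  }
})

test_that("an unobserved cell's expected squared residual is its prediction
           variance (law of total variance)", {
  tk <- tiny_system(n = 2, T_ = 3, q = 4, p_z = 2, seed = 31, drop_cells = 5)
  sys <- tk$sys
  st <- estep(sys)
  or <- dense_gaussian_oracle(sys)
  osm <- oracle_smooth(or)
  Phi <- sys$Phi_zq
  miss <- which(is.na(sys$y), arr.ind = TRUE)
  for (k in seq_len(nrow(miss))) {
    r <- miss[k, 1]; t <- miss[k, 2]
    i <- (r - 1) %/% sys$q + 1; h <- (r - 1) %% sys$q + 1
    idx <- (1:2 - 1) * sys$n + i
    qf <- drop(Phi[h, ] %*% osm$P_sm[[t + 1]][idx, idx] %*% Phi[h, ])
    expect_equal(st$resid2[r, t], qf + sys$rdiag[r], tolerance = 1e-9)
  }
})

test_that("in the noiseless limit the smoothed state reproduces the
           generating latent values", {
  # square invertible case: q = p_z, tiny noise
  psi <- parameter_set(
    c_eps = c(log(1e-8), 0, 0), c_beta = matrix(c(10, 2, 1), 3, 1,
      dimnames = list(NULL, "(Intercept)")),
    g = c(0.5, 0.2, -0.3), v = c(30, 20, 10), theta = c(40, 30, 20)
  )
  sc <- sim_scenario(n = 2, n_days = 4, q = 3, covariates = character(),
                     p_z = 3, p_beta = 3, p_eps = 3, psi = psi, seed = 32)
  sim <- simulate_panel(sc)
  spec <- stfm_spec(covariates = character(), p_z = 3, p_beta = 3, p_eps = 3)
  st <- estep(assemble_system(sim$cube, spec, psi))
  expect_equal(st$zhat[, -1], sim$z[, -1], tolerance = 1e-3)
})

test_that("the c_beta update solves the explicit weighted normal equations", {
  tk <- tiny_system(n = 3, T_ = 4, q = 4, p_z = 2, seed = 33, drop_cells = 6)
  sys <- tk$sys
  st <- estep(sys)
  new_psi <- mstep(st, sys)
  obs <- !is.na(as.vector(sys$y))
  X <- sys$Xbig[obs, ]
  w <- rep(1 / sys$rdiag, sys$T)[obs]
  r <- as.vector(sys$y - sys$Z %*% st$zhat[, -1])[obs]
  ref <- solve(t(X) %*% (X * w), t(X) %*% (w * r))
  expect_equal(as.numeric(new_psi$c_beta), drop(ref), tolerance = 1e-8)
})

test_that("the g update equals the numeric maximizer of the expected
           complete-data objective", {
  tk <- tiny_system(n = 3, T_ = 6, q = 4, p_z = 2, seed = 34)
  sys <- tk$sys
  st <- estep(sys)
  new_psi <- mstep(st, sys)
  for (j in 1:2) {
    Gam <- sys$Q[(j - 1) * 3 + 1:3, (j - 1) * 3 + 1:3]
    Gi <- solve(Gam)
    qobj <- function(g) {
      M <- st$C[[j]] - g * st$B[[j]] - g * t(st$B[[j]]) + g^2 * st$A[[j]]
      -0.5 * sum(Gi * M)
    }
    grid <- seq(-0.999, 0.999, by = 1e-4)
    g_grid <- grid[which.max(vapply(grid, qobj, numeric(1)))]
    g_closed <- sum(Gi * st$B[[j]]) / sum(Gi * st$A[[j]])
    expect_equal(g_closed, g_grid, tolerance = 1e-3)
    expect_equal(new_psi$g[j], g_closed, tolerance = 1e-10)
  }
})

test_that("a saturated error basis reproduces the per-hour residual moments", {
  # p_eps = q: the log-variance curve can match any per-hour profile, so the
  # update must converge to the per-hour MLE exactly
  tk <- tiny_system(n = 3, T_ = 5, q = 3, p_z = 2, seed = 35)
  sys <- tk$sys
  st <- estep(sys)
  new_psi <- mstep(st, sys)
  # recompute the hour moments the M-step saw
  dnew <- matrix(sys$Xbig %*% as.numeric(new_psi$c_beta), nrow(sys$y), sys$T)
  e2 <- (sys$y - dnew - sys$Z %*% st$zhat[, -1])^2 + st$qform
  hr <- rep(rep(1:3, sys$n), sys$T)
  m_h <- vapply(1:3, function(h) mean(e2[hr == h]), numeric(1))
  fitted_var <- sigma_eps_curve(new_psi$c_eps, sys$basis_eps, 1:3)
  expect_equal(fitted_var, m_h, tolerance = 1e-6)
})

test_that("the EM log-likelihood trace is monotone and refitting from the
           optimum stops immediately", {
  sc <- sim_scenario(n = 4, n_days = 30, q = 8, covariates = "NO2",
                     p_z = 2, p_beta = 3, p_eps = 3,
                     psi = parameter_set(
                       c_eps = c(log(16), 0.2, 0), c_beta = matrix(
                         c(50, 10, 5, -0.5, 0.1, 0), 3, 2,
                         dimnames = list(NULL, c("(Intercept)", "NO2"))),
                       g = c(0.7, 0.2), v = c(900, 400), theta = c(45, 35)),
                     seed = 36)
  sim <- simulate_panel(sc)
  spec <- stfm_spec(covariates = "NO2", p_z = 2, p_beta = 3, p_eps = 3)
  fit <- fit_em(sim$cube, spec, em_config(tol = 1e-5, max_iter = 100))
  expect_true(all(diff(fit$loglik_trace) >= -1e-8 * abs(fit$loglik)))
  expect_true(fit$stop_rule %in% c("psi", "loglik"))
  expect_equal(fit$npar, 3 + 2 * 3 + 3 * 2)

  refit <- fit_em(sim$cube, spec,
                  em_config(tol = 1e-5, max_iter = 100, psi0 = fit$psi_hat))
  expect_lte(refit$n_iter, 1L)
})

test_that("EM handles missing data and a latent-free specification", {
  sc <- sim_scenario(n = 4, n_days = 25, q = 8, covariates = "NO2",
                     p_z = 1, p_beta = 3, p_eps = 3,
                     psi = parameter_set(
                       c_eps = c(log(9), 0, 0), c_beta = matrix(
                         c(40, 5, 2, -0.4, 0, 0), 3, 2,
                         dimnames = list(NULL, c("(Intercept)", "NO2"))),
                       g = 0.5, v = 500, theta = 40),
                     missing_rate = 0.15, seed = 37)
  sim <- simulate_panel(sc)
  spec <- stfm_spec(covariates = "NO2", p_z = 1, p_beta = 3, p_eps = 3)
  fit <- fit_em(sim$cube, spec, em_config(tol = 1e-4))
  expect_true(all(diff(fit$loglik_trace) >= -1e-8 * abs(fit$loglik)))

  spec0 <- stfm_spec(covariates = "NO2", p_z = 0, p_beta = 3, p_eps = 3)
  fit0 <- fit_em(sim$cube, spec0, em_config(tol = 1e-4))
  expect_true(all(diff(fit0$loglik_trace) >= -1e-8 * abs(fit0$loglik)))
  expect_gt(fit$ic, fit0$ic)   # the latent field is real structure
})

test_that("standard errors reduce to sigma/sqrt(N) in the iid mean-only
           case", {
  set.seed(38)
  n <- 4; T_ <- 40; q <- 8
  sigma <- 3
  y <- array(rnorm(n * T_ * q, 50, sigma), c(n, T_, q))
  cube <- panel_cube(y, array(0, c(n, T_, q, 0)), beijing_like_layout(n),
                     character())
  spec <- stfm_spec(covariates = character(), p_z = 0, p_beta = 1, p_eps = 1)
  fit <- fit_em(cube, spec, em_config(tol = 1e-8, max_iter = 50))
  info <- observed_information(cube, spec, fit$psi_hat)
  N <- n * T_ * q
  sig_hat <- sqrt(exp(fit$psi_hat$c_eps[1]))
  expect_equal(unname(info$se["c_beta.(Intercept).1"]), sig_hat / sqrt(N),
               tolerance = 1e-3)
})

test_that("the numerical Hessian is exact on a quadratic log-likelihood", {
  A <- matrix(c(4, 1, 0.5, 1, 3, -0.2, 0.5, -0.2, 2), 3)
  f <- function(x) -0.5 * drop(t(x) %*% A %*% x) + sum(x)
  H <- fdstm:::numerical_hessian(f, c(0.3, -0.2, 1.1))
  expect_equal(H, -A, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("reported standard errors are calibrated against the Monte-Carlo
           spread of repeated fits", {
  # modest replication: empirical SD of estimates within a factor 2 of the
  # mean reported SE, on the unconstrained scale
  n_rep <- 12
  ests <- ses <- NULL
  spec <- stfm_spec(covariates = character(), p_z = 1, p_beta = 1, p_eps = 1)
  psi_true <- parameter_set(c_eps = log(16), c_beta = matrix(60, 1, 1,
                              dimnames = list(NULL, "(Intercept)")),
                            g = 0.6, v = 700, theta = 40)
  layout <- beijing_like_layout(4, seed = 39)
  for (r in seq_len(n_rep)) {
    sc <- sim_scenario(n = 4, n_days = 60, q = 8, covariates = character(),
                       p_z = 1, p_beta = 1, p_eps = 1, psi = psi_true,
                       layout = layout, seed = 400 + r)
    sim <- simulate_panel(sc)
    fit <- fit_em(sim$cube, spec, em_config(tol = 1e-6, max_iter = 300))
    info <- observed_information(sim$cube, spec, fit$psi_hat)
    ests <- rbind(ests, psi_to_vector(fit$psi_hat, transformed = TRUE))
    ses <- rbind(ses, info$se_trans)
  }
  emp_sd <- apply(ests, 2, sd)
  mean_se <- colMeans(ses)
  ratio <- emp_sd / mean_se
  expect_true(all(ratio > 0.5 & ratio < 2))
})
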