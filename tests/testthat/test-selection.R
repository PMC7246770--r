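test_that("the information criterion is loglik minus twice the parameter
           count, maximized", {
  expect_equal(model_aic(0, 0), 0)
  expect_equal(model_aic(-414700, 7), -414714)
  expect_equal(model_aic(-247954, 56), -248066)
  # larger is better: removing a useless parameter improves the criterion
  expect_gt(model_aic(-100, 3), model_aic(-100, 4))
})

test_that("parameter counting follows p_eps + b p_beta + 3 p_z with a
           configurable error-coefficient convention", {
  sp <- stfm_spec(covariates = c("a", "b"), p_z = 7, p_beta = 5, p_eps = 5)
  expect_equal(npar(sp), 5 + 3 * 5 + 3 * 7)
  expect_equal(npar(sp, include_c_eps = FALSE), 3 * 5 + 3 * 7)
})

test_that("Wald statistics follow the chi-square construction including
           rank-deficient covariances", {
  # null coefficients: statistic 0, p = 1
  wt0 <- wald_test(rep(0, 5), diag(5))
  expect_equal(wt0$statistic, 0)
  expect_equal(wt0$p_value, 1)
  # identity covariance: statistic is the squared norm, df the length
  cc <- c(1, -2, 0.5)
  wt1 <- wald_test(cc, diag(3))
  expect_equal(wt1$statistic, sum(cc^2))
  expect_equal(wt1$df, 3L)
  expect_equal(wt1$p_value, pchisq(sum(cc^2), 3, lower.tail = FALSE))

  # singular covariance of rank 2: df = 2 and the statistic equals the
  # restriction to the rank-2 subspace (eigendecomposition oracle)
  U <- qr.Q(qr(matrix(c(1, 1, 0, 0, 1, 1, 1, 0, 1), 3)))
  S <- U %*% diag(c(2, 0.5, 0)) %*% t(U)
  c2 <- drop(U %*% c(1, 1, 0))   # inside the column space
  wt2 <- wald_test(c2, S)
  expect_equal(wt2$df, 2L)
  proj <- drop(t(U[, 1:2]) %*% c2)
  expect_equal(wt2$statistic, sum(proj^2 / c(2, 0.5)), tolerance = 1e-10)

  expect_error(wald_test(c(1, 0), matrix(0, 2, 2)), "zero-rank")
})

test_that("confidence bands collapse with zero covariance, nest across
           levels, match the scalar delta-method width, and are periodic", {
  fb <- fourier_basis(5, period = 24)
  cc <- c(2, 1, -1, 0.3, 0.2)
  S0 <- matrix(0, 5, 5)
  b0 <- confidence_bands(cc, S0, fb, hours = 0:24)
  expect_equal(b0$lower_95, b0$estimate)
  expect_equal(b0$upper_95, b0$estimate)

  set.seed(40)
  Araw <- matrix(rnorm(25), 5)
  S <- crossprod(Araw) / 10
  bb <- confidence_bands(cc, S, fb, hours = 0:24)
  expect_true(all(bb$lower_99 <= bb$lower_95 + 1e-12))
  expect_true(all(bb$upper_99 >= bb$upper_95 - 1e-12))
  # half-width at a single hour equals the direct variance formula
  h <- 7
  phi <- drop(eval_basis(fb, h))
  half <- qnorm(0.975) * sqrt(drop(phi %*% S %*% phi))
  row <- which(bb$hour == h)
  expect_equal(bb$upper_95[row] - bb$estimate[row], half, tolerance = 1e-10)
  # periodic: band at 0 equals band at 24
  expect_equal(unlist(bb[bb$hour == 0, -1]), unlist(bb[bb$hour == 24, -1]),
               tolerance = 1e-10)
})

test_that("held-out prediction reduces to the shared smooth at a coincident
           location and to the fixed effects far away", {
  tk <- tiny_system(n = 3, T_ = 4, q = 4, p_z = 2, seed = 41)
  spec <- tk$spec
  fit <- fit_em(tk$cube, spec, em_config(tol = 1e-4, max_iter = 50))

  # coincident: duplicate station 1 as a held-out location
  held <- subset_stations(tk$cube, 1L)
  pr <- predict_heldout(fit, tk$cube, held)
  expect_equal(pr$pred[1, , ], pr$fitted[1, , ], tolerance = 1e-6)

  # far away (>> max theta): prediction falls back to the fixed effects
  far <- held
  far$locations$lat <- far$locations$lat + 30   # ~3300 km
  pr_far <- predict_heldout(fit, tk$cube, far)
  sys_far <- assemble_system(
    combine_cubes(tk$cube, local({h <- far; h$y[] <- NA; h$missing[] <- TRUE; h})),
    spec, fit$psi_hat)
  d_far <- matrix(sys_far$d[3 * 4 + 1:4, ], 1)
  expect_equal(max(abs(pr_far$pred[1, , ] -
                         aperm(array(sys_far$d[3 * 4 + 1:4, ],
                                     c(4, 1, 4)), c(2, 3, 1))[1, , ])),
               0, tolerance = 1e-3)
})

test_that("held-out prediction equals the brute-force Gaussian conditional
           mean on a tiny instance", {
  tk <- tiny_system(n = 3, T_ = 3, q = 4, p_z = 2, seed = 42)
  cube <- tk$cube
  fit_idx <- 1:2
  cube_fit <- subset_stations(cube, fit_idx)
  held <- subset_stations(cube, 3L)
  # a hand-made fit object at the true parameters (prediction is defined by
  # psi, not by how it was estimated)
  fit <- structure(list(psi_hat = tk$psi, spec = tk$spec), class = "stfm_fit")
  pr <- predict_heldout(fit, cube_fit, held)

  # oracle: joint system over all 3 stations, condition on stations 1-2
  joint <- cube
  joint$y[3, , ] <- NA
  joint$missing[3, , ] <- TRUE
  sys <- assemble_system(joint, tk$spec, tk$psi)
  or <- dense_gaussian_oracle(sys)
  held_rows <- as.vector(vapply(seq_len(sys$T), function(t)
    (t - 1) * 12 + 2 * 4 + 1:4, numeric(4)))
  pred_or <- oracle_predict_cells(or, held_rows)
  expect_lt(rel_err(as.vector(aperm(pr$pred, c(3, 2, 1))), pred_or), 1e-8)
})

test_that("cross-validation scores follow their definitions and B counts
           observed cells only", {
  # perfect predictions: MSE 0, R2 1
  y <- matrix(rnorm(40, 50, 10), 4)
  s <- fdstm:::cv_score_station(y, y, matrix(FALSE, 4, 10))
  expect_equal(s$mse, 0)
  expect_equal(s$r2, 1)
  expect_equal(s$B, 40L)
  # station-mean predictor: R2 = 0 exactly under the population variance
  s0 <- fdstm:::cv_score_station(y, matrix(mean(y), 4, 10),
                                 matrix(FALSE, 4, 10))
  expect_equal(s0$r2, 0, tolerance = 1e-12)
  # deleting k observed cells reduces B by k
  miss <- matrix(FALSE, 4, 10); miss[c(2, 9, 17)] <- TRUE
  expect_equal(fdstm:::cv_score_station(y, y, miss)$B, 37L)
})

test_that("two-fold and leave-one-station-out cross-validation run end to
           end and average per-station scores", {
  sc <- sim_scenario(n = 5, n_days = 20, q = 8, covariates = "NO2",
                     p_z = 1, p_beta = 3, p_eps = 3,
                     psi = parameter_set(
                       c_eps = c(log(9), 0, 0), c_beta = matrix(
                         c(40, 8, 3, -0.4, 0, 0), 3, 2,
                         dimnames = list(NULL, c("(Intercept)", "NO2"))),
                       g = 0.6, v = 600, theta = 45),
                     seed = 43)
  sim <- simulate_panel(sc)
  spec <- stfm_spec(covariates = "NO2", p_z = 1, p_beta = 3, p_eps = 3)
  cfg <- em_config(tol = 1e-3, max_iter = 40)

  cv2 <- cv_two_fold(sim$cube, spec, cfg, seed = 7)
  expect_equal(length(cv2$mse), 2L)
  expect_equal(cv2$mse_bar, mean(cv2$mse))
  expect_true(all(cv2$r2 > 0))      # the model is far better than the mean
  expect_error(cv_two_fold(sim$cube, spec, cfg, split = c(1L)),
               "at least 2 stations")

  cvl <- loso_cv(sim$cube, spec, cfg)
  expect_equal(length(cvl$mse), 5L)
  expect_equal(cvl$mse_bar, mean(cvl$mse))
  expect_equal(cvl$r2_bar, mean(cvl$r2))
  expect_error(loso_cv(subset_stations(sim$cube, 1:2), spec, cfg),
               "at least 3")
})

test_that("forward selection returns an empty path without candidates and
           finds a strong covariate first", {
  sc <- sim_scenario(n = 4, n_days = 25, q = 8, covariates = c("NO2", "W1"),
                     p_z = 1, p_beta = 3, p_eps = 3,
                     psi = parameter_set(
                       c_eps = c(log(9), 0, 0),
                       c_beta = matrix(c(40, 8, 3, -0.8, 0.1, 0, 0, 0, 0),
                                       3, 3, dimnames = list(NULL,
                                         c("(Intercept)", "NO2", "W1"))),
                       g = 0.6, v = 400, theta = 45),
                     seed = 44)
  sim <- simulate_panel(sc)
  spec <- stfm_spec(p_z = 1, p_beta = 3, p_eps = 3)
  cfg <- em_config(tol = 1e-3, max_iter = 40)

  empty <- forward_select(sim$cube, character(), spec, cfg)
  expect_equal(nrow(empty$path), 0L)
  expect_true(is.finite(empty$baseline_ic))

  sel <- forward_select(sim$cube, c("W1", "NO2"), spec, cfg)
  expect_equal(sel$path$covariate[1], "NO2")
  # greedy additions: criterion trace reported per step
  expect_equal(nrow(sel$path), 2L)
})

test_that("the basis-size grid reports one row per combination with the
           argmax bookkeeping", {
  sc <- sim_scenario(n = 4, n_days = 15, q = 8, covariates = character(),
                     p_z = 1, p_beta = 1, p_eps = 1,
                     psi = parameter_set(
                       c_eps = log(9), c_beta = matrix(50, 1, 1,
                         dimnames = list(NULL, "(Intercept)")),
                       g = 0.5, v = 400, theta = 45),
                     seed = 45)
  sim <- simulate_panel(sc)
  grid <- data.frame(p_z = c(1, 1), p_beta = 1, p_eps = c(1, 3))
  out <- basis_grid_search(sim$cube, grid, character(),
                           em_config(tol = 1e-3, max_iter = 30))
  expect_equal(nrow(out), 2L)
  expect_true(all(is.finite(out$ic)))
  expect_true(attr(out, "best_ic") %in% 1:2)
})
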