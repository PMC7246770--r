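#' Random station layout over a dense urban monitoring region
#'
#' Draws `n` station locations uniformly in a roughly 50 km box centred on a
#' dense mid-latitude monitoring network (default centre 39.9 N, 116.4 E),
#' so pairwise great-circle distances are mostly below 60 km — the spatial
#' scale at which the default latent ranges operate.
#'
#' @param n number of stations.
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @param center latitude/longitude of the box centre (degrees).
#' @param half_width_km half-width of the box (km).
#' @return locations data.frame with `station`, `lat`, `lon`.
#' @export
beijing_like_layout <- function(n, seed = NULL, center = c(39.9, 116.4),
                                half_width_km = 25) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  dlat <- half_width_km / 111.19
  dlon <- half_width_km / (111.19 * cos(center[1] * pi / 180))
  data.frame(
    station = seq_len(n),
    lat = stats::runif(n, center[1] - dlat, center[1] + dlat),
    lon = stats::runif(n, center[2] - dlon, center[2] + dlon)
  )
}

#' Reference latent-process parameters for a summertime ozone network
#'
#' Latent transition diagonals, spatial ranges and scales at the magnitudes
#' estimated for a 7-component latent field on a dense urban ozone network:
#' one strongly persistent leading component and progressively faster, less
#' variable harmonics, with ranges of 30-65 km.  `p_z < 7` keeps the leading
#' components.  Default error-variance and effect-curve coefficients are
#' supplied so the result is a complete [parameter_set()] usable as
#' simulation truth.
#'
#' @param p_z number of latent components to keep (1..7).
#' @param covariates covariate names to attach default effect curves for
#'   (see [default_effect_coefs()]).
#' @param p_beta,p_eps basis sizes for the effect and log-variance curves.
#' @return a [parameter_set()].
#' @export
beijing_psi <- function(p_z = 7, covariates = character(), p_beta = 5,
                        p_eps = 5) {
  stopifnot(p_z >= 1, p_z <= 7)
  g <- c(0.739, 0.229, 0.179, 0.034, 0.106, 0.043, -0.210)
  theta <- c(63.12, 50.94, 36.98, 36.34, 39.75, 31.92, 37.10)
  v <- c(8422.14, 3799.47, 2027.63, 896.86, 702.64, 191.09, 151.80)
  parameter_set(
    c_eps = default_c_eps(p_eps),
    c_beta = default_effect_coefs(covariates, p_beta),
    g = g[seq_len(p_z)], v = v[seq_len(p_z)], theta = theta[seq_len(p_z)]
  )
}

# noise log-variance curve: around 60-150 (ug/m3)^2, larger at night, far
# below the latent-field variance as on a real network
default_c_eps <- function(p_eps) {
  full <- c(log(100), 0.25, 0.45, 0, 0)
  c(full, rep(0, max(0, p_eps - 5)))[seq_len(p_eps)]
}

#' Default effect-curve coefficients for simulation truths
#'
#' Smooth diurnal effect curves for commonly used covariate names: a
#' midday-peaking baseline for the intercept, a negative curve for
#' `"NO2"`-like precursors, midday-peaking positive curves for `"TEMP"` and
#' `"UVB"`, a sign-changing curve for `"PM10"`, a double-spike curve for
#' `"SO2"`, an exactly-zero (inert) curve for `"IRAIN"`, and zero for any
#' unrecognized name.  Magnitudes are free choices recorded as truth.
#'
#' @param covariates covariate names (the intercept column is always first).
#' @param p_beta basis size of the curves.
#' @return `p_beta x (1 + length(covariates))` coefficient matrix.
#' @export
default_effect_coefs <- function(covariates = character(), p_beta = 5) {
  peak_curve <- function(mean, amp, peak_hour, omega = 2 * pi / 24) {
    # mean + amp * cos(omega (h - peak)) expressed in basis coordinates
    c(mean, amp * sin(omega * peak_hour), amp * cos(omega * peak_hour))
  }
  pad <- function(x) c(x, rep(0, max(0, p_beta - length(x))))[seq_len(p_beta)]
  curves <- list(
    "(Intercept)" = pad(c(peak_curve(80, 45, 14), 0, 0)),
    NO2  = pad(c(peak_curve(-0.45, 0.15, 5), 0, 0)),
    TEMP = pad(c(peak_curve(0.8, 0.6, 13), 0, 0)),
    UVB  = pad(c(peak_curve(1.2, 0.9, 13), 0, 0)),
    PM10 = pad(c(peak_curve(0.05, 0.15, 15), 0.05, 0)),
    SO2  = pad(c(0.3, 0, 0, 0.25, 0.1)),
    IRAIN = pad(0)
  )
  cols <- c("(Intercept)", covariates)
  out <- vapply(cols, function(nm) curves[[nm]] %||% pad(0),
                numeric(p_beta))
  matrix(out, p_beta, length(cols), dimnames = list(NULL, cols))
}

#' Simulation scenario
#'
#' Bundles everything [simulate_panel()] needs: layout, grid sizes, the true
#' parameters and the covariate-generator settings.  Defaults mirror a dense
#' summertime urban ozone study: 36 stations in a ~50 km region, 92 days of
#' 24 hourly readings, a 7-component latent field at reference magnitudes.
#'
#' @param n stations; `n_days` days; `q` hours per day.
#' @param n_days,q grid sizes.
#' @param covariates covariate names to generate.
#' @param p_z,p_beta,p_eps basis sizes.
#' @param psi true [parameter_set()]; default [beijing_psi()].
#' @param layout optional locations data.frame; default
#'   [beijing_like_layout()] drawn under `seed`.
#' @param missing_rate fraction of cells made missing at random.
#' @param seed RNG seed; identical scenarios produce identical panels.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(n = 36, n_days = 92, q = 24,
                         covariates = c("NO2", "PM10", "SO2", "TEMP",
                                        "IRAIN", "UVB"),
                         p_z = 7, p_beta = 5, p_eps = 5,
                         psi = NULL, layout = NULL, missing_rate = 0,
                         seed = 1L) {
  psi <- psi %||% beijing_psi(p_z, covariates, p_beta, p_eps)
  stopifnot(length(psi$g) == p_z, nrow(psi$c_beta) == p_beta,
            length(psi$c_eps) == p_eps,
            ncol(psi$c_beta) == length(covariates) + 1L)
  if (any(abs(psi$g) >= 1)) stop("nonstationary true 'g'")
  structure(
    list(n = n, n_days = n_days, q = q, covariates = covariates,
         p_z = p_z, p_beta = p_beta, p_eps = p_eps, psi = psi,
         layout = layout, missing_rate = missing_rate, seed = seed),
    class = "sim_scenario"
  )
}

# covariate generator settings: diurnal mean curve, day-to-day AR(1)
# perturbation, and white noise, loosely at urban-pollutant magnitudes
covariate_settings <- function(name) {
  defaults <- list(
    NO2  = list(mean = 35, amp = 15, peak = 8,  ar = 0.6, ar_sd = 10, noise = 5),
    PM10 = list(mean = 70, amp = 20, peak = 10, ar = 0.7, ar_sd = 20, noise = 10),
    SO2  = list(mean = 8,  amp = 3,  peak = 9,  ar = 0.5, ar_sd = 3,  noise = 1.5),
    TEMP = list(mean = 26, amp = 5,  peak = 14, ar = 0.8, ar_sd = 3,  noise = 1),
    IRAIN = list(mean = 1, amp = 0.5, peak = 16, ar = 0.3, ar_sd = 1, noise = 0.5),
    UVB  = list(mean = 4,  amp = 3.5, peak = 12, ar = 0.4, ar_sd = 0.8, noise = 0.5)
  )
  defaults[[name]] %||%
    list(mean = 0, amp = 1, peak = 12, ar = 0.5, ar_sd = 1, noise = 0.5)
}

#' Simulate a panel from the generative model
#'
#' Draws the initial latent state from its stationary law, iterates the
#' component-wise AR(1) dynamics with spatially correlated innovations,
#' generates covariates as smooth diurnal curves plus AR(1) day-to-day
#' perturbations plus white noise, evaluates the effect curves, and adds
#' heteroskedastic measurement noise from the log-linear variance curve.
#'
#' @param scenario a [sim_scenario()].
#' @return list with `cube` (a [panel_cube()]), `z` (true latent states,
#'   state-dim x (n_days + 1), component-major), `truth` (the generating
#'   [parameter_set()]), and `components` (the fixed-effect and latent mean
#'   surfaces as `n x n_days x q` arrays).
#' @export
simulate_panel <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n; T_ <- scenario$n_days; q <- scenario$q
  p <- scenario$p_z; psi <- scenario$psi
  locs <- scenario$layout %||% beijing_like_layout(n)
  D <- distance_matrix_km(locs)
  hours <- seq_len(q)

  # latent field, component-major state stacking
  blocks <- gamma_blocks(D, psi$v, psi$theta)
  chol_b <- lapply(blocks, chol)
  chol_s <- lapply(stationary_state_cov(psi$g, blocks), chol)
  m <- n * p
  z <- matrix(0, m, T_ + 1L)
  for (j in seq_len(p)) {
    idx <- (j - 1L) * n + seq_len(n)
    z[idx, 1L] <- drop(crossprod(chol_s[[j]], stats::rnorm(n)))
  }
  for (t in seq_len(T_)) {
    for (j in seq_len(p)) {
      idx <- (j - 1L) * n + seq_len(n)
      z[idx, t + 1L] <- psi$g[j] * z[idx, t] +
        drop(crossprod(chol_b[[j]], stats::rnorm(n)))
    }
  }

  # covariates
  b_cov <- length(scenario$covariates)
  X <- array(0, c(n, T_, q, b_cov))
  omega <- 2 * pi / q
  for (jc in seq_len(b_cov)) {
    s <- covariate_settings(scenario$covariates[jc])
    mu_h <- s$mean - s$amp * cos(omega * (hours - s$peak))
    a <- matrix(0, n, T_)
    a[, 1] <- stats::rnorm(n, 0, s$ar_sd)
    for (t in seq_len(T_ - 1L)) {
      a[, t + 1L] <- s$ar * a[, t] +
        stats::rnorm(n, 0, s$ar_sd * sqrt(1 - s$ar^2))
    }
    X[, , , jc] <- rep(a, times = q) +
      rep(mu_h, each = n * T_) +
      stats::rnorm(n * T_ * q, 0, s$noise)
  }

  # observation pieces
  basis_beta <- fourier_basis(scenario$p_beta, period = q)
  basis_eps <- fourier_basis(scenario$p_eps, period = q)
  basis_z <- fourier_basis(p, period = q, allow_even = TRUE)
  beta_h <- eval_basis(basis_beta, hours) %*% psi$c_beta   # q x (b_cov+1)
  fixed <- array(rep(beta_h[, 1], each = n * T_), c(n, T_, q))
  for (jc in seq_len(b_cov)) {
    xj <- array(X[, , , jc], c(n, T_, q))
    fixed <- fixed + xj * rep(beta_h[, jc + 1L], each = n * T_)
  }
  Phi_zq <- eval_basis(basis_z, hours)
  latent <- array(0, c(n, T_, q))
  for (t in seq_len(T_)) {
    zc <- matrix(z[, t + 1L], n, p)            # station x component
    latent[, t, ] <- zc %*% t(Phi_zq)
  }
  sig2 <- sigma_eps_curve(psi$c_eps, basis_eps, hours)
  eps <- array(stats::rnorm(n * T_ * q, 0, rep(sqrt(sig2), each = n * T_)),
               c(n, T_, q))
  y <- fixed + latent + eps

  cube <- panel_cube(y, X, locs, covariate_names = scenario$covariates,
                     hours = hours)
  if (scenario$missing_rate > 0) {
    cube <- inject_missing(cube, scenario$missing_rate)
  }
  list(cube = cube, z = z, truth = psi,
       components = list(fixed = fixed, latent = latent))
}

#' Make a fraction of cells missing at random
#'
#' @param cube a [panel_cube()].
#' @param rate fraction of cells to delete (0..1).
#' @param seed optional seed (uses the current stream when `NULL`).
#' @return the cube with additional missing cells (`y` set to `NA`).
#' @export
inject_missing <- function(cube, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  drop_idx <- which(stats::runif(length(cube$y)) < rate)
  cube$y[drop_idx] <- NA_real_
  cube$missing[drop_idx] <- TRUE
  cube
}
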