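#' Combine two panel cubes over stations
#'
#' Stations of `b` are appended to `a`; day and hour grids must agree.
#'
#' @param a,b [panel_cube()] objects with identical day/hour grids and
#'   covariate sets.
#' @return a combined [panel_cube()].
#' @export
combine_cubes <- function(a, b) {
  stopifnot(identical(dim(a$y)[2:3], dim(b$y)[2:3]),
            identical(a$covariate_names, b$covariate_names))
  da <- dim(a$y); db <- dim(b$y)
  y <- array(NA_real_, c(da[1] + db[1], da[2], da[3]))
  y[seq_len(da[1]), , ] <- a$y
  y[da[1] + seq_len(db[1]), , ] <- b$y
  nb <- length(a$covariate_names)
  X <- array(NA_real_, c(da[1] + db[1], da[2], da[3], nb))
  if (nb > 0) {
    X[seq_len(da[1]), , , ] <- a$X
    X[da[1] + seq_len(db[1]), , , ] <- b$X
  }
  miss <- array(TRUE, dim(y))
  miss[seq_len(da[1]), , ] <- a$missing
  miss[da[1] + seq_len(db[1]), , ] <- b$missing
  locs <- rbind(a$locations[, c("station", "lat", "lon")],
                b$locations[, c("station", "lat", "lon")])
  panel_cube(y, X, locs, covariate_names = a$covariate_names, missing = miss,
             dates = a$dates, hours = a$hours)
}

#' Conditional-mean prediction at held-out stations
#'
#' Exact kriging-type prediction under the fitted model: the latent state is
#' augmented with the held-out locations (the joint innovation covariance
#' uses the fitted scales and ranges over all locations), the smoother is
#' rerun with the held-out responses treated as missing, and the prediction
#' is the conditional mean `x'beta(h) + phi(h)' E[z | Y]` at every held-out
#' cell.  Held-out locations coincident with a fitting location are allowed:
#' their latent values collapse onto the shared one.
#'
#' @param fit an [fit_em()] result.
#' @param cube_fit the [panel_cube()] the model was fitted on.
#' @param heldout a [panel_cube()] of held-out stations with covariates at
#'   every (day, hour); its response (if any) is ignored for prediction.
#' @return list with `pred` (held-out predictions, `n_held x T x q` array),
#'   `fitted` (in-sample conditional means for the fitting stations under
#'   the same joint smoother), and `zhat` (joint smoothed states).
#' @export
predict_heldout <- function(fit, cube_fit, heldout) {
  stopifnot(inherits(fit, "stfm_fit"))
  n_fit <- dim(cube_fit$y)[1]; n_held <- dim(heldout$y)[1]
  # held-out responses are withheld from conditioning
  blank <- heldout
  blank$y[] <- NA_real_
  blank$missing <- array(TRUE, dim(blank$y))
  joint <- combine_cubes(cube_fit, blank)

  sys <- assemble_system(joint, fit$spec, fit$psi_hat)
  ks <- kalman_smoother(sys)
  T_ <- sys$T; q <- sys$q
  cond_mean <- sys$d +
    (if (sys$p_z > 0) sys$Z %*% ks$a_sm[, -1L, drop = FALSE] else 0)

  to_array <- function(rows, nst) {
    aperm(array(cond_mean[rows, , drop = FALSE], c(q, nst, T_)), c(2, 3, 1))
  }
  fit_rows <- seq_len(n_fit * q)
  held_rows <- n_fit * q + seq_len(n_held * q)
  list(pred = to_array(held_rows, n_held),
       fitted = to_array(fit_rows, n_fit),
       zhat = ks$a_sm)
}
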