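cv_score_station <- function(y_true, y_pred, miss) {
  keep <- !miss & is.finite(y_true)
  B <- sum(keep)
  if (B == 0L) return(list(mse = NA_real_, r2 = NA_real_, B = 0L))
  err <- y_true[keep] - y_pred[keep]
  mse <- mean(err^2)
  vr <- mean((y_true[keep] - mean(y_true[keep]))^2)
  list(mse = mse, r2 = 1 - mse / vr, B = B)
}

cv_result <- function(stations, mse, r2, B, fold) {
  structure(
    list(station = stations, mse = mse, r2 = r2, B = B, fold = fold,
         mse_bar = mean(mse, na.rm = TRUE), r2_bar = mean(r2, na.rm = TRUE)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d scored station(s), MSE-bar %.4f, R2-bar %.4f\n",
              length(x$station), x$mse_bar, x$r2_bar))
  invisible(x)
}

#' Two-fold cross-validation over stations
#'
#' Partitions the stations into an estimation set and a validation set, fits
#' the model on the estimation stations, predicts the validation stations by
#' [predict_heldout()], and scores each held-out station by its
#' cross-validation mean squared error over observed cells and the
#' corresponding R-squared `1 - MSE_s / VAR_s`.
#'
#' @param cube a [panel_cube()].
#' @param spec an [stfm_spec()].
#' @param config an [em_config()].
#' @param split optional logical/integer vector assigning stations to the
#'   validation fold; default is a seeded random half split.
#' @param seed seed for the default random split.
#' @return a `cv_result` for the validation stations.
#' @export
cv_two_fold <- function(cube, spec, config = em_config(), split = NULL,
                        seed = 1L) {
  n <- dim(cube$y)[1]
  if (is.null(split)) {
    set.seed(seed)
    split <- seq_len(n) %in% sample(n, floor(n / 2))
  }
  if (is.numeric(split)) split <- seq_len(n) %in% split
  est <- which(!split); val <- which(split)
  if (length(est) < 2L || length(val) < 2L) {
    stop("each fold must contain at least 2 stations")
  }
  fit <- fit_em(subset_stations(cube, est), spec, config)
  pr <- predict_heldout(fit, subset_stations(cube, est),
                        subset_stations(cube, val))
  mse <- r2 <- numeric(length(val)); B <- integer(length(val))
  for (k in seq_along(val)) {
    s <- cv_score_station(cube$y[val[k], , ], pr$pred[k, , ],
                          cube$missing[val[k], , ])
    mse[k] <- s$mse; r2[k] <- s$r2; B[k] <- s$B
  }
  cv_result(cube$locations$station[val], mse, r2, B,
            fold = ifelse(split, "validation", "estimation"))
}

#' Leave-one-station-out cross-validation
#'
#' Refits the model `n` times, each time holding out one station, predicting
#' its hourly profiles, and scoring them; reports the per-station MSE and
#' R-squared and their averages.  A failing fold is reported with a warning
#' and the averages are taken over the completed folds.
#'
#' @param cube a [panel_cube()].
#' @param spec an [stfm_spec()].
#' @param config an [em_config()].
#' @return a `cv_result` over all stations.
#' @export
loso_cv <- function(cube, spec, config = em_config()) {
  n <- dim(cube$y)[1]
  if (n < 3L) stop("leave-one-station-out needs at least 3 stations")
  mse <- r2 <- rep(NA_real_, n); B <- integer(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      rest <- subset_stations(cube, setdiff(seq_len(n), i))
      fit <- fit_em(rest, spec, config)
      pr <- predict_heldout(fit, rest, subset_stations(cube, i))
      cv_score_station(cube$y[i, , ], pr$pred[1, , ], cube$missing[i, , ])
    }, error = function(e) {
      warning("fold for station ", cube$locations$station[i], " failed: ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(res)) { mse[i] <- res$mse; r2[i] <- res$r2; B[i] <- res$B }
  }
  cv_result(cube$locations$station, mse, r2, B, fold = "loso")
}
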