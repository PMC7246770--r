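#' Integrated wind speed
#'
#' Within-event cumulative wind speed: the running sum restarts whenever the
#' wind direction changes, i.e. `IWS[t] = WS[t]` if `WD[t] != WD[t-1]`, else
#' `IWS[t-1] + WS[t]`, with `IWS[1] = WS[1]`.
#'
#' @param ws wind speeds (m/s), non-negative.
#' @param wd wind directions, compared as exact categorical equality. Numeric
#'   directions in degrees can be binned first with [wind_sectors()].
#' @return numeric vector of integrated wind speeds.
#' @export
integrate_wind <- function(ws, wd) {
  stopifnot(length(ws) == length(wd), length(ws) >= 1L)
  if (any(ws < 0, na.rm = TRUE)) stop("wind speed must be non-negative")
  out <- numeric(length(ws))
  out[1] <- ws[1]
  for (t in seq_along(ws)[-1]) {
    same <- identical(wd[t], wd[t - 1]) ||
      (!is.na(wd[t]) && !is.na(wd[t - 1]) && wd[t] == wd[t - 1])
    out[t] <- if (same) out[t - 1] + ws[t] else ws[t]
  }
  out
}

#' Bin wind direction degrees into compass sectors
#'
#' @param degrees wind direction in degrees from north.
#' @param sectors number of equal sectors (default 16).
#' @return integer sector labels in `1:sectors`.
#' @export
wind_sectors <- function(degrees, sectors = 16L) {
  stopifnot(sectors >= 1L)
  (floor(((degrees %% 360) + 360 / (2 * sectors)) / (360 / sectors)) %%
      sectors) + 1L
}

#' Integrated rainfall
#'
#' Within-event cumulative rainfall: `IRAIN[t] = 0` when `RAIN[t] = 0`, else
#' `IRAIN[t-1] + RAIN[t]`, with `IRAIN[1] = RAIN[1]`.
#'
#' @param rain rainfall (mm), non-negative.
#' @return numeric vector of integrated rainfall.
#' @export
integrate_rain <- function(rain) {
  stopifnot(length(rain) >= 1L)
  if (any(rain < 0, na.rm = TRUE)) stop("rainfall must be non-negative")
  out <- numeric(length(rain))
  out[1] <- rain[1]
  for (t in seq_along(rain)[-1]) {
    out[t] <- if (!is.na(rain[t]) && rain[t] == 0) 0 else out[t - 1] + rain[t]
  }
  out
}

#' Log-transform solar UVB radiation
#'
#' UVB varies over orders of magnitude between night and day, so it enters
#' the model on the log scale; a floor (default 1 J/m2) guards the night-time
#' zeros.
#'
#' @param uvb radiation values (J/m2), non-negative.
#' @param floor lower bound applied before taking logs.
#' @return `log(pmax(uvb, floor))`.
#' @export
log_transform_uvb <- function(uvb, floor = 1.0) {
  if (any(uvb < 0, na.rm = TRUE)) stop("UVB must be non-negative")
  log(pmax(uvb, floor))
}

#' Match monitoring stations to their nearest weather station
#'
#' Each air-quality station is mapped to the weather station at minimum
#' great-circle distance; ties break to the lowest index.
#'
#' @param air locations of air-quality stations ([spatial_locations()]).
#' @param weather locations of weather stations.
#' @return integer vector: for each air station, the row index of its
#'   matched weather station.
#' @export
match_weather_stations <- function(air, weather) {
  if (is.null(weather) || nrow(weather) == 0L) {
    stop("no weather stations to match against")
  }
  vapply(seq_len(nrow(air)), function(i) {
    d <- geodesic_km(air[rep(i, nrow(weather)), , drop = FALSE], weather)
    which.min(d)  # which.min takes the first (lowest index) on ties
  }, integer(1))
}
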