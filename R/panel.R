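#' Hourly station panel cube
#'
#' Container for a response and covariates observed on a full
#' station x day x hour grid, with explicit missingness.  `y` is an
#' `n x T x q` array (stations, days, hours-of-day), `X` an `n x T x q x b`
#' covariate array, `locations` one row per station, and `missing` a logical
#' `n x T x q` mask that is `TRUE` where the response (or any covariate) is
#' unavailable.
#'
#' @param y numeric array `n x T x q`; entries at missing cells may be `NA`.
#' @param X numeric array `n x T x q x b` (use `b = 0` via
#'   `array(dim = c(n, T, q, 0))` for a covariate-free panel).
#' @param locations data.frame with columns `station`, `lat`, `lon`.
#' @param covariate_names character vector of length `b`.
#' @param missing optional logical array `n x T x q`; defaults to cells where
#'   `y` or any covariate is `NA`.
#' @param dates optional vector labelling the day index.
#' @param hours hour points of the within-day grid (default `1:q`).
#' @return object of class `panel_cube`.
#' @export
panel_cube <- function(y, X, locations, covariate_names = character(),
                       missing = NULL, dates = NULL, hours = NULL) {
  stopifnot(is.array(y), length(dim(y)) == 3L)
  n <- dim(y)[1]; T_ <- dim(y)[2]; q <- dim(y)[3]
  stopifnot(is.array(X), length(dim(X)) == 4L,
            all(dim(X)[1:3] == c(n, T_, q)))
  b <- dim(X)[4]
  if (length(covariate_names) != b) {
    stop("'covariate_names' must have one entry per covariate slice of X")
  }
  if (nrow(locations) != n) stop("'locations' must have one row per station")
  if (is.null(locations$station)) locations$station <- seq_len(n)
  spatial_locations(locations$lat, locations$lon)  # validates ranges
  if (is.null(missing)) {
    missing <- is.na(y)
    if (b > 0) missing <- missing | apply(is.na(X), 1:3, any)
  }
  stopifnot(is.logical(missing), all(dim(missing) == dim(y)))
  if (any(!missing & !is.finite(y))) {
    stop("non-missing response values must be finite")
  }
  if (is.null(hours)) hours <- seq_len(q)
  if (is.null(dates)) dates <- seq_len(T_)
  structure(
    list(y = y, X = X, locations = locations,
         covariate_names = as.character(covariate_names),
         missing = missing, dates = dates, hours = as.numeric(hours)),
    class = "panel_cube"
  )
}

#' @export
print.panel_cube <- function(x, ...) {
  d <- dim(x$y)
  cat(sprintf(
    "panel_cube: %d stations x %d days x %d hours, %d covariate(s), %.1f%% missing\n",
    d[1], d[2], d[3], dim(x$X)[4], 100 * mean(x$missing)))
  if (length(x$covariate_names)) {
    cat("covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.panel_cube <- function(x) dim(x$y)

#' Subset a panel cube by station
#'
#' @param cube a [panel_cube()].
#' @param stations integer indices of stations to keep.
#' @return a [panel_cube()] restricted to those stations.
#' @export
subset_stations <- function(cube, stations) {
  panel_cube(
    y = cube$y[stations, , , drop = FALSE],
    X = cube$X[stations, , , , drop = FALSE],
    locations = cube$locations[stations, , drop = FALSE],
    covariate_names = cube$covariate_names,
    missing = cube$missing[stations, , , drop = FALSE],
    dates = cube$dates, hours = cube$hours
  )
}

#' Read a long-format hourly panel CSV into a cube
#'
#' Expects one row per (station, date, hour).  Rows absent from the full
#' station x date x hour grid become missing cells.  Stations are ordered by
#' id and days by date.
#'
#' @param path CSV file path.
#' @param schema named list mapping roles to column names; roles `station`,
#'   `lat`, `lon`, `date`, `hour`, `response` are required, and `covariates`
#'   is a character vector of covariate columns (possibly empty).
#' @return a [panel_cube()].
#' @export
load_panel_csv <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  need <- c("station", "lat", "lon", "date", "hour", "response")
  if (!all(need %in% names(schema))) {
    stop("schema must name columns for: ", paste(need, collapse = ", "))
  }
  covs <- schema$covariates %||% character()
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no records in ", path)
  cols <- c(unlist(schema[need]), covs)
  miss_cols <- setdiff(cols, names(df))
  if (length(miss_cols)) stop("columns missing from CSV: ",
                              paste(miss_cols, collapse = ", "))

  st <- df[[schema$station]]
  date <- df[[schema$date]]
  hour <- as.numeric(df[[schema$hour]])

  key <- paste(st, date, hour, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    k <- strsplit(key[which(dup)[1]], "\r")[[1]]
    stop(sprintf("duplicate record for station '%s', date '%s', hour %s",
                 k[1], k[2], k[3]))
  }

  stations <- sort(unique(st))
  dates <- sort(unique(date))
  hour_grid <- sort(unique(hour))
  n <- length(stations); T_ <- length(dates); q <- length(hour_grid)

  # per-station coordinates must be consistent
  loc <- unique(df[, c(schema$station, schema$lat, schema$lon)])
  if (anyDuplicated(loc[[schema$station]])) {
    bad <- loc[[schema$station]][duplicated(loc[[schema$station]])][1]
    stop("inconsistent lat/lon for station '", bad, "'")
  }
  loc <- loc[match(stations, loc[[schema$station]]), ]
  locations <- data.frame(station = stations,
                          lat = as.numeric(loc[[schema$lat]]),
                          lon = as.numeric(loc[[schema$lon]]))

  i <- match(st, stations)
  t <- match(date, dates)
  h <- match(hour, hour_grid)
  idx3 <- cbind(i, t, h)

  y <- array(NA_real_, c(n, T_, q))
  y[idx3] <- as.numeric(df[[schema$response]])
  b <- length(covs)
  X <- array(NA_real_, c(n, T_, q, b))
  for (j in seq_len(b)) {
    X[cbind(idx3, j)] <- as.numeric(df[[covs[j]]])
  }
  panel_cube(y, X, locations, covariate_names = covs, dates = dates,
             hours = hour_grid)
}

#' Write a panel cube to a long-format CSV
#'
#' Emits one row per observed (station, date, hour) cell; missing cells are
#' omitted, so a round trip through [load_panel_csv()] reproduces `y`, `X`
#' and the missingness mask exactly.
#'
#' @param cube a [panel_cube()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(cube, path) {
  d <- dim(cube$y)
  grid <- expand.grid(h = seq_len(d[3]), t = seq_len(d[2]), i = seq_len(d[1]))
  idx <- cbind(grid$i, grid$t, grid$h)
  keep <- !cube$missing[idx]
  idx <- idx[keep, , drop = FALSE]
  out <- data.frame(
    station = cube$locations$station[idx[, 1]],
    lat = cube$locations$lat[idx[, 1]],
    lon = cube$locations$lon[idx[, 1]],
    date = cube$dates[idx[, 2]],
    hour = cube$hours[idx[, 3]],
    y = cube$y[idx]
  )
  for (j in seq_along(cube$covariate_names)) {
    out[[cube$covariate_names[j]]] <- cube$X[cbind(idx, j)]
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

default_schema <- function(covariates = character()) {
  list(station = "station", lat = "lat", lon = "lon", date = "date",
       hour = "hour", response = "y", covariates = covariates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
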