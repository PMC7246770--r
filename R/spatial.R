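#' Spatial locations on the sphere
#'
#' Light validation helper: a locations object is a data.frame with numeric
#' `lat` in \[-90, 90\] and `lon` in \[-180, 180\] (degrees), one row per
#' station.
#'
#' @param lat,lon numeric vectors of equal length, degrees.
#' @return data.frame with columns `lat`, `lon`.
#' @export
spatial_locations <- function(lat, lon) {
  stopifnot(length(lat) == length(lon))
  if (any(!is.finite(lat)) || any(abs(lat) > 90)) {
    stop("latitude must be finite and within [-90, 90]")
  }
  if (any(!is.finite(lon)) || any(abs(lon) > 180)) {
    stop("longitude must be finite and within [-180, 180]")
  }
  data.frame(lat = as.numeric(lat), lon = as.numeric(lon))
}

EARTH_RADIUS_KM <- 6371.0

#' Great-circle distance in kilometres
#'
#' Haversine distance with Earth radius 6371 km, vectorised over rows.
#'
#' @param a,b locations as created by [spatial_locations()] (recycled to a
#'   common number of rows).
#' @return numeric vector of distances in km.
#' @export
geodesic_km <- function(a, b) {
  geosphere::distHaversine(
    cbind(a$lon, a$lat), cbind(b$lon, b$lat), r = EARTH_RADIUS_KM
  )
}

#' Pairwise great-circle distance matrix (km)
#'
#' @param locs locations data.frame (`lat`, `lon`).
#' @return symmetric n x n matrix of distances in km, zero diagonal.
#' @export
distance_matrix_km <- function(locs) {
  d <- geosphere::distm(cbind(locs$lon, locs$lat),
                        fun = geosphere::distHaversine) / 1000 *
    (EARTH_RADIUS_KM / 6378.137)
  # distm has no radius argument; rescale from its default WGS84-equatorial
  # radius (6378137 m) to the 6371 km sphere used throughout.
  d
}

#' Exponential spatial correlation matrix
#'
#' \eqn{\rho(s, s'; \theta) = \exp(-d(s,s')/\theta)} with `d` the great-circle
#' distance in km.  Valid (positive definite) on the sphere for distinct
#' points; unit diagonal.
#'
#' @param locs locations data.frame, or a precomputed distance matrix in km.
#' @param theta positive range parameter in km.
#' @return n x n correlation matrix.
#' @export
correlation_matrix <- function(locs, theta) {
  if (length(theta) != 1L || !is.finite(theta) || theta <= 0) {
    stop("'theta' must be a positive scalar range in km")
  }
  D <- if (is.matrix(locs)) locs else distance_matrix_km(locs)
  exp(-D / theta)
}

#' Component-wise latent innovation covariance blocks
#'
#' The latent innovations are independent across components j with covariance
#' \eqn{v_j \rho(s, s'; \theta_j)}; the full np x np covariance is block
#' diagonal in these n x n blocks.
#'
#' @param locs locations data.frame or distance matrix (km).
#' @param v positive scale coefficients, one per latent component.
#' @param theta positive ranges in km, one per latent component.
#' @return list of `length(v)` covariance matrices.
#' @export
gamma_blocks <- function(locs, v, theta) {
  stopifnot(length(v) == length(theta))
  if (any(v < 0)) stop("'v' must be non-negative")
  D <- if (is.matrix(locs)) locs else distance_matrix_km(locs)
  lapply(seq_along(v), function(j) v[j] * correlation_matrix(D, theta[j]))
}

#' Stationary covariance of the latent AR(1) components
#'
#' Component j of the latent field evolves as an AR(1) in the day index with
#' transition `g[j]` and innovation covariance block `blocks[[j]]`; its
#' stationary covariance is `blocks[[j]] / (1 - g[j]^2)`.  Used as the initial
#' state law.
#'
#' @param g transition diagonals, all `|g| < 1`.
#' @param blocks innovation covariance blocks from [gamma_blocks()].
#' @return list of stationary covariance blocks.
#' @export
stationary_state_cov <- function(g, blocks) {
  stopifnot(length(g) == length(blocks))
  if (any(abs(g) >= 1)) stop("nonstationary: all |g| must be < 1")
  lapply(seq_along(g), function(j) blocks[[j]] / (1 - g[j]^2))
}

block_diag <- function(blocks) {
  sizes <- vapply(blocks, nrow, integer(1))
  out <- matrix(0, sum(sizes), sum(sizes))
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    out[idx, idx] <- b
    at <- at + nrow(b)
  }
  out
}
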