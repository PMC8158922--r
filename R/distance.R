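#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised over the
#' first pair; used for the 10-km station-association rule, pseudo-station
#' clustering and IDW interpolation.
#'
#' @param lat1,lon1,lat2,lon2 Decimal degrees; `lat1`/`lon1` recycle against
#'   `lat2`/`lon2`.
#' @return Distance(s) in kilometres.
#' @export
#' @examples
#' haversine_km(36.7, -122.0, 37.7, -123.0)
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# pairwise haversine distance matrix (km) for small point sets
haversine_matrix <- function(lat, lon) {
  n <- length(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d[i, ] <- haversine_km(lat[i], lon[i], lat, lon)
  }
  d[abs(d) < 1e-12] <- 0
  0.5 * (d + t(d))
}

# centroid of points on the sphere via the mean of unit vectors
spherical_centroid <- function(lat, lon) {
  to_rad <- pi / 180
  phi <- lat * to_rad
  lam <- lon * to_rad
  x <- mean(cos(phi) * cos(lam))
  y <- mean(cos(phi) * sin(lam))
  z <- mean(sin(phi))
  h <- sqrt(x^2 + y^2)
  c(lat = atan2(z, h) / to_rad, lon = atan2(y, x) / to_rad)
}
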