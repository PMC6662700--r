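#' Rhumb-line (loxodromic) distance
#'
#' Constant-bearing distance between two points on a sphere of radius
#' 6,371,000 m. Used for inter-ping distances and speed derivation, as is
#' conventional when cleaning vessel-monitoring tracks. Vectorized over
#' coordinates.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees; latitudes must
#'   satisfy |lat| < 90.
#' @param radius sphere radius in metres.
#' @return distance in metres.
#' @export
rhumb_distance <- function(lon1, lat1, lon2, lat2, radius = 6371000) {
  if (any(!is.finite(c(lon1, lat1, lon2, lat2)))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (any(abs(c(lat1, lat2)) >= 90)) {
    stop("rhumb distance undefined at the poles (|lat| must be < 90)", call. = FALSE)
  }
  phi1 <- lat1 * pi / 180; phi2 <- lat2 * pi / 180
  dphi <- phi2 - phi1
  dlam <- (lon2 - lon1) * pi / 180
  dlam <- ((dlam + pi) %% (2 * pi)) - pi
  dpsi <- log(tan(pi / 4 + phi2 / 2) / tan(pi / 4 + phi1 / 2))
  q <- ifelse(abs(dpsi) > 1e-12, dphi / dpsi, cos(phi1))
  radius * sqrt(dphi^2 + (q * dlam)^2)
}

# rhumb bearing in degrees [0, 360); NA for coincident points
rhumb_bearing <- function(lon1, lat1, lon2, lat2) {
  phi1 <- lat1 * pi / 180; phi2 <- lat2 * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  dlam <- ((dlam + pi) %% (2 * pi)) - pi
  dpsi <- log(tan(pi / 4 + phi2 / 2) / tan(pi / 4 + phi1 / 2))
  b <- atan2(dlam, dpsi) * 180 / pi
  b <- (b + 360) %% 360
  b[abs(dlam) < 1e-15 & abs(dpsi) < 1e-15] <- NA_real_
  b
}
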