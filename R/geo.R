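#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km, the radius conventionally
#' used for movement-track metrics. Vectorised over rows.
#'
#' @param a,b Two-column matrices or length-2 vectors of (lon, lat) in decimal
#'   degrees WGS84.
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(c(0, 0), c(1, 0)) # one degree along a meridian, ~111.19 km
#' @export
haversine_km <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  geosphere::distHaversine(a, b, r = 6371000) / 1000
}

#' Initial great-circle bearing between fixes
#'
#' @param a,b (lon, lat) matrices or vectors, degrees.
#' @return Bearing in degrees clockwise from true north, in [0, 360).
#' @export
bearing_deg <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  (geosphere::bearing(a, b) + 360) %% 360
}

#' Circular mean and standard deviation of angles
#'
#' Mean direction from the resultant vector; dispersion is the Mardia circular
#' standard deviation sqrt(-2 log Rbar), reported in degrees. Wraparound is
#' respected (359 and 1 average to 0).
#'
#' @param deg Angles in degrees.
#' @param w Optional non-negative weights.
#' @return List with `mean` (degrees in [0, 360)) and `sd` (degrees).
#' @export
circular_mean_deg <- function(deg, w = NULL) {
  rad <- deg * pi / 180
  if (is.null(w)) w <- rep(1, length(rad))
  s <- sum(w * sin(rad)) / sum(w)
  c_ <- sum(w * cos(rad)) / sum(w)
  rbar <- sqrt(s^2 + c_^2)
  mu <- (atan2(s, c_) * 180 / pi + 360) %% 360
  sd <- if (rbar > 0) sqrt(-2 * log(rbar)) * 180 / pi else Inf
  list(mean = mu, sd = sd)
}

## Local azimuthal equidistant projection --------------------------------------
## Distances from the projection centre are exact; at platform scale (~50 km)
## area distortion is far below 0.1%, adequate for km^2 home-range reporting.

.R_EARTH_M <- 6371000

#' Project lon/lat to local azimuthal-equidistant plane coordinates
#'
#' @param lonlat Two-column matrix (lon, lat) in degrees.
#' @param center Projection centre (lon, lat); defaults to the centroid.
#' @return List with `xy` (matrix, metres) and `center`.
#' @export
aeqd_project <- function(lonlat, center = NULL) {
  lonlat <- matrix(as.numeric(unlist(lonlat)), ncol = 2)
  if (is.null(center)) center <- colMeans(lonlat)
  lon0 <- center[1] * pi / 180
  lat0 <- center[2] * pi / 180
  lon <- lonlat[, 1] * pi / 180
  lat <- lonlat[, 2] * pi / 180
  dlon <- lon - lon0
  cosc <- sin(lat0) * sin(lat) + cos(lat0) * cos(lat) * cos(dlon)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ <- acos(cosc)
  k <- ifelse(c_ < 1e-12, 1, c_ / sin(c_))
  x <- .R_EARTH_M * k * cos(lat) * sin(dlon)
  y <- .R_EARTH_M * k * (cos(lat0) * sin(lat) - sin(lat0) * cos(lat) * cos(dlon))
  list(xy = cbind(x = x, y = y), center = c(center[1], center[2]))
}

#' Inverse of [aeqd_project()]
#'
#' @param xy Two-column matrix of planar coordinates in metres.
#' @param center Projection centre (lon, lat) in degrees.
#' @return Two-column matrix (lon, lat) in degrees.
#' @export
aeqd_inverse <- function(xy, center) {
  xy <- matrix(as.numeric(unlist(xy)), ncol = 2)
  lon0 <- center[1] * pi / 180
  lat0 <- center[2] * pi / 180
  rho <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  c_ <- rho / .R_EARTH_M
  lat <- ifelse(rho < 1e-9, lat0,
                asin(cos(c_) * sin(lat0) + xy[, 2] * sin(c_) * cos(lat0) / pmax(rho, 1e-12)))
  lon <- ifelse(rho < 1e-9, lon0,
                lon0 + atan2(xy[, 1] * sin(c_),
                             rho * cos(c_) * cos(lat0) - xy[, 2] * sin(c_) * sin(lat0)))
  cbind(lon = lon * 180 / pi, lat = lat * 180 / pi)
}

#' Shoelace area of a planar polygon
#'
#' @param xy Two-column matrix of vertices (metres); closure optional.
#' @return Absolute area in square metres.
#' @export
polygon_area_m2 <- function(xy) {
  xy <- matrix(as.numeric(unlist(xy)), ncol = 2)
  n <- nrow(xy)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}

#' Point-in-polygon test
#'
#' Thin wrapper over [mgcv::in.out()] on one polygon ring.
#'
#' @param pts Two-column matrix of query points.
#' @param poly Two-column matrix of polygon vertices.
#' @return Logical vector.
#' @export
points_in_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(unlist(pts)), ncol = 2)
  poly <- matrix(as.numeric(unlist(poly)), ncol = 2)
  # in.out needs a closed boundary
  if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  mgcv::in.out(poly, pts)
}

## Solar position ---------------------------------------------------------------

#' Solar elevation angle
#'
#' Low-precision NOAA-style solar position: fractional year from the UTC
#' timestamp, declination and equation-of-time series expansions, hour angle
#' from apparent solar time. Accuracy a fraction of a degree, ample for
#' day/night classification.
#'
#' @param time POSIXct, UTC.
#' @param lon,lat Position in degrees.
#' @return Elevation of the sun's centre above the horizon, degrees.
#' @export
solar_elevation <- function(time, lon, lat) {
  t <- as.POSIXlt(time, tz = "UTC")
  doy <- t$yday + 1
  hour_utc <- t$hour + t$min / 60 + t$sec / 3600
  gamma <- 2 * pi / 365 * (doy - 1 + (hour_utc - 12) / 24)
  decl <- 0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gamma) - 0.032077 * sin(gamma) -
    0.014615 * cos(2 * gamma) - 0.040849 * sin(2 * gamma))
  tst <- (hour_utc * 60 + eqtime + 4 * lon) %% 1440
  ha <- (tst / 4 - 180) * pi / 180
  latr <- lat * pi / 180
  cosz <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  cosz <- pmin(1, pmax(-1, cosz))
  90 - acos(cosz) * 180 / pi
}

#' Classify fixes by photoperiod
#'
#' Day when the centre of the sun is above the horizon at the fix position and
#' time; night otherwise.
#'
#' @inheritParams solar_elevation
#' @return Character vector, "day" or "night".
#' @export
photoperiod <- function(time, lon, lat) {
  ifelse(solar_elevation(time, lon, lat) > 0, "day", "night")
}
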