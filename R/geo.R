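#' @title Spherical geometry primitives
#' @description Great-circle helpers on the spherical Earth used throughout the
#'   dead-reckoning machinery. All angles are degrees; distances are metres.
#'   The Earth radius is fixed at 6,371,000 m, the value conventional for
#'   haversine work in biologging.
#' @name geo-primitives
NULL

#' Mean Earth radius (metres) used for all spherical computations.
#' @keywords internal
.EARTH_RADIUS_M <- 6371000

.deg2rad <- function(x) x * (pi / 180)
.rad2deg <- function(x) x * (180 / pi)

#' Wrap headings to [0, 360)
#'
#' @param h heading(s) in degrees, any real value.
#' @return headings in `[0, 360)`, degrees clockwise from North.
#' @export
wrap_heading <- function(h) {
  r <- h %% 360
  r[r == 360] <- 0  # guard the floating-point case (-eps %% 360 == 360)
  r
}

#' Wrap signed angles to (-180, 180]
#'
#' Used for heading correction factors, which are signed rotations.
#'
#' @param x angle(s) in degrees.
#' @return angles wrapped into `(-180, 180]`.
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Great-circle (haversine) distance
#'
#' Distance along the surface of a spherical Earth (R = 6,371,000 m), the
#' standard 2-D distance for net-error and distance-moved metrics.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (WGS-84);
#'   vectorised and recycled.
#' @return distance(s) in metres.
#' @examples
#' haversine(0, 0, 0, 1)   # one degree of longitude on the equator
#' @export
haversine <- function(lat1, lon1, lat2, lon2) {
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dphi <- .deg2rad(lat2 - lat1)
  dlam <- .deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * .EARTH_RADIUS_M * asin(sqrt(a))
}

#' Initial great-circle bearing
#'
#' @inheritParams haversine
#' @return bearing(s) in degrees clockwise from true North, `[0, 360)`.
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dlam <- .deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam)
  wrap_heading(.rad2deg(atan2(y, x)))
}

#' Spherical destination point ("forward step")
#'
#' Moves a position a given distance along a given bearing on the spherical
#' Earth; this is the geodesic realisation of one dead-reckoning travel-vector
#' step.
#'
#' @param lat,lon start coordinates, decimal degrees.
#' @param heading bearing in degrees clockwise from true North.
#' @param distance distance in metres, `>= 0`.
#' @return a list with elements `lat` and `lon` (degrees, `lon` in
#'   `(-180, 180]`). Vectorised over all arguments.
#' @export
forward_step <- function(lat, lon, heading, distance) {
  stopifnot(all(is.finite(lat)), all(is.finite(lon)),
            all(is.finite(heading)), all(is.finite(distance)))
  if (any(distance < 0)) stop("forward_step: distance must be >= 0")
  phi1 <- .deg2rad(lat)
  lam1 <- .deg2rad(lon)
  th <- .deg2rad(heading)
  delta <- distance / .EARTH_RADIUS_M
  sphi2 <- sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(th)
  sphi2 <- pmin(pmax(sphi2, -1), 1)
  phi2 <- asin(sphi2)
  lam2 <- lam1 + atan2(sin(th) * sin(delta) * cos(phi1),
                       cos(delta) - sin(phi1) * sphi2)
  lon2 <- .rad2deg(lam2)
  lon2 <- ((lon2 + 180) %% 360) - 180
  lon2[lon2 == -180] <- 180
  list(lat = .rad2deg(phi2), lon = lon2)
}

# Local tangent ("equirectangular") plane about a reference position.
# x = east metres, y = north metres. Exact inverse at any projected point;
# used where planar exactness matters (segment-wise drift correction).
.to_plane <- function(lat, lon, lat0, lon0) {
  k <- .EARTH_RADIUS_M * pi / 180
  dlon <- lon - lon0
  dlon <- ((dlon + 180) %% 360) - 180
  list(x = dlon * cos(.deg2rad(lat0)) * k,
       y = (lat - lat0) * k)
}

.from_plane <- function(x, y, lat0, lon0) {
  k <- .EARTH_RADIUS_M * pi / 180
  lat <- lat0 + y / k
  lon <- lon0 + x / (k * cos(.deg2rad(lat0)))
  lon <- ((lon + 180) %% 360) - 180
  lon[lon == -180] <- 180
  list(lat = lat, lon = lon)
}

#' Geodetic to Earth-centred Cartesian (ECEF) coordinates
#'
#' Converts WGS-84 geodetic coordinates plus a vertical offset to Earth-centred,
#' Earth-fixed Cartesian coordinates, honouring the oblate spheroid
#' (a = 6,378,137 m, f = 1/298.257223563). Used for 3-D distance moved, where
#' straight-line (Pythagorean) distances between Cartesian positions are
#' summed.
#'
#' @param lat,lon decimal degrees.
#' @param z vertical coordinate in metres: depth (positive down) for
#'   `medium = "water"`, altitude (positive up) for `medium = "air"`, ignored
#'   sign-wise for `medium = "land"` (treated as height above the ellipsoid).
#' @param medium one of `"land"`, `"water"`, `"air"`; controls the sign with
#'   which `z` enters the ellipsoidal height.
#' @return a data.frame with columns `x`, `y`, `z` in metres.
#' @export
geodetic_to_cartesian <- function(lat, lon, z = 0, medium = c("land", "water", "air")) {
  medium <- match.arg(medium)
  a <- 6378137
  f <- 1 / 298.257223563
  e2 <- f * (2 - f)
  h <- switch(medium, water = -z, air = z, land = z)
  phi <- .deg2rad(lat); lam <- .deg2rad(lon)
  N <- a / sqrt(1 - e2 * sin(phi)^2)
  data.frame(
    x = (N + h) * cos(phi) * cos(lam),
    y = (N + h) * cos(phi) * sin(lam),
    z = (N * (1 - e2) + h) * sin(phi)
  )
}
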