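# Independent oracles used across the suite.

# Earth magnetic field in the tag frame for a given attitude, built directly
# from rotation matrices (independent of the package's compass code).
simulate_tag_field <- function(yaw, pitch, roll, inclination = 60,
                               declination = 0, strength = 1) {
  d2r <- pi / 180
  f_e <- strength * c(cos(inclination * d2r) * cos(declination * d2r),
                      cos(inclination * d2r) * sin(declination * d2r),
                      -sin(inclination * d2r))          # (N, E, Up)
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  Ry <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                           3, 3, byrow = TRUE)
  Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)),
                           3, 3, byrow = TRUE)
  as.numeric(Rx(roll * d2r) %*% Ry(pitch * d2r) %*% Rz(yaw * d2r) %*% f_e)
}

# Gravity vector seen by the accelerometer at a given attitude (same frames).
simulate_tag_gravity <- function(pitch, roll) {
  simulate_tag_field(0, pitch, roll, inclination = 90, strength = 1) * -1
}

# Brute-force shrinking-window centred mean.
brute_running_mean <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

# Iterative ECEF -> geodetic inverse (WGS-84), oracle for the round trip.
ecef_to_geodetic <- function(x, y, z) {
  a <- 6378137; f <- 1 / 298.257223563; e2 <- f * (2 - f)
  lon <- atan2(y, x)
  p <- sqrt(x^2 + y^2)
  lat <- atan2(z, p * (1 - e2))
  for (i in 1:10) {
    N <- a / sqrt(1 - e2 * sin(lat)^2)
    h <- p / cos(lat) - N
    lat <- atan2(z, p * (1 - e2 * N / (N + h)))
  }
  N <- a / sqrt(1 - e2 * sin(lat)^2)
  c(lat = lat * 180 / pi, lon = lon * 180 / pi, h = p / cos(lat) - N)
}

# Random points on a sphere (fixed seed supplied by caller).
sphere_points <- function(n, centre = c(0, 0, 0), radii = c(1, 1, 1)) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  sweep(u %*% diag(radii), 2, centre, "+")
}

# Small constant-velocity IMU builder for unit tests.
flat_imu <- function(n = 120, fs = 1, az = 1, mx = 0.5, mz = -0.8) {
  t <- (seq_len(n) - 1) / fs
  imu_series(t, ax = rep(0, n), ay = rep(0, n), az = rep(az, n),
             mx = rep(mx, n), my = rep(0, n), mz = rep(mz, n))
}
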