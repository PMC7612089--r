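make_imu <- function(t, a, m, pressure = NULL) {
  imu_series(t, a[, 1], a[, 2], a[, 3], m[, 1], m[, 2], m[, 3], pressure)
}

test_that("static/dynamic separation reconstructs raw exactly and finds the mean", {
  n <- 200; fs <- 10
  t <- (seq_len(n) - 1) / fs
  # constant raw: static is the constant, dynamic zero
  imu <- flat_imu(n, fs)
  sp <- separate_acceleration(imu, 2)
  expect_equal(sp$static[, 3], rep(1, n))
  expect_equal(sp$dynamic, matrix(0, n, 3), ignore_attr = TRUE)
  # sine on top of gravity: window of an integer number of periods removes it
  a <- cbind(0, 0, 1 + 0.2 * sin(2 * pi * 2 * t))
  imu <- make_imu(t, a, a)
  sp <- separate_acceleration(imu, 2)
  mid <- 30:170
  expect_lt(max(abs(sp$static[mid, 3] - 1)), 0.01)
  expect_equal(sp$dynamic[mid, 3], a[mid, 3] - sp$static[mid, 3])
  # exact reconstruction on rough data
  set.seed(1)
  a <- matrix(rnorm(3 * n), n, 3)
  sp <- separate_acceleration(make_imu(t, a, a), 0.7)
  expect_equal(sp$static + sp$dynamic, a, tolerance = 1e-12, ignore_attr = TRUE)
  # window shorter than a sample: static == raw, with a warning
  expect_warning(sp0 <- separate_acceleration(make_imu(t, a, a), 0.01), "window")
  expect_equal(sp0$dynamic, matrix(0, n, 3), ignore_attr = TRUE)
})

test_that("VeDBA is the smoothed norm of dynamic acceleration", {
  n <- 100; fs <- 5
  sp <- structure(list(t = (1:n) / fs, static = matrix(0, n, 3),
                       dynamic = matrix(0, n, 3)),
                  fs = fs, class = "static_dynamic_split")
  expect_equal(compute_vedba(sp), rep(0, n))
  sp$dynamic <- matrix(rep(c(0.3, 0, 0.4), each = n), n, 3)
  expect_equal(compute_vedba(sp, smooth_s = 0), rep(0.5, n))
  set.seed(2)
  sp$dynamic <- matrix(rnorm(3 * n), n, 3)
  v <- compute_vedba(sp, smooth_s = 2)
  oracle <- brute_running_mean(sqrt(rowSums(sp$dynamic^2)), floor(2 * fs / 2))
  expect_equal(v, oracle, tolerance = 1e-12)
  expect_true(all(v >= 0))
})

test_that("pitch and roll are recovered from rotated gravity", {
  n <- 50; fs <- 1
  t <- seq_len(n) - 1
  flat <- separate_acceleration(flat_imu(n, fs), 2)
  pr <- estimate_pitch_roll(flat, smooth_s = 0)
  expect_equal(pr$pitch, rep(0, n))
  expect_equal(pr$roll, rep(0, n))
  # nose vertical
  a <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  pr <- estimate_pitch_roll(separate_acceleration(make_imu(t, a, a), 2), smooth_s = 0)
  expect_equal(pr$pitch, rep(90, n))
  # rotation-matrix oracle over a grid of attitudes
  for (pitch in c(-60, -15, 30, 75)) {
    for (roll in c(-120, -30, 45, 170)) {
      g <- simulate_tag_gravity(pitch, roll)
      a <- matrix(rep(g, each = n), n, 3)
      pr <- estimate_pitch_roll(separate_acceleration(make_imu(t, a, a), 2),
                                smooth_s = 0)
      expect_equal(pr$pitch[1], pitch, tolerance = 1e-9)
      expect_equal(pr$roll[1], roll, tolerance = 1e-9)
    }
  }
  # unreliable samples carry the last reliable value forward
  a <- matrix(rep(c(0, 0, 1), each = 10), 10, 3)
  a[6, ] <- c(0.01, 0, 0.01)   # norm << 0.1 g
  sp <- separate_acceleration(make_imu(1:10, a, a), 1)
  pr <- estimate_pitch_roll(sp, smooth_s = 0)
  expect_true(pr$unreliable[6])
  expect_equal(pr$pitch[6], pr$pitch[5])
  a[, 3] <- 0.01; a[, 1] <- 0
  expect_error(estimate_pitch_roll(separate_acceleration(make_imu(1:10, a, a), 1)),
               "unreliable")
})

test_that("magnetometer calibration recovers hard-iron offsets and soft-iron shape", {
  set.seed(7)
  pts <- sphere_points(500)
  cal <- calibrate_magnetometer(pts)
  expect_equal(cal$hard_iron_offset, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(cal$soft_iron_matrix, diag(3))
  # translated sphere: offset recovered
  b <- c(0.3, -0.2, 0.45)
  cal <- calibrate_magnetometer(sweep(pts, 2, b, "+"))
  expect_equal(cal$hard_iron_offset, b, tolerance = 1e-6)
  # anisotropic scaling: full fit restores constant field norm
  distorted <- sweep(pts %*% diag(c(1, 2, 1)), 2, b, "+")
  cal <- calibrate_magnetometer(distorted, fit_soft_iron = TRUE)
  corrected <- apply_calibration(distorted, cal)
  nrm <- sqrt(rowSums(corrected^2))
  expect_lt(stats::sd(nrm) / mean(nrm), 1e-6)
  raw_nrm <- sqrt(rowSums(distorted^2))
  expect_lt(stats::sd(nrm) / mean(nrm), stats::sd(raw_nrm) / mean(raw_nrm))
  # degenerate coverage names the deficient axis
  planar <- cbind(pts[, 1], pts[, 2], 0)
  expect_error(calibrate_magnetometer(planar), "z axis")
})

test_that("tilt-compensated heading inverts a forward-simulated field", {
  cal0 <- calibration_model()
  flat <- data.frame(pitch = 0, roll = 0)
  m_north <- simulate_tag_field(0, 0, 0)
  h <- tilt_compensated_heading(flat, matrix(m_north, 1), cal0, smooth_s = 0)
  expect_equal(h$heading, 0, tolerance = 1e-9)
  m_yawed <- simulate_tag_field(90, 0, 0)
  h <- tilt_compensated_heading(flat, matrix(m_yawed, 1), cal0, smooth_s = 0)
  expect_equal(h$heading, 90, tolerance = 1e-9)
  cal10 <- calibration_model(declination = 10)
  h <- tilt_compensated_heading(flat, matrix(m_yawed, 1), cal10, smooth_s = 0)
  expect_equal(h$heading, 100, tolerance = 1e-9)
  # attitude grid: yaw recovered to 1e-6 degrees for |pitch| <= 80
  for (yaw in c(1, 137.3, 222.2, 359)) {
    for (pitch in c(-80, -30, 0, 30, 80)) {
      for (roll in c(-90, 0, 20, 120)) {
        m <- simulate_tag_field(yaw, pitch, roll, inclination = 60)
        o <- data.frame(pitch = pitch, roll = roll)
        h <- tilt_compensated_heading(o, matrix(m, 1), cal0, smooth_s = 0)
        expect_equal(h$heading, yaw, tolerance = 1e-6)
      }
    }
  }
  # circular smoothing does not average across the 0/360 wrap incorrectly
  hseq <- c(350, 355, 0, 5, 10)
  m <- t(vapply(hseq, function(y) simulate_tag_field(y, 0, 0), numeric(3)))
  o <- data.frame(pitch = rep(0, 5), roll = rep(0, 5))
  sm <- tilt_compensated_heading(o, m, cal0, smooth_s = 5, fs = 1)
  expect_equal(sm$heading[3], 0, tolerance = 1e-9)
  expect_true(all(pmin(sm$heading, 360 - sm$heading) <= 10 + 1e-9))
  # gimbal guard flags and carries forward
  m2 <- rbind(simulate_tag_field(40, 0, 0), simulate_tag_field(40, 89.9, 0))
  o2 <- data.frame(pitch = c(0, 89.9), roll = c(0, 0))
  h2 <- tilt_compensated_heading(o2, m2, cal0, smooth_s = 0)
  expect_true(h2$flagged[2])
  expect_equal(h2$heading[2], h2$heading[1])
})

test_that("tag rotation preserves norms and round-trips", {
  imu <- flat_imu(20)
  ident <- apply_tag_rotation(imu, calibration_model())
  expect_equal(as.data.frame(ident), as.data.frame(imu))
  # 180-degree roll flips sway and heave
  R180 <- diag(c(1, -1, -1))
  r <- apply_tag_rotation(imu, calibration_model(tag_rotation = R180))
  expect_equal(r$az, -imu$az)
  expect_equal(r$mz, -imu$mz)
  # random rotation then its inverse restores the input
  set.seed(9)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  fwd <- apply_tag_rotation(imu, calibration_model(tag_rotation = q))
  back <- apply_tag_rotation(fwd, calibration_model(tag_rotation = t(q)))
  expect_equal(as.data.frame(back), as.data.frame(imu), tolerance = 1e-12)
  expect_equal(sqrt(fwd$ax^2 + fwd$ay^2 + fwd$az^2),
               sqrt(imu$ax^2 + imu$ay^2 + imu$az^2), tolerance = 1e-12)
  expect_error(calibration_model(tag_rotation = diag(c(2, 1, 1))), "orthonormal")
})

test_that("asymmetric least squares baseline hugs the lower envelope", {
  expect_equal(pressure_baseline(rep(7, 50)), rep(7, 50), tolerance = 1e-6)
  # linear ramp + positive dive excursions
  n <- 600
  t <- seq_len(n)
  ramp <- 1000 + 0.01 * t
  dives <- numeric(n)
  for (s in seq(50, 550, by = 100)) dives[s:(s + 30)] <- 40 * sin(seq(0, pi, length.out = 31))
  bl <- pressure_baseline(ramp + dives, smoothness = 1e5, asymmetry = 0.01)
  expect_lt(max(abs(bl - ramp)), 0.02 * 40)
  expect_equal((ramp + dives - bl) - dives, ramp - bl, tolerance = 1e-12)
})

test_that("pressure converts to depth and barometric altitude", {
  p <- c(1000, 1005, 1020)
  expect_equal(pressure_to_vertical(p, p, "water"), c(0, 0, 0))
  expect_equal(pressure_to_vertical(1000 + c(0, 100, 250), rep(1000, 3), "water"),
               c(0, 1, 2.5))
  # baseline overshoot never yields negative depth
  expect_equal(pressure_to_vertical(c(999, 1000), rep(1000, 2), "water"), c(0, 0))
  expect_equal(pressure_to_vertical(1013.25, medium = "air", reference = 1013.25), 0)
  # closed form: P chosen so altitude is exactly 100 m
  p100 <- 1013.25 * (1 - 100 / 44330)^(1 / 0.1903)
  expect_equal(pressure_to_vertical(p100, medium = "air", reference = 1013.25),
               100, tolerance = 1e-9)
  expect_error(pressure_to_vertical(1000, medium = "air"), "reference")
})
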