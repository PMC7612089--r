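#' Separate static (gravity) and dynamic acceleration
#'
#' Splits raw tri-axial acceleration into a static (gravity) estimate -- a
#' centred running mean per axis -- and the dynamic residual generated by body
#' movement. The two components reconstruct the raw signal exactly per sample.
#'
#' @param imu an [imu_series()].
#' @param window_s running-mean window in seconds (default 2 s, matching the
#'   VeDBA smoothing window).
#' @return an object of class `static_dynamic_split`: a list with `static` and
#'   `dynamic` (n x 3 matrices, g), `t`, and attribute `fs`.
#' @export
separate_acceleration <- function(imu, window_s = 2) {
  stopifnot(inherits(imu, "imu_series"))
  if (window_s <= 0) stop("separate_acceleration: window_s must be > 0")
  fs <- attr(imu, "fs")
  raw <- cbind(ax = imu$ax, ay = imu$ay, az = imu$az)
  if (window_s < 1 / fs) {
    warning("separate_acceleration: window shorter than one sample; static = raw")
    static <- raw
  } else {
    static <- apply(raw, 2L, running_mean, window_s = window_s, fs = fs)
  }
  structure(list(t = imu$t, static = static, dynamic = raw - static),
            fs = fs, class = "static_dynamic_split")
}

#' @export
print.static_dynamic_split <- function(x, ...) {
  cat(sprintf("<static_dynamic_split> %d samples @ %.3g Hz\n",
              length(x$t), attr(x, "fs")))
  invisible(x)
}

#' Vector of the Dynamic Body Acceleration (VeDBA)
#'
#' Per-sample Euclidean norm of the dynamic acceleration vector,
#' sqrt(Dx^2 + Dy^2 + Dz^2), then smoothed with a centred running mean.
#' Smoothed VeDBA is the standard locomotion-intensity proxy used to
#' extrapolate speed for terrestrial movement.
#'
#' @param split a [separate_acceleration()] result.
#' @param smooth_s smoothing window in seconds (default 2 s); `0` disables
#'   smoothing.
#' @return numeric vector of VeDBA values in g (non-negative).
#' @export
compute_vedba <- function(split, smooth_s = 2) {
  stopifnot(inherits(split, "static_dynamic_split"))
  v <- sqrt(rowSums(split$dynamic^2))
  if (smooth_s > 0) v <- running_mean(v, smooth_s, attr(split, "fs"))
  v
}

#' Pitch and roll from static acceleration
#'
#' Posture (Euler angles) from the gravity estimate: pitch is the angle of the
#' surge axis above the horizon, `asin(static_surge / ||static||)`; roll is
#' `atan2(static_sway, static_heave)`. Samples whose static vector norm is
#' below 0.1 g (free-fall-like, centripetal contamination) are flagged
#' unreliable and carry the last reliable value forward.
#'
#' @param split a [separate_acceleration()] result.
#' @param smooth_s post-smoothing window in seconds for pitch and roll
#'   (default 1 s, i.e. within the conventional 1-2 s range); `0` disables.
#' @return a data.frame with columns `pitch` (degrees, `[-90, 90]`, positive
#'   nose-up), `roll` (degrees, `(-180, 180]`) and `unreliable` (logical).
#' @export
estimate_pitch_roll <- function(split, smooth_s = 1) {
  stopifnot(inherits(split, "static_dynamic_split"))
  s <- split$static
  nrm <- sqrt(rowSums(s^2))
  ok <- nrm > 0.1
  if (!any(ok)) stop("estimate_pitch_roll: all samples unreliable (static norm <= 0.1 g)")
  pitch <- .rad2deg(asin(pmin(pmax(s[, 1L] / nrm, -1), 1)))
  roll <- .rad2deg(atan2(s[, 2L], s[, 3L]))
  pitch <- .carry_forward(pitch, ok)
  roll <- .carry_forward(roll, ok)
  if (smooth_s > 0) {
    fs <- attr(split, "fs")
    pitch <- running_mean(pitch, smooth_s, fs)
    roll <- wrap_angle(.rolling_circular_mean(roll, smooth_s, fs))
  }
  data.frame(pitch = pitch, roll = roll, unreliable = !ok)
}

#' Construct a sensor calibration model
#'
#' Bundles the magnetometer distortion corrections (hard-iron offset,
#' soft-iron shape matrix), the magnetic declination and the tag-to-body
#' rotation applied when a tag is mounted off the animal's longitudinal axis.
#'
#' @param hard_iron_offset additive offset, length-3, magnetometer units.
#' @param soft_iron_matrix 3 x 3 symmetric positive-definite correction
#'   matrix; identity when only hard-iron correction is fitted.
#' @param declination magnetic declination in degrees, positive East; added to
#'   magnetic heading to obtain true heading.
#' @param tag_rotation 3 x 3 rotation matrix (orthonormal, det +1) mapping the
#'   tag frame to the body frame.
#' @return an object of class `calibration_model`.
#' @export
calibration_model <- function(hard_iron_offset = c(0, 0, 0),
                              soft_iron_matrix = diag(3),
                              declination = 0,
                              tag_rotation = diag(3)) {
  stopifnot(length(hard_iron_offset) == 3L, all(is.finite(hard_iron_offset)),
            is.matrix(soft_iron_matrix), all(dim(soft_iron_matrix) == 3L),
            is.matrix(tag_rotation), all(dim(tag_rotation) == 3L),
            is.finite(declination))
  if (max(abs(soft_iron_matrix - t(soft_iron_matrix))) > 1e-8 ||
      any(eigen(soft_iron_matrix, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("calibration_model: soft_iron_matrix must be symmetric positive-definite")
  }
  .check_rotation(tag_rotation)
  structure(list(hard_iron_offset = as.numeric(hard_iron_offset),
                 soft_iron_matrix = soft_iron_matrix,
                 declination = declination,
                 tag_rotation = tag_rotation),
            class = "calibration_model")
}

.check_rotation <- function(R) {
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8) {
    stop("rotation matrix must be orthonormal with determinant +1")
  }
  invisible(R)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(paste0("<calibration_model> hard-iron (%.4g, %.4g, %.4g), ",
                     "declination %+.2f deg, soft-iron %s, tag rotation %s\n"),
              x$hard_iron_offset[1L], x$hard_iron_offset[2L], x$hard_iron_offset[3L],
              x$declination,
              if (isTRUE(all.equal(x$soft_iron_matrix, diag(3)))) "identity" else "fitted",
              if (isTRUE(all.equal(x$tag_rotation, diag(3)))) "identity" else "set"))
  invisible(x)
}

#' Fit a magnetometer calibration
#'
#' Least-squares fit of the hard-iron offset (sphere centre) and, optionally,
#' the soft-iron shape (ellipsoid fit) from magnetometer data spanning diverse
#' orientations. Applying the fitted model maps readings onto a sphere scaled
#' to the mean field strength, reducing the coefficient of variation of the
#' per-sample field norm.
#'
#' @param imu an [imu_series()] (or a 3-column matrix of magnetometer
#'   readings) covering varied orientations.
#' @param fit_soft_iron if `TRUE`, fit the full ellipsoid (soft-iron) model;
#'   default fits the hard-iron offset only.
#' @param declination declination to store on the returned model (degrees,
#'   positive East).
#' @return a [calibration_model()].
#' @export
calibrate_magnetometer <- function(imu, fit_soft_iron = FALSE, declination = 0) {
  M <- if (inherits(imu, "imu_series")) cbind(imu$mx, imu$my, imu$mz) else as.matrix(imu)
  stopifnot(ncol(M) == 3L, nrow(M) >= 10L)
  ctr <- scale(M, center = TRUE, scale = FALSE)
  sv <- svd(ctr, nu = 0L)
  if (any(sv$d < 1e-9 * max(sv$d, 1e-300))) {
    axis <- c("x", "y", "z")[which.max(abs(sv$v[, which.min(sv$d)]))]
    stop("calibrate_magnetometer: degenerate orientation coverage along the ",
         axis, " axis")
  }
  if (!fit_soft_iron) {
    # Sphere fit: ||m - b||^2 = r^2 is linear in (b, r^2 - ||b||^2).
    A <- cbind(2 * M, 1)
    y <- rowSums(M^2)
    theta <- qr.solve(A, y)
    offset <- theta[1:3]
    soft <- diag(3)
  } else {
    # Algebraic ellipsoid fit: m'Qm + 2 q'm = 1.
    x <- M[, 1L]; y2 <- M[, 2L]; z <- M[, 3L]
    A <- cbind(x^2, y2^2, z^2, 2 * x * y2, 2 * x * z, 2 * y2 * z, 2 * x, 2 * y2, 2 * z)
    theta <- qr.solve(A, rep(1, nrow(M)))
    Q <- matrix(c(theta[1], theta[4], theta[5],
                  theta[4], theta[2], theta[6],
                  theta[5], theta[6], theta[3]), 3L, 3L)
    q <- theta[7:9]
    offset <- as.numeric(-solve(Q, q))
    s <- 1 + as.numeric(crossprod(offset, Q %*% offset)) + 2 * sum(q * offset)
    S <- Q / s                                  # (m - b)' S (m - b) = 1
    eg <- eigen(S, symmetric = TRUE)
    if (any(eg$values <= 0)) stop("calibrate_magnetometer: ellipsoid fit not positive-definite")
    W <- eg$vectors %*% diag(sqrt(eg$values)) %*% t(eg$vectors)
    # scale so the mean corrected norm equals the mean raw centred norm
    Fbar <- mean(sqrt(rowSums((ctr)^2)))
    soft <- W * Fbar
  }
  calibration_model(hard_iron_offset = offset, soft_iron_matrix = soft,
                    declination = declination)
}

#' Apply a magnetometer calibration
#'
#' @param mag n x 3 matrix (or `imu_series`) of raw magnetometer readings.
#' @param cal a [calibration_model()].
#' @return n x 3 matrix of corrected readings,
#'   `soft_iron_matrix %*% (m - hard_iron_offset)` per sample.
#' @export
apply_calibration <- function(mag, cal) {
  stopifnot(inherits(cal, "calibration_model"))
  M <- if (inherits(mag, "imu_series")) cbind(mag$mx, mag$my, mag$mz) else as.matrix(mag)
  sweep(M, 2L, cal$hard_iron_offset) %*% t(cal$soft_iron_matrix)
}

#' Rotate sensor axes from the tag frame to the body frame
#'
#' Pre-multiplies both acceleration and magnetism by the calibration's
#' `tag_rotation`, correcting for imperfect tag placement. Norms are
#' preserved.
#'
#' @param imu an [imu_series()].
#' @param cal a [calibration_model()] carrying the tag rotation.
#' @return a new [imu_series()] in the body frame.
#' @export
apply_tag_rotation <- function(imu, cal) {
  stopifnot(inherits(imu, "imu_series"), inherits(cal, "calibration_model"))
  R <- cal$tag_rotation
  .check_rotation(R)
  A <- cbind(imu$ax, imu$ay, imu$az) %*% t(R)
  M <- cbind(imu$mx, imu$my, imu$mz) %*% t(R)
  imu_series(imu$t, A[, 1L], A[, 2L], A[, 3L], M[, 1L], M[, 2L], M[, 3L],
             pressure = if ("pressure" %in% names(imu)) imu$pressure else NULL)
}

#' Tilt-compensated compass heading
#'
#' De-rotates the (calibrated) magnetic vector into the Earth's horizontal
#' plane using pitch and roll, then takes the arctangent of the horizontal
#' components to give heading in degrees clockwise from North; declination
#' (positive East) is added to convert magnetic to true heading, and the
#' result is post-smoothed with a rolling circular mean.
#'
#' Samples within 0.5 degrees of gimbal lock (|pitch| >= 89.5), or whose
#' de-rotated horizontal field is vanishingly small (pole-like inclination),
#' are flagged and carry the last reliable heading forward.
#'
#' @param orientation a data.frame with `pitch` and `roll` columns (degrees),
#'   as from [estimate_pitch_roll()].
#' @param mag_calibrated n x 3 matrix of calibrated body-frame magnetometer
#'   readings (see [apply_calibration()]).
#' @param cal a [calibration_model()] (supplies the declination).
#' @param smooth_s circular-mean smoothing window in seconds (default 1 s);
#'   `0` disables.
#' @param fs sampling frequency in Hz (required when `smooth_s > 0`).
#' @return a data.frame with columns `heading` (degrees, `[0, 360)`) and
#'   `flagged` (logical).
#' @export
tilt_compensated_heading <- function(orientation, mag_calibrated, cal,
                                     smooth_s = 1, fs = NULL) {
  stopifnot(inherits(cal, "calibration_model"))
  M <- as.matrix(mag_calibrated)
  stopifnot(ncol(M) == 3L, nrow(M) == nrow(orientation))
  th <- .deg2rad(orientation$pitch)
  ph <- .deg2rad(orientation$roll)
  # de-rotate roll then pitch: m1 = Ry(-pitch) Rx(-roll) m_body
  y2 <- cos(ph) * M[, 2L] - sin(ph) * M[, 3L]
  z2 <- sin(ph) * M[, 2L] + cos(ph) * M[, 3L]
  x1 <- cos(th) * M[, 1L] - sin(th) * z2
  y1 <- y2
  horiz <- sqrt(x1^2 + y1^2)
  total <- sqrt(rowSums(M^2))
  flagged <- abs(orientation$pitch) >= 89.5 | horiz < 1e-9 * pmax(total, 1e-300)
  h <- wrap_heading(.rad2deg(atan2(-y1, x1)) + cal$declination)
  h <- .carry_forward(h, !flagged)
  if (smooth_s > 0) {
    if (is.null(fs)) stop("tilt_compensated_heading: fs required when smooth_s > 0")
    h <- .rolling_circular_mean(h, smooth_s, fs)
  }
  data.frame(heading = h, flagged = flagged)
}

#' Baseline pressure drift by asymmetric least squares
#'
#' Estimates a slowly varying pressure baseline with a Whittaker smoother
#' under asymmetric weights (iteratively reweighted penalised least squares).
#' With asymmetry `p < 0.5` the baseline tracks the lower envelope of the
#' series, i.e. the surface pressure under positive dive excursions; the
#' baseline-subtracted series is then a drift-free depth-pressure signal.
#'
#' @param pressure numeric series, length >= 10.
#' @param smoothness penalty weight (lambda) on the squared second
#'   differences of the baseline; larger is stiffer. Default `1e6` suits
#'   1-Hz dive records with drift over hours.
#' @param asymmetry weight `p` in (0, 1) given to points above the baseline
#'   (default 0.01: excursions above are nearly ignored).
#' @param max_iter maximum weight-update iterations (default 20); if the
#'   baseline has not converged to `1e-8` in the sup norm by then, the last
#'   iterate is returned with a warning.
#' @return numeric baseline series, same length as `pressure`.
#' @export
pressure_baseline <- function(pressure, smoothness = 1e6, asymmetry = 0.01,
                              max_iter = 20L) {
  n <- length(pressure)
  if (n < 10L) stop("pressure_baseline: series length must be >= 10")
  stopifnot(smoothness > 0, asymmetry > 0, asymmetry < 1,
            all(is.finite(pressure)))
  D <- Matrix::diff(Matrix::Diagonal(n), differences = 2L)
  P <- smoothness * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- pressure
  for (i in seq_len(max_iter)) {
    W <- Matrix::Diagonal(n, w)
    z_new <- as.numeric(Matrix::solve(W + P, w * pressure))
    delta <- max(abs(z_new - z))
    z <- z_new
    w_new <- ifelse(pressure > z, asymmetry, 1 - asymmetry)
    if (delta < 1e-8) return(z)
    if (all(w_new == w) && i > 1L) return(z)
    w <- w_new
  }
  warning("pressure_baseline: no convergence in ", max_iter,
          " iterations; returning last iterate")
  z
}

#' Convert pressure to depth or altitude
#'
#' Water: depth (m, positive down) from baseline-subtracted hydrostatic
#' pressure at a configurable conversion (default 0.01 m per hPa, i.e.
#' 1 hPa is about 1 cm of water), clamped at >= 0. Air: barometric-formula
#' altitude `44330 * (1 - (P/P0)^0.1903)` against a reference sea-level
#' pressure series interpolated linearly in time.
#'
#' @param pressure pressure series (hPa or consistent units).
#' @param baseline baseline series from [pressure_baseline()] (water only).
#' @param medium `"water"` or `"air"`.
#' @param reference for air: either a single reference pressure `P0` or a
#'   data.frame with columns `t` and `p0` interpolated to `t_grid`.
#' @param t_grid sample times (needed when `reference` is a time series).
#' @param m_per_unit metres of depth per pressure unit (water; default 0.01
#'   m/hPa).
#' @return numeric `z` series: depth in metres (positive down) for water,
#'   altitude in metres (positive up) for air.
#' @export
pressure_to_vertical <- function(pressure, baseline = NULL,
                                 medium = c("water", "air"),
                                 reference = NULL, t_grid = NULL,
                                 m_per_unit = 0.01) {
  medium <- match.arg(medium)
  if (medium == "water") {
    if (is.null(baseline)) baseline <- rep(min(pressure), length(pressure))
    pmax((pressure - baseline) * m_per_unit, 0)
  } else {
    if (is.null(reference)) stop("pressure_to_vertical: reference pressure required for air")
    p0 <- if (is.data.frame(reference)) {
      if (is.null(t_grid)) stop("pressure_to_vertical: t_grid required for a reference series")
      stats::approx(reference$t, reference$p0, xout = t_grid, rule = 2)$y
    } else {
      rep(reference, length(pressure))
    }
    44330 * (1 - (pressure / p0)^0.1903)
  }
}
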