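#' Simulation configuration
#'
#' Describes a synthetic deployment: a state-switching correlated random walk
#' ground truth, the sensor streams consistent with it, and a noisy,
#' dropout-prone Verified Position record. All randomness derives from the
#' single `seed` via fixed per-stream offsets, so outputs are bitwise
#' reproducible.
#'
#' @param seed integer RNG seed.
#' @param duration_s simulated duration in seconds.
#' @param fs sampling frequency in Hz (1-40).
#' @param medium `"land"`, `"water"` or `"air"`.
#' @param states named list of behaviour states, each a list with
#'   `speed_mean` (m/s), `speed_cv`, `turn_sd_deg` (heading random-walk sd in
#'   degrees per sqrt(second)), `vz_mean` (m/s, in the medium's z convention),
#'   `dwell_mean_s`, and for diving states `max_depth_m`.
#' @param start numeric `c(lat, lon)` of the release position.
#' @param heading_bias systematic heading error injected into the sensor
#'   streams (degrees; emulates e.g. a yaw mounting offset).
#' @param speed_scale_error multiplicative error of the recovered speed
#'   (1 = unbiased).
#' @param vedba list `m_true`, `c_true` (the VeDBA-speed coefficients the
#'   dynamic acceleration is synthesised to satisfy) and `noise_sd` (g).
#' @param mag list `inclination` (deg, downward positive), `declination`
#'   (deg, positive East), `field_strength`, `hard_iron` (length-3 offset).
#' @param gps list `interval_s`, `error_sd_m` (per-component isotropic sd in
#'   the tangent plane) and `dropout_depth_m` (no fix while deeper; `NA`
#'   disables).
#' @param current `NULL`, or `list(type = "constant", u, v)`, or
#'   `list(type = "gyre", omega, center = c(lat, lon))` (solid-body rotation,
#'   rad/s about the centre).
#' @param pressure list `surface_hpa` and `drift_hpa_per_h` (linear sensor
#'   drift added to the synthetic pressure channel).
#' @param t0 epoch start time in seconds.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       duration_s = 3600,
                       fs = 1,
                       medium = c("land", "water", "air"),
                       states = list(travel = list(speed_mean = 1, speed_cv = 0.2,
                                                   turn_sd_deg = 8, vz_mean = 0,
                                                   dwell_mean_s = 300)),
                       start = c(-25.0, 20.0),
                       heading_bias = 0,
                       speed_scale_error = 1,
                       vedba = list(m_true = 2.5, c_true = 0, noise_sd = 0),
                       mag = list(inclination = 60, declination = 0,
                                  field_strength = 1, hard_iron = c(0, 0, 0)),
                       gps = list(interval_s = 1, error_sd_m = 0, dropout_depth_m = NA),
                       current = NULL,
                       pressure = list(surface_hpa = 1013.25, drift_hpa_per_h = 0),
                       t0 = 0) {
  medium <- match.arg(medium)
  stopifnot(fs >= 1, fs <= 40, duration_s > 0, length(states) >= 1L,
            !is.null(names(states)))
  for (st in states) {
    stopifnot(st$speed_mean >= 0, st$speed_cv >= 0, st$dwell_mean_s > 0)
  }
  structure(list(seed = as.integer(seed), duration_s = duration_s, fs = fs,
                 medium = medium, states = states, start = start,
                 heading_bias = heading_bias,
                 speed_scale_error = speed_scale_error,
                 vedba = vedba, mag = mag, gps = gps, current = current,
                 pressure = pressure, t0 = t0),
            class = "sim_config")
}

# Deterministic per-stream sub-seed below 2^31.
.stream_seed <- function(seed, stream) {
  (abs(as.integer(seed)) * 7919L + sum(utf8ToInt(stream)) * 104729L) %% 2147483629L
}

# Ambient flow (m/s east, north) at a position/time, analytic form.
.ambient_uv <- function(current, lat, lon, t) {
  if (is.null(current)) return(c(0, 0))
  if (current$type == "constant") return(c(current$u, current$v))
  if (current$type == "gyre") {
    p <- .to_plane(lat, lon, current$center[1L], current$center[2L])
    return(c(-current$omega * p$y, current$omega * p$x))
  }
  stop("unknown current type: ", current$type)
}

#' Preset simulation scenarios
#'
#' Three ready-made configurations mirroring the three travel media:
#' `land_walker` (a collared terrestrial carnivore: 1-Hz sensors, 1-Hz GPS,
#' travel/rest switching around 0.9 m/s), `sea_diver` (a pursuit-diving
#' seabird: 2-Hz sensors, surface swimming at 0.416 m/s, dives at 2.1 m/s
#' with ~1 m/s vertical rates, fixes lost below 0.3 m), and `aerial_flyer`
#' (a pelagic flier: 10-Hz sensors, ~12 m/s flight, 1 fix/min GPS).
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @param duration_s simulated duration (default 3600 s).
#' @param ... further arguments overriding [sim_config()] defaults.
#' @return a [sim_config()].
#' @export
sim_preset <- function(name = c("land_walker", "sea_diver", "aerial_flyer"),
                       seed = 1L, duration_s = 3600, ...) {
  name <- match.arg(name)
  base <- switch(name,
    land_walker = list(
      fs = 1, medium = "land",
      states = list(
        travel = list(speed_mean = 0.9, speed_cv = 0.25, turn_sd_deg = 8,
                      vz_mean = 0, dwell_mean_s = 400),
        rest = list(speed_mean = 0, speed_cv = 0, turn_sd_deg = 2,
                    vz_mean = 0, dwell_mean_s = 150)),
      vedba = list(m_true = 2.5, c_true = 0, noise_sd = 0),
      gps = list(interval_s = 1, error_sd_m = 0, dropout_depth_m = NA)),
    sea_diver = list(
      fs = 2, medium = "water",
      states = list(
        surface = list(speed_mean = 0.416, speed_cv = 0.2, turn_sd_deg = 10,
                       vz_mean = 0, dwell_mean_s = 90),
        dive = list(speed_mean = 2.1, speed_cv = 0.15, turn_sd_deg = 6,
                    vz_mean = 1, dwell_mean_s = 120, max_depth_m = 20)),
      vedba = list(m_true = 4, c_true = 0, noise_sd = 0),
      gps = list(interval_s = 1, error_sd_m = 0, dropout_depth_m = 0.3)),
    aerial_flyer = list(
      fs = 10, medium = "air",
      states = list(
        flight = list(speed_mean = 12, speed_cv = 0.15, turn_sd_deg = 6,
                      vz_mean = 0.2, dwell_mean_s = 600),
        rest = list(speed_mean = 0.1, speed_cv = 0.3, turn_sd_deg = 10,
                    vz_mean = 0, dwell_mean_s = 120)),
      vedba = list(m_true = 20, c_true = 0, noise_sd = 0),
      gps = list(interval_s = 60, error_sd_m = 0, dropout_depth_m = NA)))
  args <- utils::modifyList(c(list(seed = seed, duration_s = duration_s), base),
                            list(...))
  do.call(sim_config, args)
}

#' Simulate ground-truth movement
#'
#' A semi-Markov state-switching correlated random walk: exponential dwell
#' times; per state the heading evolves as a wrapped-normal random walk, the
#' speed as a positive AR(1) around the state mean (innovated at 1-s nodes
#' and interpolated, so speed is smooth below the stride scale), and the
#' vertical rate
#' follows the state's profile (dive states oscillate between the surface and
#' their maximum depth; surface states relax towards z = 0). Positions are
#' accumulated by spherical forward steps of the powered travel vector plus
#' any ambient current.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `ground_truth`: list with `track` (a
#'   `geo_track` of true positions, z included), and per-sample `heading`,
#'   `speed` (powered, i.e. what the sensors can see), `vz`, `state`.
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.stream_seed(cfg$seed, "truth"))
  fs <- cfg$fs
  dt <- 1 / fs
  n <- max(2L, round(cfg$duration_s * fs))
  t <- cfg$t0 + (seq_len(n) - 1L) * dt

  # state sequence (semi-Markov, uniform switch among the other states)
  state_names <- names(cfg$states)
  state <- character(n)
  i <- 1L
  cur <- sample.int(length(state_names), 1L)
  while (i <= n) {
    dwell <- stats::rexp(1L, 1 / cfg$states[[cur]]$dwell_mean_s)
    k <- max(1L, round(dwell * fs))
    j <- min(n, i + k - 1L)
    state[i:j] <- state_names[cur]
    i <- j + 1L
    if (length(state_names) > 1L) {
      cur <- sample(setdiff(seq_along(state_names), cur), 1L)
    }
  }

  mu <- vapply(cfg$states, function(s) s$speed_mean, numeric(1L))[state]
  sig <- vapply(cfg$states, function(s) s$speed_mean * s$speed_cv, numeric(1L))[state]
  # finite acceleration: ramp the state speed mean over ~2 s at transitions
  ramp <- max(1L, round(2 * fs))
  if (n > ramp) {
    mu <- running_mean(mu, 2, fs)
    sig <- running_mean(sig, 2, fs)
  }
  turn <- vapply(cfg$states, function(s) s$turn_sd_deg, numeric(1L))[state]
  vz_mu <- vapply(cfg$states, function(s) s$vz_mean %||% 0, numeric(1L))[state]
  zmax <- vapply(cfg$states, function(s) s$max_depth_m %||% 20, numeric(1L))[state]

  # speed: positive AR(1) deviation around the state mean, innovated at 1-s
  # nodes (30-s autocorrelation time) and interpolated to fs -- animal speed
  # is smooth below the stride scale
  node <- unique(c(seq(1L, n, by = max(1L, round(fs))), n))
  a1 <- exp(-1 / 30)
  e_node <- numeric(length(node))
  e_node[1L] <- stats::rnorm(1L)
  innov <- stats::rnorm(length(node))
  for (k in seq_along(node)[-1L]) {
    e_node[k] <- a1 * e_node[k - 1L] + sqrt(1 - a1^2) * innov[k]
  }
  e <- if (length(node) > 1L) stats::approx(node, e_node, xout = seq_len(n))$y
       else rep(e_node, n)
  speed <- pmax(mu + sig * e, 0)

  heading <- numeric(n)
  heading[1L] <- stats::runif(1L, 0, 360)
  steps <- stats::rnorm(n, sd = 1) * turn * sqrt(dt)
  heading <- wrap_heading(heading[1L] + cumsum(c(0, steps[-1L])))

  # vertical profile
  z <- numeric(n)
  vz <- numeric(n)
  dir <- 1
  for (i in seq_len(n - 1L)) {
    if (cfg$medium == "water") {
      if (vz_mu[i] > 0) {                 # diving state: down, then back up
        if (dir > 0 && z[i] >= zmax[i]) dir <- -1
        if (dir < 0 && z[i] <= 0) dir <- 1
        vz[i] <- dir * vz_mu[i]
      } else {                            # surface state: relax to z = 0
        vz[i] <- -min(z[i] / dt, 1)
        dir <- 1
      }
      z[i + 1L] <- max(0, z[i] + vz[i] * dt)
    } else if (cfg$medium == "air") {
      vz[i] <- vz_mu[i]
      z[i + 1L] <- max(0, z[i] + vz[i] * dt)
    } else {
      z[i + 1L] <- 0
    }
  }

  lat <- numeric(n); lon <- numeric(n)
  lat[1L] <- cfg$start[1L]; lon[1L] <- cfg$start[2L]
  h_rad <- .deg2rad(heading)
  for (i in seq_len(n - 1L)) {
    de <- speed[i] * dt * sin(h_rad[i])
    dn <- speed[i] * dt * cos(h_rad[i])
    if (!is.null(cfg$current)) {
      uv <- .ambient_uv(cfg$current, lat[i], lon[i], t[i])
      de <- de + uv[1L] * dt
      dn <- dn + uv[2L] * dt
    }
    d <- sqrt(de^2 + dn^2)
    if (d > 0) {
      p <- forward_step(lat[i], lon[i], .rad2deg(atan2(de, dn)), d)
      lat[i + 1L] <- p$lat; lon[i + 1L] <- p$lon
    } else {
      lat[i + 1L] <- lat[i]; lon[i + 1L] <- lon[i]
    }
  }

  structure(list(track = {
    tr <- geo_track(t, lat, lon, z, kind = "dead_reckoned")
    attr(tr, "medium") <- cfg$medium
    tr
  }, heading = heading, speed = speed, vz = vz, state = state, cfg = cfg),
  class = "ground_truth")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d samples @ %g Hz (%s), states: %s\n",
              nrow(x$track), x$cfg$fs, x$cfg$medium,
              paste(names(table(x$state)), collapse = ", ")))
  invisible(x)
}

#' Simulate the inertial sensor stream for a ground truth
#'
#' Inverts the sensor-processing model: static acceleration is gravity
#' rotated by the true pitch (from vertical rate and horizontal speed; roll
#' is held at 0), dynamic acceleration is synthesised along the heave axis
#' as a sinusoid -- two cycles per 2-s smoothing window -- whose smoothed
#' norm equals the VeDBA level
#' implied by the configured VeDBA-speed coupling (so smoothed VeDBA recovers
#' `(speed_scale_error * speed - c_true) / m_true` plus noise), magnetism is
#' the Earth field at the configured inclination/declination rotated into the
#' tag frame at yaw `heading + heading_bias`, plus the hard-iron offset, and
#' pressure follows depth/altitude with optional linear drift.
#'
#' @param truth a [simulate_truth()] result.
#' @param cfg the same [sim_config()].
#' @return an [imu_series()].
#' @export
simulate_imu <- function(truth, cfg = truth$cfg) {
  stopifnot(inherits(truth, "ground_truth"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.stream_seed(cfg$seed, "imu"))
  n <- nrow(truth$track)
  t <- truth$track$t
  climb <- switch(cfg$medium, water = -truth$vz, air = truth$vz, land = rep(0, n))
  pitch <- atan2(climb, truth$speed)
  pitch[truth$speed == 0 & climb == 0] <- 0
  v_target <- pmax((cfg$speed_scale_error * truth$speed - cfg$vedba$c_true) /
                     cfg$vedba$m_true, 0)
  if (cfg$vedba$noise_sd > 0) {
    v_target <- pmax(v_target + stats::rnorm(n, sd = cfg$vedba$noise_sd), 0)
  }
  # Dynamic acceleration along the heave axis as a sinusoid completing an
  # exact integer number of cycles per 2-s smoothing window: its running mean
  # over that window is exactly zero (so the gravity estimate is
  # uncontaminated) and the smoothed norm equals the target VeDBA level for
  # slowly varying targets.
  n_win <- 2L * floor(cfg$fs) + 1L
  m_cyc <- max(1L, floor(n_win / 4))  # higher harmonic: small window first moment
  s_wave <- sin(2 * pi * m_cyc * (seq_len(n) - 1L) / n_win)
  mean_abs <- mean(abs(sin(2 * pi * m_cyc * (0:(n_win - 1L)) / n_win)))
  ax <- sin(pitch)
  ay <- rep(0, n)
  az <- cos(pitch) + v_target * s_wave / mean_abs

  psi <- .deg2rad(truth$heading + cfg$heading_bias)
  inc <- .deg2rad(cfg$mag$inclination)
  dec <- .deg2rad(cfg$mag$declination)
  Fs <- cfg$mag$field_strength
  fN <- Fs * cos(inc) * cos(dec)
  fE <- Fs * cos(inc) * sin(dec)
  fU <- -Fs * sin(inc)
  x1 <- cos(psi) * fN + sin(psi) * fE
  y1 <- -sin(psi) * fN + cos(psi) * fE
  mx <- cos(pitch) * x1 + sin(pitch) * fU + cfg$mag$hard_iron[1L]
  my <- y1 + cfg$mag$hard_iron[2L]
  mz <- -sin(pitch) * x1 + cos(pitch) * fU + cfg$mag$hard_iron[3L]

  drift <- cfg$pressure$drift_hpa_per_h * (t - t[1L]) / 3600
  pressure <- if (cfg$medium == "water") {
    cfg$pressure$surface_hpa + truth$track$z / 0.01 + drift
  } else if (cfg$medium == "air") {
    cfg$pressure$surface_hpa * (1 - truth$track$z / 44330)^(1 / 0.1903) + drift
  } else {
    cfg$pressure$surface_hpa + drift
  }
  imu_series(t, ax, ay, az, mx, my, mz, pressure = pressure)
}

#' Simulate Verified Positions for a ground truth
#'
#' Fixes at the configured interval, displaced by isotropic Gaussian noise in
#' the local tangent plane, and removed while the animal is deeper than the
#' dropout threshold (fix success fails under water).
#'
#' @param truth a [simulate_truth()] result.
#' @param cfg the same [sim_config()].
#' @return a `geo_track` of kind `"verified"` (z = 0: fixes are surface
#'   positions).
#' @export
simulate_vps <- function(truth, cfg = truth$cfg) {
  stopifnot(inherits(truth, "ground_truth"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.stream_seed(cfg$seed, "vps"))
  tr <- truth$track
  n <- nrow(tr)
  step <- max(1L, round(cfg$gps$interval_s * cfg$fs))
  idx <- seq(1L, n, by = step)
  if (!is.na(cfg$gps$dropout_depth_m)) {
    idx <- idx[tr$z[idx] <= cfg$gps$dropout_depth_m]
  }
  if (length(idx) < 2L) stop("simulate_vps: fewer than 2 fixes survive dropout")
  lat <- tr$lat[idx]; lon <- tr$lon[idx]
  if (cfg$gps$error_sd_m > 0) {
    k <- .EARTH_RADIUS_M * pi / 180
    dx <- stats::rnorm(length(idx), sd = cfg$gps$error_sd_m)
    dy <- stats::rnorm(length(idx), sd = cfg$gps$error_sd_m)
    lat <- lat + dy / k
    lon <- lon + dx / (k * cos(.deg2rad(lat)))
  }
  geo_track(tr$t[idx], lat, lon, z = 0, kind = "verified")
}

#' Simulate a gridded current field
#'
#' Realises the configured ambient flow (constant or solid-body gyre) on a
#' regular lon/lat/time grid around the release position, for exercising the
#' grid lookup and current integration machinery.
#'
#' @param cfg a [sim_config()] with a non-`NULL` `current` entry.
#' @param extent_deg half-width of the grid in degrees (default 0.5).
#' @param res_deg grid resolution in degrees (default 0.05).
#' @param time_step_s spacing of time layers in seconds (default 3600).
#' @return a [current_field()].
#' @export
simulate_current <- function(cfg, extent_deg = 0.5, res_deg = 0.05,
                             time_step_s = 3600) {
  stopifnot(inherits(cfg, "sim_config"), !is.null(cfg$current))
  lons <- seq(cfg$start[2L] - extent_deg, cfg$start[2L] + extent_deg, by = res_deg)
  lats <- seq(cfg$start[1L] - extent_deg, cfg$start[1L] + extent_deg, by = res_deg)
  times <- seq(cfg$t0, cfg$t0 + cfg$duration_s + time_step_s, by = time_step_s)
  grid <- expand.grid(lon = lons, lat = lats, time = times)
  uv <- mapply(function(la, lo, tt) .ambient_uv(cfg$current, la, lo, tt),
               grid$lat, grid$lon, grid$time)
  grid$u <- uv[1L, ]
  grid$v <- uv[2L, ]
  current_field(grid)
}

#' Travel vectors implied by a ground truth
#'
#' Builds the per-step travel-vector series that a perfect sensor-processing
#' chain would recover, optionally with an injected systematic heading bias
#' and/or speed scale error -- the parameter-injection route for testing the
#' identifiability of the correction factors.
#'
#' @param truth a [simulate_truth()] result.
#' @param heading_bias degrees added to every heading.
#' @param speed_scale factor multiplying every speed.
#' @return a [travel_vectors()] with one step per truth interval.
#' @export
travel_vectors_from_truth <- function(truth, heading_bias = 0, speed_scale = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  n <- nrow(truth$track)
  travel_vectors(truth$track$t[-n],
                 truth$heading[-n] + heading_bias,
                 truth$speed[-n] * speed_scale,
                 dz = diff(truth$track$z),
                 medium = truth$cfg$medium)
}
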