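#' Speed model configuration
#'
#' Parameters shared by the speed models: the linear VeDBA-speed coefficients,
#' a table of behaviour-specific constant speeds, and the thresholds used by
#' the vertical-rate model and the movement gate.
#'
#' @param m VeDBA-to-speed gradient (m/s per g), `>= 0`.
#' @param c intercept (m/s); negative extrapolations are floored at 0 when the
#'   model is applied.
#' @param behaviour_speed_table named numeric vector mapping behaviour-state
#'   labels to constant speeds (m/s, all `>= 0`).
#' @param pitch_threshold pitch magnitude (degrees) above which the
#'   vertical-rate model takes over (default 10).
#' @param depth_threshold depth (m) above which the animal is considered
#'   submerged (default 0.3).
#' @param speed_cap upper cap (m/s) for vertical-rate-derived speed
#'   (default 3).
#' @param vedba_threshold VeDBA movement-gate threshold in g (default 0.1).
#' @param travelling_states character vector of state labels counted as
#'   genuine travelling when gating on behaviour labels.
#' @return an object of class `speed_model_config`.
#' @export
speed_model_config <- function(m = 1, c = 0,
                               behaviour_speed_table = NULL,
                               pitch_threshold = 10,
                               depth_threshold = 0.3,
                               speed_cap = 3,
                               vedba_threshold = 0.1,
                               travelling_states = NULL) {
  stopifnot(m >= 0, speed_cap > 0, pitch_threshold >= 0, vedba_threshold >= 0)
  if (!is.null(behaviour_speed_table)) {
    stopifnot(!is.null(names(behaviour_speed_table)),
              all(behaviour_speed_table >= 0))
  }
  structure(list(m = m, c = c,
                 behaviour_speed_table = behaviour_speed_table,
                 pitch_threshold = pitch_threshold,
                 depth_threshold = depth_threshold,
                 speed_cap = speed_cap,
                 vedba_threshold = vedba_threshold,
                 travelling_states = travelling_states),
            class = "speed_model_config")
}

.speed_series <- function(speed, source) {
  stopifnot(all(speed >= 0), length(source) == length(speed))
  structure(data.frame(speed = speed, source = source),
            class = c("speed_series", "data.frame"))
}

#' @export
print.speed_series <- function(x, ...) {
  tab <- table(x$source)
  cat(sprintf("<speed_series> %d samples, mean %.3g m/s [%s]\n",
              nrow(x), mean(x$speed),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Speed from the linear VeDBA model
#'
#' `speed = m * VeDBA + c`, floored at 0.
#'
#' @param vedba VeDBA series in g.
#' @param cfg a [speed_model_config()].
#' @return a `speed_series` (columns `speed`, `source`).
#' @export
vedba_speed <- function(vedba, cfg) {
  stopifnot(inherits(cfg, "speed_model_config"))
  .speed_series(pmax(cfg$m * vedba + cfg$c, 0), rep("vedba", length(vedba)))
}

#' Fit the VeDBA-speed relation
#'
#' Two fitting routes: ordinary least-squares regression of VP-derived speed
#' on VeDBA, or scale matching -- `c = 0` with `m` chosen so the total
#' dead-reckoned path length equals the total VP path length (the closed-form
#' ratio of sums, equivalent to iteratively rescaling the gradient until the
#' uncorrected track is scaled to the VP track).
#'
#' @param vedba VeDBA series (g) at paired sample times.
#' @param vp_speed VP-derived speed (m/s) at the same times.
#' @param method `"regression"` or `"scale_match"`.
#' @param mask optional logical movement-gate mask; only open samples are
#'   used. At least 10 open pairs are required.
#' @return a list with elements `m` and `c`.
#' @export
fit_vedba_speed <- function(vedba, vp_speed,
                            method = c("regression", "scale_match"),
                            mask = NULL) {
  method <- match.arg(method)
  stopifnot(length(vedba) == length(vp_speed))
  if (!is.null(mask)) {
    vedba <- vedba[mask]
    vp_speed <- vp_speed[mask]
  }
  if (length(vedba) < 10L) stop("fit_vedba_speed: need >= 10 paired samples")
  if (stats::var(vedba) < 1e-300) stop("fit_vedba_speed: zero VeDBA variance")
  if (method == "regression") {
    fit <- stats::lm(vp_speed ~ vedba)
    list(m = unname(stats::coef(fit)[2L]), c = unname(stats::coef(fit)[1L]))
  } else {
    if (sum(vedba) <= 0) stop("fit_vedba_speed: zero VeDBA variance")
    list(m = sum(vp_speed) / sum(vedba), c = 0)
  }
}

#' Constant speed per behaviour state
#'
#' Looks each state label up in the configured behaviour-speed table
#' (e.g. a penguin's 0.416 m/s surface-swimming constant or a cormorant's
#' 12 m/s flight speed).
#'
#' @param states character vector of per-sample behaviour labels.
#' @param cfg a [speed_model_config()] with a non-empty
#'   `behaviour_speed_table`.
#' @return a `speed_series` with source `"behaviour"`.
#' @export
behaviour_speed <- function(states, cfg) {
  stopifnot(inherits(cfg, "speed_model_config"))
  tab <- cfg$behaviour_speed_table
  if (is.null(tab) || !length(tab)) stop("behaviour_speed: empty behaviour speed table")
  unknown <- setdiff(unique(states), names(tab))
  if (length(unknown)) {
    stop("behaviour_speed: unknown state label(s): ", paste(unknown, collapse = ", "))
  }
  .speed_series(unname(tab[states]), rep("behaviour", length(states)))
}

#' Speed from vertical rate and pitch
#'
#' Where the animal is submerged beyond the depth threshold and pitched
#' steeply enough (|pitch| >= threshold, default 10 degrees), speed is the
#' vertical rate divided by the tangent of the pitch,
#' `|dz/dt| / |tan(pitch * pi / 180)|`, capped (default 3 m/s); elsewhere the
#' fallback model's value and source are used.
#'
#' @param z depth series (m, positive down), aligned with `pitch`.
#' @param pitch pitch series (degrees).
#' @param cfg a [speed_model_config()].
#' @param fallback a `speed_series` covering every sample.
#' @param fs sampling frequency in Hz.
#' @param smooth_s smoothing window (s) applied to the vertical rate, matching
#'   the pitch post-smoothing window (default 1 s); `0` disables.
#' @return a `speed_series` with source `"vertical"` where the rule applies.
#' @export
vertical_rate_speed <- function(z, pitch, cfg, fallback, fs, smooth_s = 1) {
  stopifnot(inherits(cfg, "speed_model_config"), inherits(fallback, "speed_series"),
            length(z) == length(pitch), nrow(fallback) == length(z))
  n <- length(z)
  dz <- numeric(n)
  if (n > 2L) dz[2:(n - 1L)] <- (z[3:n] - z[1:(n - 2L)]) / 2
  if (n > 1L) {
    dz[1L] <- z[2L] - z[1L]
    dz[n] <- z[n] - z[n - 1L]
  }
  rate <- abs(dz) * fs
  if (smooth_s > 0) rate <- running_mean(rate, smooth_s, fs)
  use <- abs(pitch) >= cfg$pitch_threshold & z > cfg$depth_threshold
  v <- pmin(rate / abs(tan(.deg2rad(pitch))), cfg$speed_cap)
  speed <- ifelse(use, v, fallback$speed)
  source <- ifelse(use, "vertical", fallback$source)
  .speed_series(speed, source)
}

#' Speed from Verified Position displacement
#'
#' Haversine distance between consecutive fixes divided by the time between
#' them, assigned to the interval midpoint and interpolated linearly onto the
#' sample grid (extended constantly beyond the first/last interval).
#'
#' @param vps a `geo_track` of VPs (>= 2 fixes).
#' @param t_grid sample times to interpolate onto.
#' @return a `speed_series` with source `"gps"`.
#' @export
vp_derived_speed <- function(vps, t_grid) {
  stopifnot(inherits(vps, "geo_track"))
  n <- nrow(vps)
  if (n < 2L) stop("vp_derived_speed: need >= 2 fixes")
  d <- haversine(vps$lat[-n], vps$lon[-n], vps$lat[-1L], vps$lon[-1L])
  dt <- diff(vps$t)
  v <- d / dt
  mid <- vps$t[-n] + dt / 2
  out <- if (length(mid) == 1L) rep(v, length(t_grid)) else {
    stats::approx(mid, v, xout = t_grid, rule = 2)$y
  }
  .speed_series(pmax(out, 0), rep("gps", length(t_grid)))
}

#' Movement gate
#'
#' Marks the samples during which the travel vector is allowed to advance:
#' either samples whose VeDBA exceeds the configured threshold, or (when
#' behaviour labels are supplied) samples whose state is in the configured
#' travelling set. Gated-out samples should contribute zero displacement;
#' see [apply_gate()].
#'
#' @param vedba VeDBA series in g.
#' @param cfg a [speed_model_config()].
#' @param states optional character vector of behaviour labels.
#' @param mode `"auto"` (labels when supplied, else the VeDBA threshold),
#'   `"vedba"`, or `"labels"` (errors when no labels are supplied).
#' @return logical mask, `TRUE` where movement is accepted.
#' @export
movement_gate <- function(vedba, cfg, states = NULL,
                          mode = c("auto", "vedba", "labels")) {
  stopifnot(inherits(cfg, "speed_model_config"))
  mode <- match.arg(mode)
  if (mode == "auto") mode <- if (is.null(states)) "vedba" else "labels"
  if (mode == "labels") {
    if (is.null(states)) {
      stop("movement_gate: behaviour-label gating requested but no labels supplied")
    }
    if (is.null(cfg$travelling_states)) {
      stop("movement_gate: cfg$travelling_states is empty")
    }
    states %in% cfg$travelling_states
  } else {
    vedba > cfg$vedba_threshold
  }
}

#' Apply a movement gate to a speed series
#'
#' @param speed a `speed_series`.
#' @param mask logical mask from [movement_gate()].
#' @return the gated `speed_series`: gated-out samples get speed 0 and source
#'   `"gated-zero"`.
#' @export
apply_gate <- function(speed, mask) {
  stopifnot(inherits(speed, "speed_series"), nrow(speed) == length(mask))
  .speed_series(ifelse(mask, speed$speed, 0),
                ifelse(mask, speed$source, "gated-zero"))
}
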