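#' Total distance moved along a track
#'
#' 2-D: summed haversine distances between consecutive positions. 3-D: the
#' positions are converted to Earth-centred Cartesian coordinates on the
#' WGS-84 oblate spheroid (depth/altitude entering the ellipsoidal height)
#' and straight-line (Pythagorean) distances are summed.
#'
#' @param track a `geo_track` with at least 2 positions.
#' @param mode `"2d"` or `"3d"`.
#' @param medium sign convention for `z` in 3-D (defaults to the track's
#'   `medium` attribute, else `"land"`).
#' @return total distance in metres.
#' @export
distance_moved <- function(track, mode = c("2d", "3d"), medium = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(track, "geo_track"), nrow(track) >= 2L)
  n <- nrow(track)
  if (mode == "2d") {
    sum(haversine(track$lat[-n], track$lon[-n], track$lat[-1L], track$lon[-1L]))
  } else {
    medium <- medium %||% attr(track, "medium") %||% "land"
    p <- geodetic_to_cartesian(track$lat, track$lon, track$z, medium)
    sum(sqrt(diff(p$x)^2 + diff(p$y)^2 + diff(p$z)^2))
  }
}

#' Net error of a corrected track against Verified Positions
#'
#' Net error is the haversine distance between every VP (irrespective of the
#' correction rate actually used) and the time-matched corrected
#' dead-reckoned position. VPs used as correction anchors have (numerically)
#' zero net error.
#'
#' @param corrected a corrected `geo_track`.
#' @param all_vps a `geo_track` of all (screened) VPs to evaluate against.
#' @return an object of class `net_error_series`: data.frame `t, error_m`
#'   with attributes `mean`, `median` and `skipped`.
#' @export
net_error <- function(corrected, all_vps) {
  m <- time_match(corrected, all_vps)
  err <- haversine(all_vps$lat[m$vp], all_vps$lon[m$vp],
                   corrected$lat[m$sample], corrected$lon[m$sample])
  structure(data.frame(t = all_vps$t[m$vp], error_m = err),
            mean = mean(err), median = stats::median(err),
            skipped = attr(m, "skipped"),
            class = c("net_error_series", "data.frame"))
}

#' @export
print.net_error_series <- function(x, ...) {
  cat(sprintf("<net_error_series> %d VPs, mean %.3g m, median %.3g m\n",
              nrow(x), attr(x, "mean"), attr(x, "median")))
  invisible(x)
}

#' VP-thinning accuracy sweep
#'
#' Re-runs the drift correction across a schedule of VP correction intervals
#' (e.g. the conventional 1 fix/24 h down to 1 fix/s ladder) and quantifies,
#' per interval: mean and median net error against all (screened) VPs, the
#' corrected dead-reckoned distance moved (3-D when the medium has a
#' vertical dimension, else 2-D), the 2-D VP-path distance over the thinned
#' fixes (3-D VP distances are deliberately not computed), the mean time
#' between corrections actually achieved, and the standardised error rate
#' (mean net error / mean time between corrections, m/s).
#'
#' @param track an uncorrected dead-reckoned `geo_track`.
#' @param vps a `geo_track` of screened VPs.
#' @param schedule numeric vector of correction intervals in seconds.
#' @param mode `"2d"` or `"3d"` for the dead-reckoned distance moved.
#' @return a data.frame with one row per interval: `interval_s`,
#'   `mean_net_error_m`, `median_net_error_m`, `dr_distance_m`,
#'   `vp_distance_m`, `mean_dt_s`, `error_rate_m_per_s`, `n_vps_used`.
#' @export
thinning_sweep <- function(track, vps, schedule, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  stopifnot(length(schedule) >= 1L)
  rows <- lapply(schedule, function(iv) {
    thinned <- thin_vps(vps, iv)
    cor <- correct_track(track, thinned)
    ne <- net_error(cor$track, vps)
    used_t <- thinned$t
    mean_dt <- if (length(used_t) > 1L) mean(diff(used_t)) else NA_real_
    nvp <- nrow(thinned)
    data.frame(
      interval_s = iv,
      mean_net_error_m = attr(ne, "mean"),
      median_net_error_m = attr(ne, "median"),
      dr_distance_m = distance_moved(cor$track, mode),
      vp_distance_m = if (nvp > 1L) distance_moved(thinned, "2d") else 0,
      mean_dt_s = mean_dt,
      error_rate_m_per_s = attr(ne, "mean") / mean_dt,
      n_vps_used = nvp
    )
  })
  do.call(rbind, rows)
}
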