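#' Match Verified Positions to track samples in time
#'
#' Each VP is matched to the nearest dead-reckoned sample within half a
#' sampling step; VPs falling in logger gaps are skipped and counted.
#'
#' @param track a `geo_track` (uniformly sampled dead-reckoned track).
#' @param vps a `geo_track` of VPs.
#' @param tol matching tolerance in seconds; defaults to half the track's
#'   sampling step.
#' @return a data.frame with columns `vp` (VP row) and `sample` (track row),
#'   with attribute `skipped` (count of unmatched VPs).
#' @export
time_match <- function(track, vps, tol = NULL) {
  stopifnot(inherits(track, "geo_track"), inherits(vps, "geo_track"),
            nrow(track) > 0L, nrow(vps) > 0L)
  dt <- if (nrow(track) > 1L) stats::median(diff(track$t)) else 1
  if (is.null(tol)) tol <- dt / 2
  k <- findInterval(vps$t, track$t, all.inside = TRUE)
  nearer_right <- abs(track$t[k + 1L] - vps$t) < abs(track$t[k] - vps$t)
  k[nearer_right] <- k[nearer_right] + 1L
  ok <- abs(track$t[k] - vps$t) <= tol
  if (!any(ok)) stop("time_match: no VP matched any track sample")
  out <- data.frame(vp = which(ok), sample = k[ok])
  attr(out, "skipped") <- sum(!ok)
  out
}

#' Thin Verified Positions to a correction interval
#'
#' Greedy temporal sub-sampling used to emulate lower VP correction rates:
#' keep the first fix, then each earliest fix at least `interval_s` after the
#' last kept fix; the final fix is always kept. Because real fix success can
#' fail for longer than the requested interval, retained spacing may exceed
#' `interval_s`.
#'
#' @param vps a `geo_track` of VPs.
#' @param interval_s requested correction interval in seconds, `> 0`.
#' @return the thinned `geo_track`.
#' @export
thin_vps <- function(vps, interval_s) {
  stopifnot(inherits(vps, "geo_track"), interval_s > 0)
  n <- nrow(vps)
  keep <- logical(n)
  keep[1L] <- TRUE
  last_t <- vps$t[1L]
  for (i in seq_len(n)[-1L]) {
    if (vps$t[i] >= last_t + interval_s) {
      keep[i] <- TRUE
      last_t <- vps$t[i]
    }
  }
  keep[n] <- TRUE
  out <- geo_track(vps$t[keep], vps$lat[keep], vps$lon[keep], vps$z[keep],
                   kind = "verified")
  out
}

#' Distance and heading correction factors for one segment
#'
#' The distance correction factor (DCF) is the ratio of the beeline between
#' consecutive VPs to the beeline between the temporally aligned
#' dead-reckoned positions; the heading correction factor (HCF) is the
#' difference between the initial great-circle bearings of the two beelines
#' (positive = clockwise rotation to apply to the dead-reckoned headings).
#' A dead-reckoned beeline of zero length makes the DCF undefined and flags
#' the segment degenerate.
#'
#' @param dr_start,dr_end,vp_start,vp_end positions as numeric
#'   `c(lat, lon)`.
#' @return a list with `dcf` (dimensionless, `NA` if degenerate), `hcf`
#'   (degrees in `(-180, 180]`, `NA` if degenerate) and `degenerate`
#'   (logical).
#' @export
segment_factors <- function(dr_start, dr_end, vp_start, vp_end) {
  stopifnot(all(is.finite(c(dr_start, dr_end, vp_start, vp_end))))
  d_dr <- haversine(dr_start[1L], dr_start[2L], dr_end[1L], dr_end[2L])
  d_vp <- haversine(vp_start[1L], vp_start[2L], vp_end[1L], vp_end[2L])
  if (d_dr < 1e-9) {
    return(list(dcf = NA_real_, hcf = NA_real_, degenerate = TRUE))
  }
  b_dr <- initial_bearing(dr_start[1L], dr_start[2L], dr_end[1L], dr_end[2L])
  b_vp <- initial_bearing(vp_start[1L], vp_start[2L], vp_end[1L], vp_end[2L])
  list(dcf = d_vp / d_dr, hcf = wrap_angle(b_vp - b_dr), degenerate = FALSE)
}

#' Correct a dead-reckoned track against Verified Positions
#'
#' The segment-wise drift correction: between each pair of consecutive
#' matched VPs, every dead-reckoned step heading is rotated by the segment's
#' heading correction factor and every step distance is multiplied by its
#' distance correction factor, and the steps are re-integrated from the
#' segment's starting VP -- which lands the corrected segment endpoint on the
#' ending VP. Factors are computed (and the transform applied) in the local
#' tangent plane at the starting VP, which makes anchor alignment exact to
#' numerical precision at biologging scales; the logged residual tracks the
#' planar-approximation error. Steps of zero distance stay zero -- stationary
#' clusters are never expanded ("multiplying by zero achieves a
#' zero-correction factor") -- because the correction is a similarity
#' transform of the segment. Spans before the first and after the last
#' matched VP are rigidly translated to abut their anchor. Segments whose
#' dead-reckoned beeline is zero are degenerate: the span is translated to
#' the starting VP and its final sample snapped to the ending VP, with the
#' mismatch logged as the residual.
#'
#' @param track a dead-reckoned `geo_track` (uniform sampling).
#' @param vps_thinned a `geo_track` of VPs to correct against (>= 2 must
#'   match the track in time).
#' @param tv optional [travel_vectors()] used to build `track`; checked for
#'   alignment when given (the correction itself operates on track
#'   geometry).
#' @return a list with `track` (the corrected `geo_track`) and `report` (a
#'   `correction_report`: per-segment times, dcf, hcf, residual_m,
#'   degenerate and extreme-factor flags, plus VP matching counts).
#' @export
correct_track <- function(track, vps_thinned, tv = NULL) {
  stopifnot(inherits(track, "geo_track"), inherits(vps_thinned, "geo_track"))
  if (!is.null(tv) && nrow(tv) + 1L != nrow(track)) {
    stop("correct_track: travel vectors not aligned with track steps")
  }
  m <- time_match(track, vps_thinned)
  dup <- duplicated(m$sample)
  m <- m[!dup, , drop = FALSE]
  if (nrow(m) < 2L) stop("correct_track: need >= 2 matched VPs")

  lat <- track$lat; lon <- track$lon
  out_lat <- lat; out_lon <- lon
  nseg <- nrow(m) - 1L
  seg <- data.frame(t_start = numeric(nseg), t_end = numeric(nseg),
                    dcf = numeric(nseg), hcf = numeric(nseg),
                    dr_beeline_m = numeric(nseg), vp_beeline_m = numeric(nseg),
                    dr_path_m = numeric(nseg),
                    residual_m = numeric(nseg), degenerate = logical(nseg))

  for (s in seq_len(nseg)) {
    i0 <- m$sample[s]; i1 <- m$sample[s + 1L]
    v0 <- m$vp[s]; v1 <- m$vp[s + 1L]
    lat0 <- vps_thinned$lat[v0]; lon0 <- vps_thinned$lon[v0]
    idx <- i0:i1
    p <- .to_plane(lat[idx], lon[idx], lat0, lon0)
    qx <- p$x - p$x[1L]; qy <- p$y - p$y[1L]
    e <- .to_plane(vps_thinned$lat[v1], vps_thinned$lon[v1], lat0, lon0)
    L_dr <- sqrt(qx[length(qx)]^2 + qy[length(qy)]^2)
    L_vp <- sqrt(e$x^2 + e$y^2)
    seg$t_start[s] <- track$t[i0]; seg$t_end[s] <- track$t[i1]
    seg$dr_beeline_m[s] <- L_dr; seg$vp_beeline_m[s] <- L_vp
    seg$dr_path_m[s] <- sum(sqrt(diff(qx)^2 + diff(qy)^2))
    if (L_dr < 1e-9) {
      cx <- qx; cy <- qy
      cx[length(cx)] <- e$x; cy[length(cy)] <- e$y
      seg$dcf[s] <- NA_real_; seg$hcf[s] <- NA_real_
      seg$degenerate[s] <- TRUE
      seg$residual_m[s] <- sqrt((qx[length(qx)] - e$x)^2 + (qy[length(qy)] - e$y)^2)
    } else {
      a <- .deg2rad(wrap_angle(.rad2deg(atan2(e$x, e$y) - atan2(qx[length(qx)], qy[length(qy)]))))
      sc <- L_vp / L_dr
      ca <- cos(a); sa <- sin(a)
      cx <- sc * (ca * qx + sa * qy)
      cy <- sc * (-sa * qx + ca * qy)
      seg$dcf[s] <- sc
      seg$hcf[s] <- .rad2deg(a)
      seg$residual_m[s] <- sqrt((cx[length(cx)] - e$x)^2 + (cy[length(cy)] - e$y)^2)
    }
    g <- .from_plane(cx, cy, lat0, lon0)
    out_lat[idx] <- g$lat; out_lon[idx] <- g$lon
  }

  # rigid translation of the spans outside the anchored range
  first <- m$sample[1L]
  if (first > 1L) {
    v0 <- m$vp[1L]
    lat0 <- vps_thinned$lat[v0]; lon0 <- vps_thinned$lon[v0]
    p <- .to_plane(lat[1:first], lon[1:first], lat0, lon0)
    g <- .from_plane(p$x - p$x[first], p$y - p$y[first], lat0, lon0)
    out_lat[1:first] <- g$lat; out_lon[1:first] <- g$lon
  }
  last <- m$sample[nrow(m)]
  n <- nrow(track)
  if (last < n) {
    v1 <- m$vp[nrow(m)]
    lat0 <- vps_thinned$lat[v1]; lon0 <- vps_thinned$lon[v1]
    p <- .to_plane(lat[last:n], lon[last:n], lat0, lon0)
    g <- .from_plane(p$x - p$x[1L], p$y - p$y[1L], lat0, lon0)
    out_lat[last:n] <- g$lat; out_lon[last:n] <- g$lon
  }

  corrected <- geo_track(track$t, out_lat, out_lon, track$z, kind = "dead_reckoned")
  attr(corrected, "medium") <- attr(track, "medium")
  seg$extreme <- !seg$degenerate & (seg$dcf > 10 | seg$dcf < 0.1)
  report <- structure(list(segments = seg,
                           vps_used = nrow(m),
                           vps_skipped = attr(m, "skipped"),
                           degenerate_segments = sum(seg$degenerate),
                           extreme_segments = sum(seg$extreme)),
                      class = "correction_report")
  list(track = corrected, report = report)
}

#' @export
print.correction_report <- function(x, ...) {
  s <- x$segments
  cat(sprintf(paste0("<correction_report> %d segments (%d degenerate, %d extreme), ",
                     "%d VPs used, %d skipped\n"),
              nrow(s), x$degenerate_segments, x$extreme_segments,
              x$vps_used, x$vps_skipped))
  if (any(!s$degenerate)) {
    cat(sprintf("  dcf median %.3g, hcf median %+.2f deg, max residual %.3g m\n",
                stats::median(s$dcf[!s$degenerate]),
                stats::median(s$hcf[!s$degenerate]),
                max(s$residual_m)))
  }
  invisible(x)
}

#' Write a correction report to CSV
#'
#' One row per segment: times, distance and heading correction factors,
#' residual, degenerate and extreme flags, plus beeline/path diagnostics.
#'
#' @param report a `correction_report` from [correct_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correction_report <- function(report, path) {
  stopifnot(inherits(report, "correction_report"))
  utils::write.csv(report$segments, path, row.names = FALSE)
  invisible(path)
}
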