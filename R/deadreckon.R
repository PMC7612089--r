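#' Construct a travel-vector series
#'
#' The per-sample travel vectors that dead-reckoning integrates: a heading
#' (direction of travel, assuming movement along the longitudinal body axis),
#' a speed, and an optional vertical displacement per step.
#'
#' @param t sample times in seconds (uniform step).
#' @param heading degrees clockwise from true North, `[0, 360)`.
#' @param speed m/s, `>= 0`.
#' @param dz vertical displacement per step in metres (positive down for
#'   depth, positive up for altitude); default 0.
#' @param medium `"land"`, `"water"` or `"air"` (carried as an attribute so
#'   downstream metrics know the sign convention of `z`).
#' @return an object of class `travel_vectors` (data.frame `t, heading,
#'   speed, dz` with attribute `medium`).
#' @export
travel_vectors <- function(t, heading, speed, dz = 0,
                           medium = c("land", "water", "air")) {
  medium <- match.arg(medium)
  n <- length(t)
  stopifnot(length(heading) == n, length(speed) == n)
  dz <- rep_len(dz, n)
  if (any(!is.finite(heading)) || any(!is.finite(speed)) || any(!is.finite(dz))) {
    stop("travel_vectors: non-finite vector components at index ",
         which(!is.finite(heading) | !is.finite(speed) | !is.finite(dz))[1L])
  }
  if (any(speed < 0)) stop("travel_vectors: speed must be >= 0")
  structure(data.frame(t = t, heading = wrap_heading(heading), speed = speed, dz = dz),
            medium = medium, class = c("travel_vectors", "data.frame"))
}

#' Construct a gridded current field
#'
#' A regular (lon, lat, time) grid of east/north flow components, e.g. tidal
#' currents or wind. Lookups outside the grid return (0, 0) and are counted.
#'
#' @param df data.frame with columns `lon`, `lat`, `time`, `u`, `v`
#'   (east/north components, m/s) covering a complete regular grid.
#' @return an object of class `current_field`.
#' @export
current_field <- function(df) {
  need <- c("lon", "lat", "time", "u", "v")
  stopifnot(all(need %in% names(df)))
  if (any(!is.finite(df$u)) || any(!is.finite(df$v))) {
    stop("current_field: non-finite flow components")
  }
  lons <- sort(unique(df$lon))
  lats <- sort(unique(df$lat))
  times <- sort(unique(df$time))
  if (nrow(df) != length(lons) * length(lats) * length(times)) {
    stop("current_field: grid is not complete/regular")
  }
  key <- function(x, vals) match(x, vals)
  u <- array(NA_real_, c(length(lons), length(lats), length(times)))
  v <- u
  idx <- cbind(key(df$lon, lons), key(df$lat, lats), key(df$time, times))
  u[idx] <- df$u
  v[idx] <- df$v
  structure(list(lons = lons, lats = lats, times = times, u = u, v = v,
                 misses = new.env(parent = emptyenv())),
            class = "current_field")
}

#' @export
print.current_field <- function(x, ...) {
  cat(sprintf("<current_field> %d x %d nodes, %d time layer(s), |flow| up to %.3g m/s\n",
              length(x$lons), length(x$lats), length(x$times),
              max(sqrt(x$u^2 + x$v^2))))
  invisible(x)
}

#' Read a current-field CSV
#'
#' Columns `lon, lat, time, u, v` on a complete regular grid (validated on
#' load).
#'
#' @param path path to the CSV file.
#' @return a [current_field()].
#' @export
read_current_csv <- function(path) {
  if (!file.exists(path)) stop("read_current_csv: no such file: ", path)
  current_field(utils::read.csv(path))
}

#' Look up flow at a position and time
#'
#' Nearest-neighbour in space, linear interpolation in time between
#' bracketing layers. Queries outside the grid (in space or time) return
#' `(0, 0)`; the number of such misses is kept on the field object
#' (`current_misses()`).
#'
#' @param field a [current_field()].
#' @param lat,lon query position, decimal degrees.
#' @param t query time, seconds.
#' @return numeric `c(u, v)` in m/s.
#' @export
current_lookup <- function(field, lat, lon, t) {
  stopifnot(inherits(field, "current_field"))
  half_dlon <- if (length(field$lons) > 1L) min(diff(field$lons)) / 2 else Inf
  half_dlat <- if (length(field$lats) > 1L) min(diff(field$lats)) / 2 else Inf
  i <- which.min(abs(field$lons - lon))
  j <- which.min(abs(field$lats - lat))
  outside <- abs(field$lons[i] - lon) > half_dlon + 1e-12 ||
    abs(field$lats[j] - lat) > half_dlat + 1e-12 ||
    t < field$times[1L] - 1e-9 || t > field$times[length(field$times)] + 1e-9
  if (outside) {
    field$misses$n <- (field$misses$n %||% 0L) + 1L
    return(c(0, 0))
  }
  ts <- field$times
  if (length(ts) == 1L || t <= ts[1L]) {
    return(c(field$u[i, j, 1L], field$v[i, j, 1L]))
  }
  k <- findInterval(t, ts)
  if (k >= length(ts)) return(c(field$u[i, j, length(ts)], field$v[i, j, length(ts)]))
  w <- (t - ts[k]) / (ts[k + 1L] - ts[k])
  c((1 - w) * field$u[i, j, k] + w * field$u[i, j, k + 1L],
    (1 - w) * field$v[i, j, k] + w * field$v[i, j, k + 1L])
}

#' Number of out-of-grid current lookups so far
#' @param field a [current_field()].
#' @return integer count.
#' @export
current_misses <- function(field) field$misses$n %||% 0L

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integrate travel vectors into a dead-reckoned track
#'
#' Sequentially integrates per-sample travel vectors from a starting
#' position: each step's powered displacement `speed * dt * (sin h, cos h)`
#' (east, north) is -- when a current field is supplied -- summed with the
#' flow displacement `(u, v) * dt` sampled at the pre-step position and time
#' ("current integration"), and the summed vector's bearing and magnitude are
#' applied as a spherical forward step. The vertical coordinate accumulates
#' `dz` (clamped at zero depth in water).
#'
#' @param start numeric `c(lat, lon)` or `c(lat, lon, z)`.
#' @param tv a [travel_vectors()] series (n steps).
#' @param current optional [current_field()].
#' @return a `geo_track` of kind `"dead_reckoned"` with `n + 1` positions;
#'   position i+1 results from step i.
#' @export
integrate_track <- function(start, tv, current = NULL) {
  stopifnot(inherits(tv, "travel_vectors"), length(start) %in% c(2L, 3L))
  n <- nrow(tv)
  if (n == 0L) stop("integrate_track: empty travel-vector series")
  medium <- attr(tv, "medium")
  dt <- if (n > 1L) diff(tv$t) else 1
  dt <- c(dt, dt[length(dt)])
  lat <- numeric(n + 1L); lon <- numeric(n + 1L); z <- numeric(n + 1L)
  lat[1L] <- start[1L]; lon[1L] <- start[2L]
  z[1L] <- if (length(start) == 3L) start[3L] else 0
  h_rad <- .deg2rad(tv$heading)
  de_p <- tv$speed * dt * sin(h_rad)
  dn_p <- tv$speed * dt * cos(h_rad)
  for (i in seq_len(n)) {
    de <- de_p[i]; dn <- dn_p[i]
    if (!is.null(current)) {
      uv <- current_lookup(current, lat[i], lon[i], tv$t[i])
      de <- de + uv[1L] * dt[i]
      dn <- dn + uv[2L] * dt[i]
    }
    d <- sqrt(de^2 + dn^2)
    if (d > 0) {
      p <- forward_step(lat[i], lon[i], .rad2deg(atan2(de, dn)), d)
      lat[i + 1L] <- p$lat; lon[i + 1L] <- p$lon
    } else {
      lat[i + 1L] <- lat[i]; lon[i + 1L] <- lon[i]
    }
    z[i + 1L] <- z[i] + tv$dz[i]
    if (medium == "water" && z[i + 1L] < 0) z[i + 1L] <- 0
  }
  out <- geo_track(c(tv$t, tv$t[n] + dt[n]), lat, lon, z, kind = "dead_reckoned")
  attr(out, "medium") <- medium
  out
}
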