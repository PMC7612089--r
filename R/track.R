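#' Construct a geo-referenced track
#'
#' An ordered, timestamped sequence of positions: either a dead-reckoned
#' pseudo-track or a series of Verified Positions (VPs, e.g. GPS fixes).
#'
#' @param t time in seconds since epoch; strictly increasing.
#' @param lat,lon WGS-84 decimal degrees; `lat` in `[-90, 90]`, `lon` in
#'   `(-180, 180]`.
#' @param z vertical coordinate in metres (depth positive down in water,
#'   altitude positive up in air); 0 for 2-D tracks.
#' @param kind `"dead_reckoned"` or `"verified"`.
#' @return an object of class `geo_track` (a data.frame `t, lat, lon, z` with
#'   attribute `kind`).
#' @export
geo_track <- function(t, lat, lon, z = 0, kind = c("dead_reckoned", "verified")) {
  kind <- match.arg(kind)
  n <- length(t)
  z <- rep_len(z, n)
  if (n == 0L) stop("geo_track: empty track")
  if (any(!is.finite(t)) || any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(!is.finite(z))) {
    stop("geo_track: non-finite coordinates")
  }
  if (n > 1L && any(diff(t) <= 0)) stop("geo_track: timestamps not strictly increasing")
  if (any(lat < -90 | lat > 90)) stop("geo_track: latitude outside [-90, 90]")
  if (any(lon <= -180 | lon > 180)) stop("geo_track: longitude outside (-180, 180]")
  structure(data.frame(t = t, lat = lat, lon = lon, z = z),
            kind = kind, class = c("geo_track", "data.frame"))
}

#' @export
print.geo_track <- function(x, ...) {
  cat(sprintf("<geo_track:%s> %d positions, %.1f s, lat [%.5f, %.5f], lon [%.5f, %.5f]\n",
              attr(x, "kind"), nrow(x),
              if (nrow(x) > 1) diff(range(x$t)) else 0,
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  invisible(x)
}

#' Read Verified Positions from CSV
#'
#' Expects columns `time`, `lat`, `lon` and optionally `z`; time as ISO-8601
#' or epoch seconds.
#'
#' @param path path to a CSV file.
#' @return a `geo_track` of kind `"verified"`.
#' @export
read_vps_csv <- function(path) {
  if (!file.exists(path)) stop("read_vps_csv: no such file: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  for (col in c("time", "lat", "lon")) {
    if (!col %in% names(d)) stop("read_vps_csv: missing column: ", col)
  }
  bad <- which(!is.finite(d$lat) | !is.finite(d$lon))
  if (length(bad)) stop("read_vps_csv: malformed row at line ", bad[1L] + 1L)
  t <- if (is.numeric(d$time)) as.numeric(d$time) else .parse_time(d$time)
  geo_track(t, d$lat, d$lon, z = if ("z" %in% names(d)) d$z else 0,
            kind = "verified")
}

#' Write a track to CSV or GeoJSON
#'
#' CSV round-trips coordinates to full double precision. GeoJSON (RFC 7946)
#' writes a LineString, with a third coordinate element when the track is 3-D.
#' Extra per-sample columns (e.g. speed, heading, source) present on the
#' object are carried into the CSV.
#'
#' @param track a `geo_track`.
#' @param path output path.
#' @param format `"csv"` or `"geojson"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  if (format == "csv") {
    d <- as.data.frame(track)
    names(d)[names(d) == "t"] <- "time"
    utils::write.csv(format(d, digits = 17, scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    three_d <- any(track$z != 0)
    coords <- lapply(seq_len(nrow(track)), function(i) {
      if (three_d) c(track$lon[i], track$lat[i], track$z[i])
      else c(track$lon[i], track$lat[i])
    })
    gj <- list(
      type = "Feature",
      properties = list(kind = attr(track, "kind")),
      geometry = list(type = "LineString", coordinates = coords)
    )
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Screen Verified Positions for implausible fixes
#'
#' Drops fixes whose implied speed from the previously kept fix exceeds a
#' physical ceiling -- a programmatic stand-in for visual outlier removal.
#'
#' @param vps a `geo_track` of VPs.
#' @param max_speed maximum plausible ground speed in m/s.
#' @return the screened `geo_track`, with attribute `screened_out` giving the
#'   number of fixes removed.
#' @export
screen_vps <- function(vps, max_speed = 30) {
  stopifnot(inherits(vps, "geo_track"))
  n <- nrow(vps)
  keep <- logical(n)
  keep[1L] <- TRUE
  last <- 1L
  for (i in seq_len(n)[-1L]) {
    dt <- vps$t[i] - vps$t[last]
    v <- haversine(vps$lat[last], vps$lon[last], vps$lat[i], vps$lon[i]) / dt
    if (v <= max_speed) {
      keep[i] <- TRUE
      last <- i
    }
  }
  out <- geo_track(vps$t[keep], vps$lat[keep], vps$lon[keep], vps$z[keep],
                   kind = "verified")
  attr(out, "screened_out") <- sum(!keep)
  out
}
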