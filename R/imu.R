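#' Construct an IMU series
#'
#' A uniformly sampled stream of tri-axial acceleration (g) and magnetism
#' (arbitrary but consistent units) in the animal's body frame, with optional
#' pressure. Axis convention: `ax` surge (anterior-posterior, positive
#' forward), `ay` sway (medio-lateral, positive to the animal's right),
#' `az` heave (dorsal-ventral, positive dorsal) -- so an upright, motionless
#' animal reads approximately (0, 0, 1) g.
#'
#' Rows containing non-finite values are dropped and counted; timestamps must
#' then be strictly increasing with a constant step (within 1e-6 s).
#'
#' @param t time in seconds since epoch (numeric).
#' @param ax,ay,az acceleration components in g.
#' @param mx,my,mz magnetic-field components.
#' @param pressure optional pressure series (hPa in air; hydrostatic pressure
#'   units consistent with the depth conversion for water).
#' @return an object of class `imu_series`: a data.frame with the above
#'   columns and attributes `fs` (sampling frequency, Hz) and `dropped`
#'   (number of rows removed at ingest).
#' @export
imu_series <- function(t, ax, ay, az, mx, my, mz, pressure = NULL) {
  d <- data.frame(t = t, ax = ax, ay = ay, az = az, mx = mx, my = my, mz = mz)
  if (!is.null(pressure)) d$pressure <- pressure
  keep <- stats::complete.cases(d) & apply(is.finite(as.matrix(d)), 1L, all)
  dropped <- sum(!keep)
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 2L) stop("imu_series: need at least 2 finite samples")
  dt <- diff(d$t)
  if (any(dt <= 0)) {
    stop("imu_series: timestamps not strictly increasing (first offence at row ",
         which(dt <= 0)[1L] + 1L, ")")
  }
  # constant base step (1e-6 s tolerance); gaps left by dropped rows must be
  # whole multiples of it
  base <- min(dt)
  mult <- dt / base
  off <- abs(mult - round(mult))
  if (any(off > 1e-6)) {
    stop("imu_series: non-uniform sampling step (first offence at row ",
         which(off > 1e-6)[1L] + 1L, ")")
  }
  fs <- 1 / base
  if (fs < 1 - 1e-9 || fs > 40 + 1e-9) {
    stop("imu_series: sampling frequency ", signif(fs, 4), " Hz outside [1, 40] Hz")
  }
  rownames(d) <- NULL
  structure(d, fs = fs, dropped = dropped, class = c("imu_series", "data.frame"))
}

#' Sampling frequency of an IMU series (Hz)
#' @param x an `imu_series` or `static_dynamic_split`.
#' @return sampling frequency in Hz.
#' @export
sampling_rate <- function(x) attr(x, "fs")

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("<imu_series> %d samples @ %.3g Hz (%.1f s)%s, %d rows dropped at ingest\n",
              nrow(x), attr(x, "fs"), diff(range(x$t)),
              if ("pressure" %in% names(x)) ", with pressure" else "",
              attr(x, "dropped")))
  invisible(x)
}

#' Read an IMU CSV file
#'
#' Parses a CSV with a header into an [imu_series()]. Time may be ISO-8601
#' text or epoch seconds (auto-detected). Column naming dialects are handled
#' via `column_map`.
#'
#' @param path path to the CSV file.
#' @param column_map named character vector mapping the canonical names
#'   (`time`, `ax`, `ay`, `az`, `mx`, `my`, `mz`, `pressure`) to the file's
#'   column names; defaults to identity.
#' @return an [imu_series()].
#' @export
read_imu_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("read_imu_csv: no such file: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  canon <- c("time", "ax", "ay", "az", "mx", "my", "mz", "pressure")
  map <- stats::setNames(canon, canon)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  need <- canon[canon != "pressure"]
  missing <- need[!map[need] %in% names(d)]
  if (length(missing)) {
    stop("read_imu_csv: missing column(s): ",
         paste(map[missing], collapse = ", "))
  }
  tcol <- d[[map[["time"]]]]
  t <- if (is.numeric(tcol)) as.numeric(tcol) else .parse_time(tcol)
  press <- if (map[["pressure"]] %in% names(d)) d[[map[["pressure"]]]] else NULL
  imu_series(t,
             d[[map[["ax"]]]], d[[map[["ay"]]]], d[[map[["az"]]]],
             d[[map[["mx"]]]], d[[map[["my"]]]], d[[map[["mz"]]]],
             pressure = press)
}

# ISO-8601 (with optional fractional seconds) -> epoch seconds.
.parse_time <- function(x) {
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(t)) stop("could not parse timestamps (ISO-8601 or epoch seconds expected)")
  as.numeric(t)
}
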