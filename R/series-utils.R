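#' Centred running mean with shrinking edges
#'
#' The smoothing primitive used for static-acceleration extraction, VeDBA
#' smoothing and posture post-smoothing. The window shrinks at the series
#' edges (no padding), so the output has the same length as the input.
#'
#' @param x numeric vector, no non-finite values.
#' @param window_s window length in seconds.
#' @param fs sampling frequency in Hz.
#' @return numeric vector, same length as `x`.
#' @export
running_mean <- function(x, window_s, fs) {
  n <- length(x)
  if (n == 0L) stop("running_mean: empty series")
  if (window_s <= 0) stop("running_mean: window_s must be > 0")
  half <- floor(window_s * fs / 2)
  if (half < 1) return(x)
  idx <- seq_len(n)
  lo <- pmax(1L, idx - half)
  hi <- pmin(n, idx + half)
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Circular mean of headings
#'
#' Mean direction of a set of headings via the resultant vector, so that
#' e.g. the mean of 350 and 10 degrees is 0, never 180.
#'
#' @param h headings in degrees.
#' @return mean heading in degrees, `[0, 360)`; `NA` if the resultant vector
#'   is (numerically) zero.
#' @export
circular_mean <- function(h) {
  s <- mean(sin(.deg2rad(h)))
  c <- mean(cos(.deg2rad(h)))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  wrap_heading(.rad2deg(atan2(s, c)))
}

# Rolling circular mean (shrinking centred window), used to post-smooth
# headings: running means of the sine and cosine components, recombined.
.rolling_circular_mean <- function(h, window_s, fs) {
  s <- running_mean(sin(.deg2rad(h)), window_s, fs)
  c <- running_mean(cos(.deg2rad(h)), window_s, fs)
  wrap_heading(.rad2deg(atan2(s, c)))
}

# Carry the last "reliable" value forward over flagged samples; leading
# flagged samples are back-filled from the first reliable one.
.carry_forward <- function(x, ok) {
  if (!any(ok)) stop("no reliable samples to carry forward")
  idx <- cumsum(ok)
  first <- which(ok)[1L]
  idx[idx == 0L] <- 1L
  x[which(ok)][idx]
}
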