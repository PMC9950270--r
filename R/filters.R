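#' Zero-phase Butterworth filtering with reflective edge padding
#'
#' Applies a Butterworth filter forward and backward (zero phase lag, squared
#' magnitude response). Before each pass the series is extended by odd
#' (point-reflected) padding of `3 * order` coefficients per edge, which
#' suppresses the startup transient on short records.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param low,high band edges in Hz; set `low = NULL` for a low-pass, `high =
#'   NULL` for a high-pass.
#' @param order overall filter order (a band-pass of order 4 is designed with
#'   `signal::butter(2, ...)`, matching the usual IMU-pipeline convention).
#' @return filtered numeric series, same length as `x`.
#' @keywords internal
butter_filtfilt <- function(x, fs, low = NULL, high = NULL, order = 4) {
  stopifnot(is.numeric(x), fs > 0)
  nyq <- fs / 2
  if (!is.null(low) && !is.null(high)) {
    stopifnot(low > 0, high < nyq, low < high)
    ba <- signal::butter(order / 2, c(low, high) / nyq, type = "pass")
  } else if (!is.null(high)) {
    ba <- signal::butter(order, high / nyq, type = "low")
  } else if (!is.null(low)) {
    ba <- signal::butter(order, low / nyq, type = "high")
  } else {
    stop("at least one of `low`, `high` must be given")
  }
  ncoef <- max(length(ba$b), length(ba$a))
  n <- length(x)
  if (n <= 3 * ncoef) stop("too short to filter")
  # pad generously (up to 2 s) so low-frequency startup transients die out
  npad <- min(n - 1L, max(3L * ncoef, round(2 * fs)))
  # the filter state starts at zero, so remove the mean first: for band/high
  # pass the mean is stop-band anyway; for low-pass it is added back below
  m <- mean(x)
  xc <- x - m
  # odd reflection: 2*x[1] - x[k+1] ... keeps the signal value-continuous
  head_pad <- 2 * xc[1] - xc[(npad + 1):2]
  tail_pad <- 2 * xc[n] - xc[(n - 1):(n - npad)]
  xp <- c(head_pad, xc, tail_pad)
  fwd <- as.numeric(signal::filter(ba, xp))
  out <- rev(as.numeric(signal::filter(ba, rev(fwd))))[(npad + 1):(npad + n)]
  if (is.null(low)) out <- out + m   # low-pass: restore the DC level
  out
}
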