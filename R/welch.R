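#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with a Hann taper, 500-sample segments, 50%
#' overlap and a 0.1 Hz frequency grid (the segment length at 50 Hz sets the
#' resolution). Each segment is mean-removed before tapering. When the series
#' is shorter than one segment the whole series forms a single segment,
#' zero-padded to the nominal FFT length so the grid step is preserved, and
#' the estimate is flagged `short = TRUE`. One-sided scaling satisfies
#' Parseval: `sum(psd) * df` equals the analyzed variance (up to taper bias).
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param window_len segment length in samples.
#' @param overlap overlap fraction between consecutive segments.
#' @return object of class `spectral_estimate`: list with `freqs`, `psd`,
#'   `window_len`, `overlap`, `df`, `short`.
#' @export
welch_psd <- function(x, fs, window_len = 500L, overlap = 0.5) {
  n <- length(x)
  if (n < 250) stop("too short for PSD (need >= 250 samples)")
  nfft <- window_len
  short <- n < window_len
  seg_len <- if (short) n else window_len
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- hann_window(seg_len)
  scale <- 1 / (fs * sum(w^2))
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    if (short) seg <- c(seg, numeric(nfft - seg_len))
    sp <- stats::fft(seg)[1:(nfft %/% 2 + 1)]
    acc <- acc + (Mod(sp)^2) * scale
  }
  psd <- acc / length(starts)
  psd[2:(length(psd) - 1)] <- 2 * psd[2:(length(psd) - 1)]  # one-sided
  structure(list(freqs = (0:(nfft %/% 2)) * fs / nfft, psd = psd,
                 window_len = window_len, overlap = overlap, df = fs / nfft,
                 short = short),
            class = "spectral_estimate")
}

hann_window <- function(m) 0.5 - 0.5 * cos(2 * pi * seq(0, m - 1) / (m - 1))

#' Relative power of a spectral estimate in a frequency band
#'
#' Trapezoid band power over the half-open band `[lo, hi)` divided by the
#' trapezoid total power over the full one-sided grid.
#'
#' @param spec a [welch_psd()] estimate.
#' @param band `c(lo, hi)` in Hz.
#' @return fraction in \[0, 1\], or `NA` for a zero-power spectrum.
#' @export
relative_band_power <- function(spec, band) {
  stopifnot(band[1] >= 0, band[2] <= max(spec$freqs) + spec$df / 2)
  total <- pracma::trapz(spec$freqs, spec$psd)
  if (total <= 0) return(NA_real_)
  sel <- spec$freqs >= band[1] & spec$freqs < band[2]
  if (sum(sel) < 2) return(0)
  pracma::trapz(spec$freqs[sel], spec$psd[sel]) / total
}

# argmax frequency of a spectrum restricted to a band (NA if no power)
spectral_peak <- function(spec, band = c(2, 12)) {
  sel <- spec$freqs >= band[1] & spec$freqs <= band[2]
  if (!any(sel) || all(spec$psd[sel] <= 0)) return(NA_real_)
  spec$freqs[sel][which.max(spec$psd[sel])]
}
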