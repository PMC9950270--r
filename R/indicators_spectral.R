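#' Relative power in a window around the spectral peak
#'
#' Finds the spectral peak inside the tremor-relevant band and returns the
#' relative power (see [relative_band_power()]) in the interval
#' `peak +/- halfwidth` — the `RPW_G_filt_max` indicator when applied to the
#' angular-velocity spectrum.
#'
#' @param spec a [welch_psd()] estimate.
#' @param peak_band band searched for the peak, Hz.
#' @param halfwidth half-width of the interval around the peak, Hz.
#' @return fraction in \[0, 1\], `NA` when no peak exists in the band.
#' @export
rpw_peak_band <- function(spec, peak_band = c(2, 12), halfwidth = 1) {
  f_peak <- spectral_peak(spec, peak_band)
  if (is.na(f_peak)) return(NA_real_)
  relative_band_power(spec, c(max(0, f_peak - halfwidth), f_peak + halfwidth))
}

#' Mean harmonic power of the tremor component
#'
#' Natural log of the mean Welch PSD density in `peak_freq +/- halfwidth` Hz
#' of the tremor acceleration expressed in mm/s^2 — a measure of how much
#' high-frequency (tremor-band) power the acceleration carries.
#'
#' @param trem a [extract_tremor()] result (tremor series in m/s^2).
#' @param halfwidth half-width around the tremor peak, Hz.
#' @return `log((mm/s^2)^2 / Hz)` value, `NA` when the tremor peak is
#'   undefined.
#' @export
mean_harmonic_power <- function(trem, halfwidth = 1) {
  if (is.na(trem$peak_freq)) return(NA_real_)
  sp <- welch_psd(trem$tremor * 1000, trem$fs)   # m/s^2 -> mm/s^2
  sel <- sp$freqs >= trem$peak_freq - halfwidth &
    sp$freqs <= trem$peak_freq + halfwidth
  m <- mean(sp$psd[sel])
  if (m <= 0) return(NA_real_)
  log(m)
}

#' Windowed root-mean-square amplitude
#'
#' RMS over non-overlapping windows of `win_s` seconds, reduced either by the
#' mean across windows (`RMS_A`, `RMS_G`: 10-s windows) or by the maximum
#' after a 3-window moving average (`RMS_G_filt_max`: 1-s windows on the
#' peak-band-filtered angular velocity). A series shorter than one window
#' falls back to a single window covering the whole series.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param win_s window length, s.
#' @param reduce `"mean"` or `"max"`.
#' @return RMS amplitude in the units of `x`.
#' @export
windowed_rms <- function(x, fs, win_s = 10, reduce = c("mean", "max")) {
  reduce <- match.arg(reduce)
  wlen <- round(win_s * fs)
  n <- length(x)
  if (n < wlen) {
    r <- sqrt(mean(x^2))
    return(r)
  }
  starts <- seq(1L, n - wlen + 1L, by = wlen)
  r <- vapply(starts, function(s) sqrt(mean(x[s:(s + wlen - 1L)]^2)),
              numeric(1))
  if (reduce == "mean") return(mean(r))
  if (length(r) >= 3) r <- stats::filter(r, rep(1 / 3, 3), sides = 2)
  max(r, na.rm = TRUE)
}

#' Tremor signal-to-noise ratio
#'
#' Band-passes the tremor component to `peak_freq +/- halfwidth` Hz
#' (zero-phase 4th-order Butterworth) and returns the linear power ratio of
#' the in-band part to the remainder.
#'
#' @param trem a [extract_tremor()] result.
#' @param halfwidth half-width around the tremor peak, Hz.
#' @return linear power ratio, `NA` when the tremor peak is undefined.
#' @export
snr_tremor <- function(trem, halfwidth = 1) {
  if (is.na(trem$peak_freq)) return(NA_real_)
  lo <- max(0.5, trem$peak_freq - halfwidth)
  hi <- min(trem$fs / 2 - 0.5, trem$peak_freq + halfwidth)
  inband <- butter_filtfilt(trem$tremor, trem$fs, lo, hi, order = 4)
  p_in <- mean(inband^2)
  p_out <- mean((trem$tremor - inband)^2)
  if (p_out <= 0) return(Inf)
  p_in / p_out
}

#' Spectral outlier level of the PSD peak
#'
#' Over the 2-12 Hz grid of a spectral estimate: the relative outlier level is
#' the distance between the PSD peak and the PSD mean in units of the PSD
#' standard deviation (population), and the amplitude-times-outlier-level is
#' that value multiplied by the peak density. Both grow as the spectral peak
#' becomes more pronounced relative to the surrounding spectrum.
#'
#' @param spec a [welch_psd()] estimate.
#' @param band evaluation band, Hz.
#' @return named vector `c(Out_Lev_Rel, AmpXOut_Lev)`; both `NA` for a flat
#'   spectrum.
#' @export
outlier_level <- function(spec, band = c(2, 12)) {
  sel <- spec$freqs >= band[1] & spec$freqs <= band[2]
  if (!any(sel)) stop("spectrum has no grid points in the evaluation band")
  p <- spec$psd[sel]
  s <- sd_pop(p)
  if (s <= 0) return(c(Out_Lev_Rel = NA_real_, AmpXOut_Lev = NA_real_))
  olr <- (max(p) - mean(p)) / s
  c(Out_Lev_Rel = olr, AmpXOut_Lev = olr * max(p))
}
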