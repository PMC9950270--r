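#' Drawing execution time
#'
#' Time span from the first to the last pen-on-paper sample, mid-air time
#' included (start-to-end span of the drawing).
#'
#' @param seg a [segment_strokes()] result.
#' @param fs sampling rate, Hz.
#' @return seconds, or `NA` when no stroke was detected.
#' @export
execution_time <- function(seg, fs) {
  if (seg$n_strokes < 1) return(NA_real_)
  on <- which(seg$on_paper_mask)
  (on[length(on)] - on[1] + 1) / fs
}

#' Consecutive-extrema differences of a series
#'
#' Absolute differences between the values at consecutive local extrema
#' (peak-to-valley swings), summarized by their mean and coefficient of
#' variation (population standard deviation over mean).
#'
#' @param x numeric series (band-passed angular velocity norm or raw force).
#' @param prominence_frac passed to [find_extrema()].
#' @return named vector `c(avg, cv)`; both `NA` with fewer than 3 extrema.
#' @export
cons_peak_diff <- function(x, prominence_frac = 0.02) {
  ext <- find_extrema(x, prominence_frac)
  if (length(ext) < 3) return(c(avg = NA_real_, cv = NA_real_))
  d <- abs(diff(x[ext]))
  c(avg = mean(d), cv = sd_pop(d) / mean(d))
}

sd_pop <- function(v) sqrt(mean((v - mean(v))^2))

#' Summary statistics of pen-tip force
#'
#' Mean, coefficient of variation and overshoot (maximum minus median) of the
#' on-paper force samples.
#'
#' @param force on-paper force samples.
#' @return named vector `c(F_Avg, F_CV, F_OVS)`.
#' @export
force_stats <- function(force) {
  if (length(force) < 10) stop("need >= 10 on-paper force samples")
  m <- mean(force)
  c(F_Avg = m,
    F_CV = if (m > 0) sd_pop(force) / m else NA_real_,
    F_OVS = max(force) - stats::median(force))
}

#' Rate of local extrema per second
#'
#' Number of local extrema (see [find_extrema()]) divided by the analyzed
#' duration; quantifies oscillations in force (`NC_F`) and inversions in the
#' kinematic norms (`NC_A`, `NC_G`).
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param prominence_frac passed to [find_extrema()].
#' @return extrema per second (>= 0).
#' @export
rate_of_changes <- function(x, fs, prominence_frac = 0.02) {
  dur <- length(x) / fs
  if (dur <= 0) return(NA_real_)
  length(find_extrema(x, prominence_frac)) / dur
}

#' Spectral arc length (SPARC) smoothness metric
#'
#' Arc length of the normalized magnitude spectrum of the series up to an
#' adaptive cutoff: the cutoff is the highest frequency not above `f_max`
#' where the normalized spectrum still reaches `threshold_pct`% of its peak.
#' More negative values indicate a less smooth (more spectrally spread)
#' movement. The spectrum is computed on a zero-padded FFT with grid step at
#' most `grid_hz`.
#'
#' @param x numeric series (band-passed kinematic norm).
#' @param fs sampling rate, Hz.
#' @param threshold_pct amplitude threshold as a percentage of the spectral
#'   peak (the noise-removal knob; 10, 20, 30, 40, 45 or 50).
#' @param f_max upper frequency bound for the cutoff search, Hz.
#' @param grid_hz maximum spectral grid step, Hz.
#' @return SPARC value (<= 0), or `NA` for an all-zero series.
#' @export
sparc <- function(x, fs, threshold_pct = 10, f_max = 20, grid_hz = 0.05) {
  if (length(x) < 2 * fs) stop("need at least 2 s of signal for SPARC")
  if (all(x == 0)) return(NA_real_)
  nfft <- 2^ceiling(log2(max(length(x), fs / grid_hz)))
  mag <- Mod(stats::fft(c(x, numeric(nfft - length(x)))))[1:(nfft %/% 2 + 1)]
  freqs <- (0:(nfft %/% 2)) * fs / nfft
  mhat <- mag / max(mag)
  in_range <- freqs <= f_max
  above <- which(in_range & mhat >= threshold_pct / 100)
  i_c <- above[length(above)]             # highest retained frequency bin
  if (i_c < 2) return(NA_real_)
  wc <- freqs[i_c]
  dm <- diff(mhat[1:i_c]) / diff(freqs[1:i_c])
  integrand <- sqrt((1 / wc)^2 + dm^2)
  # trapezoid over the (midpoint-derivative) grid segments
  -sum(integrand * diff(freqs[1:i_c]))
}

#' Log dimensionless jerk (LDLJ) smoothness metric
#'
#' `-ln( (T / peak^2) * integral of ds/dt squared )` with `T` the duration,
#' `peak = max |x|` and the derivative taken by central differences. The
#' quantity is invariant to amplitude scaling; more negative values indicate a
#' less smooth signal.
#'
#' @param x numeric series (band-passed acceleration or angular velocity norm).
#' @param fs sampling rate, Hz.
#' @return LDLJ value, or `NA` for a zero-peak series.
#' @export
ldlj <- function(x, fs) {
  n <- length(x)
  if (n < fs) stop("need at least 1 s of signal for LDLJ")
  s_peak <- max(abs(x))
  if (s_peak == 0) return(NA_real_)
  T_dur <- n / fs
  deriv <- central_diff(x, fs)
  int_sq <- pracma::trapz(seq_len(n) / fs, deriv^2)
  -log((T_dur / s_peak^2) * int_sq)
}

central_diff <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

#' Pen-tilt summary statistics
#'
#' Mean, population variance and coefficient of variation of the tilt series
#' over the on-paper samples.
#'
#' @param tilt tilt series in degrees.
#' @return named vector `c(Tilt_Avg, Tilt_Var, Tilt_CV)`.
#' @export
tilt_stats <- function(tilt) {
  if (length(tilt) < 10) stop("need >= 10 tilt samples")
  m <- mean(tilt)
  v <- mean((tilt - m)^2)
  c(Tilt_Avg = m, Tilt_Var = v,
    Tilt_CV = if (abs(m) > .Machine$double.eps^0.5) sqrt(v) / m else NA_real_)
}
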