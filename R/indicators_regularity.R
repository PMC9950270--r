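#' Approximate entropy (ApEn)
#'
#' Standard ApEn(m, r): `Phi_m - Phi_{m+1}` with Chebyshev distance between
#' embedded templates, self-matches included. Low values indicate a regular,
#' predictable series (e.g. sustained tremor); white noise scores high.
#'
#' @param x numeric series (typically the EMD tremor component).
#' @param m embedding dimension (default 2).
#' @param r tolerance; default `0.2 * sd(x)` (population sd). A constant
#'   series returns 0.
#' @return ApEn in nats (>= 0 up to float rounding).
#' @export
approximate_entropy <- function(x, m = 2L, r = NULL) {
  n <- length(x)
  if (n < 100) stop("need >= 100 samples for ApEn")
  if (is.null(r)) r <- 0.2 * sd_pop(x)
  if (r <= 0) return(0)
  D <- abs(outer(x, x, "-"))
  phi <- function(mm) {
    ne <- n - mm + 1L
    M <- D[1:ne, 1:ne]
    if (mm > 1) for (k in 1:(mm - 1)) M <- pmax(M, D[(1 + k):(ne + k), (1 + k):(ne + k)])
    C_i <- rowSums(M <= r) / ne
    mean(log(C_i))
  }
  max(phi(m) - phi(m + 1L), 0)
}

#' Recurrence rate and determinism of a tremor series
#'
#' Time-delay embedding (dimension `dim`, delay at the first zero crossing of
#' the autocorrelation, capped at `max_delay` samples), recurrence when the
#' Euclidean distance between embedded points is at most `eps_frac` of the
#' cloud's maximum pairwise distance. `RR` is the recurrent fraction excluding
#' the main diagonal; `DET` is the fraction of those recurrent points lying on
#' diagonal lines of length at least `l_min`. Series longer than
#' `max_samples` are strided down before embedding to keep the O(n^2) matrix
#' tractable. A constant series returns `RR = DET = 1`.
#'
#' @param x numeric series.
#' @param dim embedding dimension.
#' @param max_delay cap on the embedding delay, samples.
#' @param eps_frac recurrence threshold as a fraction of the maximum pairwise
#'   distance.
#' @param l_min minimum diagonal line length.
#' @param max_samples cap on the number of samples entering the matrix.
#' @return named vector `c(RR, DET)`, both in \[0, 1\].
#' @export
recurrence_measures <- function(x, dim = 3L, max_delay = 10L, eps_frac = 0.2,
                                l_min = 2L, max_samples = 2000L) {
  if (length(x) < 200) stop("need >= 200 samples for recurrence analysis")
  if (length(x) > max_samples)
    x <- x[seq(1, length(x), by = ceiling(length(x) / max_samples))]
  if (sd_pop(x) == 0) return(c(RR = 1, DET = 1))
  tau <- autocorr_zero_delay(x, max_delay)
  ne <- length(x) - (dim - 1L) * tau
  if (ne < 10) return(c(RR = NA_real_, DET = NA_real_))
  emb <- sapply(0:(dim - 1L), function(k) x[(1 + k * tau):(ne + k * tau)])
  dm <- as.matrix(stats::dist(emb))
  eps <- eps_frac * max(dm)
  R <- dm <= eps
  n_off <- ne^2 - ne
  rec_off <- sum(R) - ne
  rr <- rec_off / n_off
  # points on diagonal lines (parallel to the main diagonal) of length >= l_min
  det_pts <- 0
  for (k in 1:(ne - 1)) {
    diag_k <- R[cbind(1:(ne - k), (1 + k):ne)]
    runs <- rle(diag_k)
    det_pts <- det_pts + 2 * sum(runs$lengths[runs$values & runs$lengths >= l_min])
  }
  c(RR = rr, DET = if (rec_off > 0) det_pts / rec_off else NA_real_)
}

autocorr_zero_delay <- function(x, max_delay = 10L) {
  ac <- stats::acf(x, lag.max = max_delay, plot = FALSE)$acf[-1]
  z <- which(ac <= 0)
  if (length(z)) z[1] else max_delay
}

#' Tremor stability index (TSI)
#'
#' Band-passes the tremor series to 2-12 Hz, segments it into cycles at
#' successive positive-going zero crossings (sub-sample interpolated),
#' converts cycle lengths to instantaneous frequencies and returns the
#' interquartile range of the consecutive-cycle frequency differences. A
#' perfectly periodic tremor gives 0; a tremor whose frequency wanders gives
#' a large TSI.
#'
#' @param x tremor series.
#' @param fs sampling rate, Hz.
#' @param band band-pass edges, Hz.
#' @param min_cycles minimum number of detected cycles.
#' @return TSI in Hz, or `NA` with fewer than `min_cycles` cycles.
#' @export
tremor_stability_index <- function(x, fs, band = c(2, 12), min_cycles = 10L) {
  if (all(x == 0)) return(NA_real_)
  xf <- butter_filtfilt(x, fs, band[1], band[2], order = 4)
  i <- which(xf[-length(xf)] < 0 & xf[-1] >= 0)
  if (length(i) < min_cycles + 1) return(NA_real_)
  tc <- i + xf[i] / (xf[i] - xf[i + 1])   # sub-sample crossing positions
  tsi_from_cycle_freqs(fs / diff(tc))
}

#' @rdname tremor_stability_index
#' @param f_cyc vector of per-cycle instantaneous frequencies, Hz.
#' @details `tsi_from_cycle_freqs()` is the final reduction step: the IQR of
#'   consecutive-cycle frequency differences, usable directly on a
#'   cycle-frequency list.
#' @export
tsi_from_cycle_freqs <- function(f_cyc) {
  df <- diff(f_cyc)
  if (length(df) < 2) return(NA_real_)
  stats::IQR(df)
}

#' Maximum windowed angular-velocity change rate
#'
#' Mean absolute first derivative (central differences) of the band-passed
#' angular velocity norm over non-overlapping 1-s windows; the maximum across
#' windows is retained (`G_Rate_max`).
#'
#' @param x band-passed angular velocity norm, deg/s.
#' @param fs sampling rate, Hz.
#' @param win_s window length, s.
#' @return deg/s^2.
#' @export
gyro_change_rate <- function(x, fs, win_s = 1) {
  n <- length(x)
  wlen <- round(win_s * fs)
  if (n < wlen) stop("need at least one full window")
  deriv <- abs(central_diff(x, fs))
  starts <- seq(1L, n - wlen + 1L, by = wlen)
  max(vapply(starts, function(s) mean(deriv[s:(s + wlen - 1L)]), numeric(1)))
}
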