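#' Empirical mode decomposition by standard sifting
#'
#' Decomposes a series into intrinsic mode functions (IMFs) using the classic
#' sifting procedure: cubic-spline envelopes through the local maxima and
#' minima (end effects handled by mirroring the two outermost extrema past
#' each edge), with the standard-deviation stopping criterion
#' `sum((h_prev - h)^2 / h_prev^2) <= sd_stop` or a cap on sift iterations.
#' Extraction stops when the residue has fewer than 4 extrema (monotone /
#' trend-like) or `max_imf` IMFs have been extracted. The decomposition is
#' exactly complete: `rowSums(imfs) + residue == x` up to float rounding.
#'
#' @param x numeric series.
#' @param sd_stop standard-deviation sifting stop criterion (default 0.2).
#' @param max_sift maximum sift iterations per IMF (default 50).
#' @param max_imf maximum number of IMFs (default 10).
#' @return list with `imfs` (n x k matrix) and `residue` (length-n vector).
#' @export
emd <- function(x, sd_stop = 0.2, max_sift = 50L, max_imf = 10L) {
  n <- length(x)
  stopifnot(n >= 8)
  residue <- as.numeric(x)
  imfs <- matrix(numeric(0), nrow = n, ncol = 0)
  for (k in seq_len(max_imf)) {
    ext <- sift_extrema(residue)
    if (length(ext$max_i) + length(ext$min_i) < 4) break
    h <- residue
    for (it in seq_len(max_sift)) {
      env <- envelope_mean(h)
      if (is.null(env)) break
      h_new <- h - env
      sd_k <- sum((h - h_new)^2) / sum(h^2 + .Machine$double.eps)
      h <- h_new
      if (sd_k <= sd_stop) break
    }
    imfs <- cbind(imfs, h)
    residue <- residue - h
  }
  colnames(imfs) <- if (ncol(imfs)) paste0("imf", seq_len(ncol(imfs)))
  list(imfs = imfs, residue = residue)
}

# strict local extrema for sifting (no prominence guard: EMD needs them all)
sift_extrema <- function(x) {
  idx <- find_extrema(x, prominence_frac = 0)
  if (!length(idx)) return(list(max_i = integer(0), min_i = integer(0)))
  is_max <- vapply(idx, function(i) {
    left <- if (i > 1) x[i] - x[i - 1] else -(x[i + 1] - x[i])
    left > 0
  }, logical(1))
  list(max_i = idx[is_max], min_i = idx[!is_max])
}

# mean of upper and lower cubic-spline envelopes; NULL when too few extrema
envelope_mean <- function(x) {
  n <- length(x)
  ext <- sift_extrema(x)
  if (length(ext$max_i) < 2 || length(ext$min_i) < 2) return(NULL)
  upper <- mirror_spline(ext$max_i, x, n)
  lower <- mirror_spline(ext$min_i, x, n)
  (upper + lower) / 2
}

# cubic spline through (idx, x[idx]) with the two outermost knots mirrored
# past each edge to tame end swings
mirror_spline <- function(idx, x, n) {
  xi <- c(2 - rev(idx[seq_len(min(2, length(idx)))]), idx,
          2 * n - rev(idx[seq.int(max(1, length(idx) - 1), length(idx))]))
  yi <- c(rev(x[idx[seq_len(min(2, length(idx)))]]), x[idx],
          rev(x[idx[seq.int(max(1, length(idx) - 1), length(idx))]]))
  keep <- !duplicated(xi)
  stats::spline(xi[keep], yi[keep], xout = seq_len(n), method = "natural")$y
}

#' Extract the tremor component of an acceleration norm via EMD
#'
#' Runs [emd()] on the mean-removed acceleration norm, assigns each IMF a
#' dominant frequency (argmax of its Welch PSD) and sums the IMFs whose
#' dominant frequency lies inside the tremor-relevant band (2-12 Hz, mirroring
#' the kinematic band-pass). The residual is the input minus the tremor sum,
#' so tremor + residual reconstructs the input exactly. The tremor peak
#' frequency is the argmax of the Welch PSD of the tremor sum; when no IMF
#' falls in band the tremor series is all zero and `peak_freq` is `NA`
#' (downstream tremor indicators then return missing).
#'
#' @param x acceleration norm series, m/s^2 (typically `acc_mag_raw`).
#' @param fs sampling rate, Hz.
#' @param band IMF selection band, Hz.
#' @param ... passed to [emd()].
#' @return object of class `tremor_component`: list with `tremor`, `residual`,
#'   `imf_table` (dominant frequency and variance fraction per IMF),
#'   `peak_freq` (Hz or `NA`), `fs`.
#' @export
extract_tremor <- function(x, fs, band = c(2, 12), ...) {
  if (length(x) < 4 * fs) stop("need at least 4 s of signal for EMD")
  dec <- emd(x, ...)
  k <- ncol(dec$imfs)
  var_x <- stats::var(x)
  if (k == 0) {
    imf_table <- data.frame(imf = integer(0), dom_freq = numeric(0),
                            var_frac = numeric(0))
    sel <- logical(0)
  } else {
    dom <- numeric(k)
    vf <- numeric(k)
    for (j in seq_len(k)) {
      sp <- welch_psd(dec$imfs[, j], fs)
      dom[j] <- sp$freqs[which.max(sp$psd)]
      vf[j] <- stats::var(dec$imfs[, j]) / max(var_x, .Machine$double.eps)
    }
    imf_table <- data.frame(imf = seq_len(k), dom_freq = dom, var_frac = vf)
    sel <- dom >= band[1] & dom <= band[2]
  }
  tremor <- if (any(sel)) rowSums(dec$imfs[, sel, drop = FALSE]) else
    numeric(length(x))
  peak_freq <- NA_real_
  if (any(sel)) {
    sp <- welch_psd(tremor, fs)
    pf <- sp$freqs[which.max(sp$psd)]
    if (pf > 0 && pf < fs / 2) peak_freq <- pf
  }
  structure(list(tremor = tremor, residual = x - tremor,
                 imf_table = imf_table, peak_freq = peak_freq, fs = fs),
            class = "tremor_component")
}
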