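# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# O(n^2) template-matching ApEn, straight from the definition
oracle_apen <- function(x, m = 2, r = 0.2 * sqrt(mean((x - mean(x))^2))) {
  n <- length(x)
  phi <- function(mm) {
    ne <- n - mm + 1
    counts <- numeric(ne)
    for (i in seq_len(ne)) {
      c_i <- 0
      for (j in seq_len(ne)) {
        d <- 0
        for (k in 0:(mm - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r) c_i <- c_i + 1
      }
      counts[i] <- c_i / ne
    }
    mean(log(counts))
  }
  max(phi(m) - phi(m + 1), 0)
}

# double-loop recurrence matrix (Euclidean) for a given embedding
oracle_recurrence_matrix <- function(x, dim, tau, eps) {
  ne <- length(x) - (dim - 1) * tau
  R <- matrix(FALSE, ne, ne)
  for (i in seq_len(ne)) {
    for (j in seq_len(ne)) {
      d2 <- 0
      for (k in 0:(dim - 1)) d2 <- d2 + (x[i + k * tau] - x[j + k * tau])^2
      R[i, j] <- sqrt(d2) <= eps
    }
  }
  R
}

# exhaustive scan of strict slope sign changes (no prominence guard)
oracle_extrema_count <- function(x) {
  cnt <- 0L
  last_slope <- 0
  for (i in 2:length(x)) {
    slope <- sign(x[i] - x[i - 1])
    if (slope != 0) {
      if (last_slope != 0 && slope != last_slope) cnt <- cnt + 1L
      last_slope <- slope
    }
  }
  cnt
}

# direct arc-length integration of a normalized magnitude spectrum
oracle_sparc <- function(x, fs, threshold_pct, f_max = 20) {
  nfft <- 2^ceiling(log2(max(length(x), fs / 0.05)))
  sp <- abs(fft(c(x, numeric(nfft - length(x)))))[1:(nfft / 2 + 1)]
  f <- (0:(nfft / 2)) * fs / nfft
  m <- sp / max(sp)
  idx <- which(f <= f_max & m >= threshold_pct / 100)
  ic <- max(idx)
  wc <- f[ic]
  arc <- 0
  for (i in 2:ic)
    arc <- arc + sqrt(((f[i] - f[i - 1]) / wc)^2 + (m[i] - m[i - 1])^2)
  -arc
}

# band power fraction from a single unwindowed periodogram (coarse oracle:
# agrees with Welch to within leakage, used at 5% tolerance)
oracle_band_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  x <- x - mean(x)
  p <- abs(fft(x))^2
  f <- (0:(n - 1)) * fs / n
  half <- f <= fs / 2
  sum(p[half & f >= lo & f < hi]) / sum(p[half])
}

# phase-continuous tone with prescribed per-cycle frequencies
make_cycle_tone <- function(f_cyc, fs, amp = 1) {
  t_edge <- c(0, cumsum(1 / f_cyc))
  n <- floor(t_edge[length(t_edge)] * fs)
  tt <- (seq_len(n) - 1) / fs
  idx <- pmin(findInterval(tt, t_edge), length(f_cyc))
  amp * sin(2 * pi * cumsum(f_cyc[idx]) / fs)
}

# minimal well-formed recording around given channel series
make_rec <- function(n = 600, fs = 50, acc = NULL, gyro = NULL, force = NULL,
                     ...) {
  t <- (seq_len(n) - 1) / fs
  if (is.null(acc)) acc <- cbind(0, 0, rep(9.81, n))
  if (is.null(gyro)) gyro <- matrix(0, n, 3)
  if (is.null(force)) force <- rep(10, n)
  pen_recording(t, acc, gyro, force, fs = fs, ...)
}

# subject-level indicator table with controlled effects for classifier tests:
# `d` is the standardized group difference applied to the first `k` indicators
make_feature_table <- function(n_per_group = 29, d = 3, k = 5, p = 10,
                               seed = 1) {
  set.seed(seed)
  group <- rep(c("PD", "control"), each = n_per_group)
  X <- matrix(rnorm(2 * n_per_group * p), 2 * n_per_group, p)
  X[group == "PD", seq_len(k)] <- X[group == "PD", seq_len(k)] + d
  cols <- indicator_names()[seq_len(p)]
  tab <- data.frame(subject_id = sprintf("S%02d", seq_along(group)),
                    group = group, hand = "dominant")
  tab[cols] <- as.data.frame(X)
  tab
}
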