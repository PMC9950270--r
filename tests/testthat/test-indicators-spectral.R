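fs <- 50

test_that("Welch PSD locates tones and satisfies Parseval within 10%", {
  t <- seq(0, 60, by = 1 / fs)
  sp <- welch_psd(sin(2 * pi * 5 * t), fs)
  expect_equal(sp$freqs[which.max(sp$psd)], 5, tolerance = 0.1)
  expect_equal(sp$df, 0.1)
  expect_equal(pracma::trapz(sp$freqs, sp$psd), 0.5, tolerance = 0.05)

  set.seed(31)
  spn <- welch_psd(rnorm(3000), fs)
  expect_equal(pracma::trapz(spn$freqs, spn$psd), 1, tolerance = 0.1)

  expect_error(welch_psd(rnorm(200), fs), "too short")
  expect_true(welch_psd(rnorm(300), fs)$short)
})

test_that("relative band power matches construction and the periodogram oracle", {
  t <- seq(0, 60, by = 1 / fs)
  x5 <- sin(2 * pi * 5 * t)
  sp5 <- welch_psd(x5, fs)
  expect_gte(relative_band_power(sp5, c(4, 7)), 0.95)
  expect_lte(relative_band_power(sp5, c(0, 2)), 0.02)

  x2 <- sin(2 * pi * 1 * t) + sin(2 * pi * 5 * t)
  sp2 <- welch_psd(x2, fs)
  expect_equal(relative_band_power(sp2, c(0, 2)), 0.5, tolerance = 0.05)
  expect_equal(relative_band_power(sp2, c(4, 7)), 0.5, tolerance = 0.05)

  set.seed(6)
  for (x in list(x2, rnorm(2000), x5 + rnorm(length(x5), 0, 0.5))) {
    sp <- welch_psd(x, fs)
    for (b in list(c(0, 2), c(2, 4), c(4, 7), c(8, 12)))
      expect_lt(abs(relative_band_power(sp, b) -
                      oracle_band_fraction(x, fs, b[1], b[2])), 0.05)
  }
})

test_that("the four reporting bands are disjoint and sub-normalized for any input", {
  set.seed(61)
  bands <- list(c(0, 2), c(2, 4), c(4, 7), c(8, 12))
  for (i in 1:5) {
    x <- rnorm(1500) + sin(2 * pi * runif(1, 0.5, 10) * seq_len(1500) / fs)
    sp <- welch_psd(x, fs)
    fr <- vapply(bands, relative_band_power, numeric(1), spec = sp)
    expect_true(all(fr >= 0 & fr <= 1))
    expect_lte(sum(fr), 1)
  }
})

test_that("relative power around the spectral peak matches flat and tonal oracles", {
  t <- seq(0, 120, by = 1 / fs)
  expect_equal(rpw_peak_band(welch_psd(sin(2 * pi * 5 * t), fs)), 1,
               tolerance = 0.02)

  two <- sin(2 * pi * 4 * t) + sin(2 * pi * 10 * t)
  expect_equal(rpw_peak_band(welch_psd(two, fs)), 0.5, tolerance = 0.05)

  set.seed(13)
  x <- rnorm(6000)
  sp <- welch_psd(x, fs)
  pk <- spiralpen:::spectral_peak(sp, c(2, 12))
  expect_equal(rpw_peak_band(sp),
               oracle_band_fraction(x, fs, pk - 1, pk + 1), tolerance = 0.05)
})

test_that("mean harmonic power scales as log amplitude squared and is frequency-shift invariant", {
  t <- seq(0, 30, by = 1 / fs)
  trem_at <- function(a, f) {
    x <- a * sin(2 * pi * f * t) + sin(2 * pi * 0.5 * t)
    extract_tremor(x - mean(x), fs)
  }
  m1 <- mean_harmonic_power(trem_at(0.5, 5))
  m2 <- mean_harmonic_power(trem_at(1.0, 5))
  expect_equal(m2 - m1, log(4), tolerance = 0.1)
  m4 <- mean_harmonic_power(trem_at(0.5, 4))
  m6 <- mean_harmonic_power(trem_at(0.5, 6))
  expect_equal(m4, m6, tolerance = 0.1)
})

test_that("windowed RMS matches closed forms and max-reduce dominates on bursts", {
  expect_equal(windowed_rms(rep(-3, 1000), fs, 10, "mean"), 3)
  expect_equal(windowed_rms(rep(-3, 1000), fs, 1, "max"), 3)
  t <- seq(0, 60, by = 1 / fs)
  expect_equal(windowed_rms(2 * sin(2 * pi * 5 * t), fs, 10, "mean"),
               2 / sqrt(2), tolerance = 0.02 * 2 / sqrt(2))
  burst <- sin(2 * pi * 5 * t) * ifelse(t >= 20 & t < 30, 3, 1)
  expect_gt(windowed_rms(burst, fs, 1, "max"),
            windowed_rms(burst, fs, 1, "mean"))
})

test_that("tremor SNR reflects the constructed in-band / out-of-band power split", {
  t <- seq(0, 60, by = 1 / fs)
  pure <- extract_tremor(sin(2 * pi * 5 * t) + sin(2 * pi * 0.5 * t), fs)
  expect_gt(snr_tremor(pure), 20)

  # tone + band-limited out-of-band disturbance of equal power in the tremor sum
  set.seed(17)
  tone <- sin(2 * pi * 5 * t)
  noise <- spiralpen:::butter_filtfilt(rnorm(length(t), 0, 3), fs, 8, 11)
  noise <- noise * sqrt(mean(tone^2) / mean(noise^2))
  fake <- structure(list(tremor = tone + noise, residual = -(tone + noise),
                         peak_freq = 5, fs = fs), class = "tremor_component")
  expect_equal(snr_tremor(fake), 1, tolerance = 0.2)
})

test_that("outlier level matches the hand-computed constructed spectrum", {
  psd <- c(rep(1, 60), 101, rep(1, 39))
  spec <- structure(list(freqs = seq(2, 11.9, by = 0.1), psd = psd, df = 0.1),
                    class = "spectral_estimate")
  ol <- outlier_level(spec)
  expect_equal(ol[["Out_Lev_Rel"]], 99 / sqrt(99), tolerance = 1e-9)
  expect_equal(ol[["AmpXOut_Lev"]], 99 / sqrt(99) * 101, tolerance = 1e-9)

  flat <- structure(list(freqs = seq(2, 11.9, by = 0.1),
                         psd = rep(2, 100), df = 0.1),
                    class = "spectral_estimate")
  expect_true(all(is.na(outlier_level(flat))))
})

test_that("outlier level grows monotonically as the tremor line sharpens", {
  t <- seq(0, 60, by = 1 / fs)
  set.seed(23)
  noise <- rnorm(length(t), 0, 1)
  amps <- c(0.2, 0.4, 0.8, 1.6, 3.2)
  olr <- vapply(amps, function(a) {
    sp <- welch_psd(a * sin(2 * pi * 5 * t) + noise, fs)
    outlier_level(sp)[["Out_Lev_Rel"]]
  }, numeric(1))
  expect_equal(cor(olr, amps, method = "spearman"), 1)
})
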