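test_that("well-formed CSV round-trips through read/write to 6 significant digits", {
  set.seed(11)
  n <- 500
  rec <- make_rec(n,
                  acc = cbind(rnorm(n), rnorm(n), 9.81 + rnorm(n)),
                  gyro = matrix(rnorm(3 * n, 0, 10), n, 3),
                  force = runif(n, 1, 20))
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f)
  back <- read_recording(f)
  expect_s3_class(back, "pen_recording")
  expect_length(back$t, n)
  expect_equal(back$acc, rec$acc, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$gyro, rec$gyro, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$force, rec$force, tolerance = 1e-6)
})

test_that("reader restores a single dropped sample by linear interpolation", {
  n <- 500
  t <- (seq_len(n) - 1) / 50
  ramp <- seq(0, 10, length.out = n)   # linear -> midpoint exact
  df <- data.frame(t = t, acc_x = ramp, acc_y = 0, acc_z = 9.81,
                   gyro_x = 0, gyro_y = 0, gyro_z = 0, force = 5)
  drop <- 100
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[-drop, ], f, row.names = FALSE)
  rec <- read_recording(f)
  expect_length(rec$t, n)
  expect_equal(rec$acc[drop, 1], (ramp[drop - 1] + ramp[drop + 1]) / 2,
               tolerance = 1e-9)
})

test_that("reader rejects malformed files with informative errors", {
  n <- 300
  t <- (seq_len(n) - 1) / 50
  df <- data.frame(t = t, acc_x = 0, acc_y = 0, acc_z = 9.81,
                   gyro_x = 0, gyro_y = 0, gyro_z = 0, force = 5)
  f <- withr::local_tempfile(fileext = ".csv")

  write.csv(df[, -8], f, row.names = FALSE)
  expect_error(read_recording(f), "missing column.*force")

  df2 <- df; df2$force[17] <- -1
  write.csv(df2, f, row.names = FALSE)
  expect_error(read_recording(f), "negative force at row 17")

  write.csv(df[-(50:52), ], f, row.names = FALSE)   # 3-sample hole
  expect_error(read_recording(f), "gap")
})

test_that("band-pass keeps in-band tones and rejects out-of-band and DC", {
  fs <- 50
  t <- seq(0, 30, by = 1 / fs)
  tone5 <- sin(2 * pi * 5 * t)
  # designed transfer function: near-unit passband, deep stopband
  expect_gte(sqrt(mean(spiralpen:::butter_filtfilt(tone5, fs, 2, 12)^2)) /
               sqrt(mean(tone5^2)), 0.95)
  tone05 <- sin(2 * pi * 0.5 * t)
  expect_lt(sqrt(mean(spiralpen:::butter_filtfilt(tone05, fs, 2, 12)^2)),
            0.05 * sqrt(mean(tone05^2)))

  # through the norm reduction: a tone riding on the dominant channel offset
  rec5 <- make_rec(length(t), gyro = cbind(20 + tone5, 0, 0))
  sig5 <- preprocess(rec5)
  expect_gte(sqrt(mean(sig5$gyro_mag_bp^2)) / sqrt(mean(tone5^2)), 0.95)

  rec05 <- make_rec(length(t), gyro = cbind(20 + tone05, 0, 0))
  expect_lt(sqrt(mean(preprocess(rec05)$gyro_mag_bp^2)),
            0.05 * sqrt(mean(tone05^2)))

  recdc <- make_rec(length(t))   # constant (0, 0, 9.81)
  expect_lt(max(abs(preprocess(recdc)$acc_mag_bp)), 1e-6)
})

test_that("band-passed norms are zero-mean and zero-phase filtering preserves symmetry", {
  set.seed(7)
  n <- 1500
  rec <- make_rec(n, acc = cbind(rnorm(n), rnorm(n), 9.81 + rnorm(n)))
  sig <- preprocess(rec)
  expect_lt(abs(mean(sig$acc_mag_bp)), 1e-6 * sd(sig$acc_mag_bp))

  # symmetric in-band Gabor pulse: zero-phase filtering must keep it symmetric
  tt <- (seq_len(1001) - 501) / 50
  pulse <- cos(2 * pi * 6 * tt) * exp(-(tt / 0.5)^2)
  out <- spiralpen:::butter_filtfilt(pulse, 50, 2, 12)
  asym <- max(abs(out - rev(out)))
  expect_lt(asym, 1e-9 * max(abs(out)))
})

test_that("acceleration norm is invariant to rigid rotations of the axes", {
  set.seed(42)
  n <- 400
  acc <- cbind(rnorm(n), rnorm(n), 9.81 + rnorm(n))
  norm0 <- sqrt(rowSums(acc^2))
  for (i in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))           # random orthogonal matrix
    if (det(q) < 0) q[, 1] <- -q[, 1]
    norm_r <- sqrt(rowSums((acc %*% q)^2))
    expect_equal(norm_r, norm0, tolerance = 1e-9)
  }
})

test_that("tilt reproduces static geometry", {
  expect_equal(mean(compute_tilt(make_rec(400))), 0, tolerance = 0.01)
  rec90 <- make_rec(400, acc = cbind(rep(9.81, 400), 0, 0))
  expect_equal(mean(compute_tilt(rec90)), 90, tolerance = 0.01)
  rec45 <- make_rec(400, acc = cbind(0, rep(6.937, 400), rep(6.937, 400)))
  expect_equal(mean(compute_tilt(rec45)), 45, tolerance = 0.1)
  recff <- make_rec(400, acc = matrix(1e-3, 400, 3))
  expect_error(compute_tilt(recff), "free-fall")
})

test_that("stroke segmentation counts strokes and internal lifts", {
  fs <- 50
  rec1 <- make_rec(500, force = rep(10, 500))
  seg1 <- segment_strokes(rec1)
  expect_equal(seg1$n_strokes, 1)
  expect_equal(seg1$n_lifts, 0)

  # 3 strokes of 2 s separated by 0.5 s gaps
  prof <- c(rep(10, 100), rep(0, 25), rep(10, 100), rep(0, 25), rep(10, 100))
  seg3 <- segment_strokes(make_rec(length(prof), force = prof))
  expect_equal(seg3$n_strokes, 3)
  expect_equal(seg3$n_lifts, 2)
  expect_equal(sum(seg3$on_paper_mask), 300)

  seg0 <- segment_strokes(make_rec(500, force = rep(0, 500)))
  expect_equal(seg0$n_strokes, 0)
})

test_that("segmentation matches a brute-force threshold scan on random piecewise-constant profiles", {
  set.seed(99)
  for (i in 1:20) {
    k <- sample(3:9, 1)
    lens <- sample(10:80, k, replace = TRUE)          # segments >= 200 ms
    vals <- sample(c(0, 10), k, replace = TRUE)
    prof <- rep(vals, lens)
    if (length(prof) < 300) prof <- c(prof, rep(0, 300 - length(prof)))
    seg <- segment_strokes(make_rec(length(prof), force = prof))
    runs <- rle(prof > 5)
    expect_equal(seg$n_strokes, sum(runs$values))
    expect_equal(seg$n_lifts, max(sum(runs$values) - 1, 0))
  }
})

test_that("QC excludes only traces with more than 20 pen lifts", {
  seg <- function(nl) structure(list(n_lifts = nl), class = "stroke_segmentation")
  expect_false(qc_exclude(seg(0)))
  expect_false(qc_exclude(seg(20)))
  expect_true(qc_exclude(seg(21)))
})
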