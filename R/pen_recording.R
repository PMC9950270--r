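#' Construct a smart-pen trial recording
#'
#' A `pen_recording` holds one trial of uniformly sampled (50 Hz by default)
#' smart-pen signals: tri-axial acceleration (m/s^2, gravity included),
#' tri-axial angular velocity (deg/s) and pen-tip force (arbitrary device
#' units, non-negative), together with the subject descriptors used downstream.
#'
#' @param t time stamps in seconds, strictly increasing uniform grid.
#' @param acc numeric matrix, n x 3, columns x/y/z, m/s^2.
#' @param gyro numeric matrix, n x 3, columns x/y/z, deg/s.
#' @param force numeric vector, length n, >= 0.
#' @param fs sampling rate in Hz.
#' @param subject_id,group,hand,trial subject descriptors; `group` is `"PD"`
#'   or `"control"`, `hand` is `"dominant"` or `"nondominant"`, `trial` 1 or 2.
#' @return an object of class `pen_recording`.
#' @export
pen_recording <- function(t, acc, gyro, force, fs = 50,
                          subject_id = "S00", group = c("control", "PD"),
                          hand = c("dominant", "nondominant"), trial = 1L) {
  group <- match.arg(group)
  hand <- match.arg(hand)
  acc <- as.matrix(acc)
  gyro <- as.matrix(gyro)
  rec <- structure(
    list(t = as.numeric(t), acc = acc, gyro = gyro, force = as.numeric(force),
         fs = fs, subject_id = subject_id, group = group, hand = hand,
         trial = as.integer(trial)),
    class = "pen_recording")
  validate_pen_recording(rec)
  rec
}

validate_pen_recording <- function(rec) {
  n <- length(rec$t)
  if (n < 2) stop("recording must have at least 2 samples")
  if (nrow(rec$acc) != n || nrow(rec$gyro) != n || length(rec$force) != n)
    stop("all channels must have the same length as `t`")
  if (ncol(rec$acc) != 3 || ncol(rec$gyro) != 3)
    stop("acc and gyro must have 3 columns (x, y, z)")
  dt <- diff(rec$t)
  if (any(dt <= 0)) stop("time stamps must be strictly increasing")
  if (any(abs(dt - 1 / rec$fs) > 1e-9))
    stop("time grid is not uniform at 1/fs within 1e-9 s")
  bad <- which(rec$force < 0)
  if (length(bad))
    stop(sprintf("negative force at row %d", bad[1]))
  invisible(rec)
}

#' @exportS3Method base::print
print.pen_recording <- function(x, ...) {
  cat(sprintf(
    "<pen_recording> subject %s (%s, %s hand, trial %d): %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$group, x$hand, x$trial, length(x$t), x$fs,
    length(x$t) / x$fs))
  invisible(x)
}

rec_duration <- function(rec) length(rec$t) / rec$fs

#' Read a smart-pen trial from CSV
#'
#' Expects the header `t,acc_x,acc_y,acc_z,gyro_x,gyro_y,gyro_z,force`
#' (UTF-8, period decimal separator; lines starting with `#` are comments).
#' Slightly non-uniform or singly-dropped time stamps are restored by linear
#' interpolation onto the nominal grid; a gap of 3 or more sample periods is a
#' hard error because tremor spectra are aliasing-sensitive. If a comment line
#' declares `# units:` with acceleration in `g`, values are converted to m/s^2
#' using 9.81 m/s^2.
#'
#' @param path CSV file path.
#' @param fs nominal sampling rate, Hz.
#' @param subject_id,group,hand,trial subject descriptors (see
#'   [pen_recording()]).
#' @return a validated [pen_recording()].
#' @export
read_recording <- function(path, fs = 50, subject_id = "S00",
                           group = "control", hand = "dominant", trial = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  header_lines <- readLines(path, n = 10L, warn = FALSE)
  acc_in_g <- any(grepl("^#\\s*units:.*\\bg\\b", header_lines))
  df <- utils::read.csv(path, comment.char = "#", check.names = TRUE)
  need <- c("t", "acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z", "force")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("format error: missing column(s) ", paste(missing_cols, collapse = ", "))
  bad <- which(df$force < 0)
  if (length(bad))
    stop(sprintf("validation error: negative force at row %d", bad[1]))
  dt <- diff(df$t)
  if (any(dt <= 0)) stop("validation error: non-increasing time stamps")
  gap <- which(dt >= 3 / fs - 1e-9)
  if (length(gap))
    stop(sprintf("validation error: gap >= 3/fs after row %d", gap[1]))
  t0 <- df$t[1]
  n_out <- round((df$t[nrow(df)] - t0) * fs) + 1L
  tg <- t0 + (seq_len(n_out) - 1L) / fs
  regrid <- function(v) stats::approx(df$t, v, xout = tg, rule = 2)$y
  acc <- cbind(regrid(df$acc_x), regrid(df$acc_y), regrid(df$acc_z))
  if (acc_in_g) acc <- acc * 9.81
  gyro <- cbind(regrid(df$gyro_x), regrid(df$gyro_y), regrid(df$gyro_z))
  force <- pmax(regrid(df$force), 0)
  pen_recording(tg - t0, acc, gyro, force, fs = fs, subject_id = subject_id,
                group = group, hand = hand, trial = trial)
}

#' Write a smart-pen trial to CSV
#'
#' Inverse of [read_recording()]; numeric cells are written with enough digits
#' to round-trip to at least 6 significant figures.
#'
#' @param rec a [pen_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(
    t = rec$t,
    acc_x = rec$acc[, 1], acc_y = rec$acc[, 2], acc_z = rec$acc[, 3],
    gyro_x = rec$gyro[, 1], gyro_y = rec$gyro[, 2], gyro_z = rec$gyro[, 3],
    force = rec$force)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: s,m/s2,m/s2,m/s2,deg/s,deg/s,deg/s,arbitrary", con)
  utils::write.table(format(df, digits = 10, scientific = FALSE, trim = TRUE),
                     con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
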