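#' Preprocess a pen recording for indicator extraction
#'
#' Builds the 1-D signals every indicator consumes. Tri-axial acceleration and
#' angular velocity are collapsed to their Euclidean norms (rotation-invariant,
#' the standard reduction for handheld IMU tremor work), which are then
#' (a) mean-removed ("raw" norms, used by the relative-power spectral
#' indicators and the tremor decomposition) and (b) band-pass filtered 2-12 Hz
#' with a zero-phase 4th-order Butterworth filter (used by the time-domain
#' kinematic indicators). Force is left unfiltered. Pen inclination comes from
#' [compute_tilt()].
#'
#' @param rec a [pen_recording()].
#' @param band band-pass edges in Hz.
#' @param tilt_axis device axis along the pen barrel, `"x"`, `"y"` or `"z"`.
#' @return a list of class `pen_signals` with elements `acc_mag_bp`,
#'   `gyro_mag_bp`, `acc_mag_raw`, `gyro_mag_raw`, `force`, `tilt`, `fs`.
#' @export
preprocess <- function(rec, band = c(2, 12), tilt_axis = "z") {
  validate_pen_recording(rec)
  if (length(rec$t) < rec$fs) stop("recording shorter than 1 s")
  acc_norm <- sqrt(rowSums(rec$acc^2))
  gyro_norm <- sqrt(rowSums(rec$gyro^2))
  demean <- function(v) v - mean(v)   # finite-window filtering leaves a tiny DC
  out <- list(
    acc_mag_bp  = demean(butter_filtfilt(acc_norm, rec$fs, band[1], band[2], order = 4)),
    gyro_mag_bp = demean(butter_filtfilt(gyro_norm, rec$fs, band[1], band[2], order = 4)),
    acc_mag_raw = acc_norm - mean(acc_norm),
    gyro_mag_raw = gyro_norm - mean(gyro_norm),
    force = rec$force,
    tilt = compute_tilt(rec, axis = tilt_axis),
    fs = rec$fs)
  class(out) <- "pen_signals"
  out
}

#' Pen inclination angle relative to gravity
#'
#' The gravity direction is estimated by low-pass filtering the raw
#' acceleration (2nd-order Butterworth, 1 Hz cutoff, zero phase); the tilt at
#' each sample is the angle between the estimated gravity vector and the pen's
#' long axis, in degrees (0 = pen vertical along the declared axis).
#'
#' @param rec a [pen_recording()].
#' @param axis device axis along the pen barrel (default `"z"`).
#' @param cutoff low-pass cutoff for the gravity estimate, Hz.
#' @return tilt series in degrees, range \[0, 180\].
#' @export
compute_tilt <- function(rec, axis = "z", cutoff = 1) {
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  g <- apply(rec$acc, 2, butter_filtfilt, fs = rec$fs, low = NULL,
             high = cutoff, order = 2)
  gnorm <- sqrt(rowSums(g^2))
  if (any(gnorm < 0.1))
    stop("free-fall / invalid gravity estimate (|g| < 0.1 m/s^2)")
  ratio <- pmin(pmax(g[, ax] / gnorm, -1), 1)
  acos(ratio) * 180 / pi
}

#' Segment pen-on-paper strokes from the force channel
#'
#' The pen is considered on paper while the tip force exceeds a contact
#' threshold, with hysteresis: contact begins when force rises above
#' `theta` and ends when it falls below `0.5 * theta`. The threshold is
#' adaptive, `max(0.05 * quantile(force, 0.95), noise_floor)`, because device
#' force units are uncalibrated. Candidate strokes shorter than `min_stroke_s`
#' are merged into a neighbor when the separating gap is shorter than a stroke
#' minimum, otherwise dropped. `n_lifts` counts only the off-paper gaps
#' strictly between the first and the last stroke (leading/trailing air time
#' is not a lift).
#'
#' @param rec a [pen_recording()] (only `force` and `fs` are used).
#' @param noise_floor device noise floor in force units.
#' @param min_stroke_s minimum stroke duration, s.
#' @return a list of class `stroke_segmentation` with `n_strokes`, `n_lifts`,
#'   `stroke_intervals` (two-column matrix of half-open sample intervals
#'   `[start, end)`, 1-based starts) and `on_paper_mask`.
#' @export
segment_strokes <- function(rec, noise_floor = 1e-3, min_stroke_s = 0.1) {
  force <- rec$force
  fs <- rec$fs
  n <- length(force)
  theta <- max(0.05 * stats::quantile(force, 0.95, names = FALSE), noise_floor)
  # hysteresis scan: enter contact at > theta, leave at < theta/2
  on <- logical(n)
  state <- FALSE
  for (i in seq_len(n)) {
    state <- if (state) force[i] >= 0.5 * theta else force[i] > theta
    on[i] <- state
  }
  iv <- mask_to_intervals(on)
  min_len <- max(1L, round(min_stroke_s * fs))
  # merge short candidates across short gaps, then drop remaining shorts
  if (nrow(iv) > 1) {
    merged <- iv[1, , drop = FALSE]
    for (k in 2:nrow(iv)) {
      gap <- iv[k, 1] - merged[nrow(merged), 2]
      short <- (iv[k, 2] - iv[k, 1] < min_len) ||
        (merged[nrow(merged), 2] - merged[nrow(merged), 1] < min_len)
      if (short && gap < min_len) {
        merged[nrow(merged), 2] <- iv[k, 2]
      } else {
        merged <- rbind(merged, iv[k, , drop = FALSE])
      }
    }
    iv <- merged
  }
  iv <- iv[iv[, 2] - iv[, 1] >= min_len, , drop = FALSE]
  mask <- logical(n)
  for (k in seq_len(nrow(iv))) mask[iv[k, 1]:(iv[k, 2] - 1L)] <- TRUE
  structure(list(
    n_strokes = nrow(iv),
    n_lifts = max(nrow(iv) - 1L, 0L),
    stroke_intervals = iv,
    on_paper_mask = mask,
    fs = fs), class = "stroke_segmentation")
}

mask_to_intervals <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep] + 1L)[, , drop = FALSE]
}

#' Quality-control exclusion rule for a spiral trace
#'
#' A trace is excluded when it contains an excessive number of pen lifts
#' (strictly more than `max_lifts`, default 20).
#'
#' @param seg a [segment_strokes()] result.
#' @param max_lifts inclusive upper bound on acceptable pen lifts.
#' @return `TRUE` if the trial should be excluded.
#' @export
qc_exclude <- function(seg, max_lifts = 20L) {
  seg$n_lifts > max_lifts
}
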