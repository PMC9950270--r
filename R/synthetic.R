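#' Synthetic smart-pen recording presets
#'
#' Presets bundle the generator parameters that emulate the signal structure
#' behind the PD-versus-control contrasts: a low-frequency drawing
#' oscillation (with a weak in-band harmonic), an additive tremor component
#' with controllable center frequency, amplitude and cycle-to-cycle frequency
#' jitter, an 8-12 Hz ripple degrading smoothness, a force profile with
#' controllable mean/variability/oscillation rate, pen lifts, and broadband
#' noise.
#'
#' The `"pd"` preset injects a strong, frequency-stable 4-7 Hz tremor, more
#' ripple, a lower and more variable force oscillating at a higher rate, and
#' fewer pen lifts; `"control"` injects a near-absent, frequency-unstable
#' tremor and a steadier force. The `"null"` preset equals `"control"` and is
#' used for type-I-error calibration (both groups drawn from it are
#' exchangeable).
#'
#' @param name `"pd"`, `"control"` or `"null"`.
#' @return a list of generator parameters (class `spiral_preset`).
#' @export
synthetic_preset <- function(name = c("pd", "control", "null")) {
  name <- match.arg(name)
  base <- list(
    fs = 50, duration = 30, drawing_freq = 0.8,
    drawing_amp_acc = 0.4, drawing_amp_gyro = 6,
    harmonic_frac = 0.25,            # in-band (3 x drawing_freq) harmonic
    gyro_offset = 20,                # mean rotation rate while spiraling, deg/s
    tremor_gyro_gain = 12,           # deg/s of gyro tremor per m/s^2 of acc tremor
    tremor_freq_range = c(4, 7),
    noise_sd = 0.03, gyro_noise_sd = 0.3,
    force_noise_sd = 0.05, lift_dur_range = c(0.3, 0.6),
    lift_jitter = TRUE)   # Poisson-vary the lift count per trial
  spec <- switch(name,
    pd = list(
      tremor_amp_meanlog = log(0.5), tremor_amp_sdlog = 0.35,
      freq_jitter_sd = 0.4, ripple_amp = 0.06, ripple_amp_gyro = 0.6,
      force_mean = 8, force_cv = 0.25, force_osc_rate = 3.74, n_lifts = 0.8),
    control = , null = list(
      tremor_amp_meanlog = log(0.03), tremor_amp_sdlog = 0.35,
      freq_jitter_sd = 1.5, ripple_amp = 0.04, ripple_amp_gyro = 0.3,
      force_mean = 12, force_cv = 0.15, force_osc_rate = 3.09, n_lifts = 2.2))
  structure(c(base, spec, list(name = name)), class = "spiral_preset")
}

#' Draw one subject's latent generator parameters from a preset
#'
#' Per-subject heterogeneity: tremor center frequency uniform over the
#' preset's range, tremor amplitude lognormal around the preset level, and
#' mild lognormal/normal scatter on force level, drawing amplitude, ripple
#' and force oscillation rate, so group distributions overlap realistically
#' instead of being point masses. The tremor amplitude doubles as the
#' subject's latent motor severity, from which the synthetic clinical scores
#' are derived.
#'
#' @param preset a [synthetic_preset()].
#' @return list of subject-level parameters.
#' @export
draw_subject_params <- function(preset) {
  sp <- preset
  sp$tremor_freq <- stats::runif(1, preset$tremor_freq_range[1],
                                 preset$tremor_freq_range[2])
  sp$tremor_amp <- stats::rlnorm(1, preset$tremor_amp_meanlog,
                                 preset$tremor_amp_sdlog)
  sp$force_mean <- preset$force_mean * stats::rlnorm(1, 0, 0.15)
  sp$drawing_amp_acc <- preset$drawing_amp_acc * stats::rlnorm(1, 0, 0.15)
  sp$drawing_amp_gyro <- preset$drawing_amp_gyro * stats::rlnorm(1, 0, 0.15)
  sp$ripple_amp <- preset$ripple_amp * stats::rlnorm(1, 0, 0.2)
  sp$ripple_amp_gyro <- preset$ripple_amp_gyro * stats::rlnorm(1, 0, 0.2)
  sp$force_cv <- preset$force_cv * stats::rlnorm(1, 0, 0.2)
  sp$freq_jitter_sd <- preset$freq_jitter_sd * stats::rlnorm(1, 0, 0.3)
  sp$force_osc_rate <- max(1, preset$force_osc_rate + stats::rnorm(1, 0, 0.5))
  sp
}

# phase-continuous oscillation whose per-cycle frequency is drawn
# Normal(f0, jitter_sd), truncated to [1.5, 11] Hz; returns the series and the
# realized cycle frequencies
jitter_tone <- function(n, fs, f0, jitter_sd, amp) {
  dur <- n / fs
  n_cyc <- ceiling(dur * (f0 + 4 * jitter_sd + 1)) + 2L
  f_cyc <- pmin(pmax(stats::rnorm(n_cyc, f0, jitter_sd), 1.5), 11)
  t_edge <- c(0, cumsum(1 / f_cyc))
  tt <- (seq_len(n) - 1) / fs
  idx <- findInterval(tt, t_edge)
  f_inst <- f_cyc[pmin(idx, n_cyc)]
  phase <- 2 * pi * cumsum(f_inst) / fs
  list(series = amp * sin(phase), f_cyc = f_cyc[seq_len(max(idx))])
}

#' Generate one synthetic smart-pen trial
#'
#' Builds a [pen_recording()] from subject parameters (see
#' [draw_subject_params()]): acceleration = gravity offset + drawing
#' oscillation (plus a weak 3rd harmonic) + phase-continuous jittered tremor +
#' 10 Hz ripple + white noise, with the tremor and ripple directed along the
#' pen axis so they survive the norm reduction; angular velocity is built
#' analogously around a nonzero mean rotation rate; force is a slowly
#' modulated mean plus an oscillation at the configured extrema rate, clipped
#' at zero, with `n_lifts` interior zero-force gaps. Deterministic given the
#' RNG state.
#'
#' @param sp subject parameter list.
#' @param subject_id,group,hand,trial recording descriptors.
#' @return list with `rec` (a [pen_recording()]) and `truth` (injected tremor
#'   series, true tremor frequency, parameter record).
#' @export
generate_trial <- function(sp, subject_id = "S00", group = "control",
                           hand = "dominant", trial = 1L) {
  fs <- sp$fs
  n <- round(sp$duration * fs)
  stopifnot(n >= 500)
  tt <- (seq_len(n) - 1) / fs
  draw <- sp$drawing_amp_acc * sin(2 * pi * sp$drawing_freq * tt) +
    sp$harmonic_frac * sp$drawing_amp_acc * sin(2 * pi * 3 * sp$drawing_freq * tt)
  trem <- jitter_tone(n, fs, sp$tremor_freq, sp$freq_jitter_sd, sp$tremor_amp)
  ripple <- sp$ripple_amp * sin(2 * pi * 10 * tt)
  acc <- cbind(
    0.3 * sp$drawing_amp_acc * cos(2 * pi * sp$drawing_freq * tt) +
      stats::rnorm(n, 0, sp$noise_sd),
    0.5 * sin(2 * pi * 0.05 * tt) + stats::rnorm(n, 0, sp$noise_sd),
    9.81 + draw + trem$series + ripple + stats::rnorm(n, 0, sp$noise_sd))
  g_draw <- sp$drawing_amp_gyro * sin(2 * pi * sp$drawing_freq * tt) +
    sp$harmonic_frac * sp$drawing_amp_gyro * sin(2 * pi * 3 * sp$drawing_freq * tt)
  gyro <- cbind(
    sp$gyro_offset + g_draw + sp$tremor_gyro_gain * trem$series +
      sp$ripple_amp_gyro * sin(2 * pi * 10 * tt) +
      stats::rnorm(n, 0, sp$gyro_noise_sd),
    stats::rnorm(n, 0, sp$gyro_noise_sd),
    stats::rnorm(n, 0, sp$gyro_noise_sd))
  force <- sp$force_mean *
    (1 + sp$force_cv * sqrt(2) * sin(2 * pi * 0.1 * tt + stats::runif(1, 0, 2 * pi))) +
    0.1 * sp$force_mean * sin(2 * pi * (sp$force_osc_rate / 2) * tt) +
    stats::rnorm(n, 0, sp$force_noise_sd)
  force <- pmax(force, 0)
  n_lifts <- if (isTRUE(sp$lift_jitter))
    min(stats::rpois(1, sp$n_lifts), 8L) else sp$n_lifts
  if (n_lifts > 0) {
    # interior gaps, placed in disjoint slots so strokes stay >= 100 ms
    slots <- seq(0.15, 0.85, length.out = n_lifts + 2L)[2:(n_lifts + 1L)]
    for (s in slots) {
      gdur <- stats::runif(1, sp$lift_dur_range[1], sp$lift_dur_range[2])
      i0 <- max(1L, round(s * n))
      i1 <- min(n, i0 + round(gdur * fs))
      force[i0:i1] <- 0
    }
  }
  rec <- pen_recording(tt, acc, gyro, force, fs = fs, subject_id = subject_id,
                       group = group, hand = hand, trial = trial)
  list(rec = rec,
       truth = list(tremor = trem$series, tremor_freq = sp$tremor_freq,
                    tremor_amp = sp$tremor_amp, f_cyc = trem$f_cyc,
                    params = sp))
}

#' Generate a synthetic PD / control cohort
#'
#' Draws `n_per_group` subjects per group (dominant hand, `trials` trials
#' each) from the PD and control presets and attaches synthetic clinical
#' scores for the PD group: each score is a monotone noisy transform of the
#' subject's injected tremor amplitude, calibrated so its Spearman
#' correlation with the latent severity is around 0.4-0.5 — only the rank
#' structure matters for the correlation stage. Fully reproducible given
#' `seed`.
#'
#' @param n_per_group subjects per group.
#' @param seed RNG seed (integer) or `NULL` to use the current RNG state.
#' @param pd,control the two [synthetic_preset()]s.
#' @param trials trials per subject.
#' @return list of class `spiral_cohort`: `recordings` (list of
#'   [pen_recording()]), `truth` (one entry per recording), `meta` (one row
#'   per subject: descriptors plus clinical scores, `NA` for controls).
#' @export
generate_cohort <- function(n_per_group = 29, seed = NULL,
                            pd = synthetic_preset("pd"),
                            control = synthetic_preset("control"),
                            trials = 2L) {
  if (!is.null(seed)) set.seed(seed)
  groups <- rep(c("PD", "control"), each = n_per_group)
  ids <- sprintf("%s%02d", ifelse(groups == "PD", "P", "C"),
                 c(seq_len(n_per_group), seq_len(n_per_group)))
  recordings <- list()
  truth <- list()
  meta <- NULL
  for (s in seq_along(ids)) {
    preset <- if (groups[s] == "PD") pd else control
    sp <- draw_subject_params(preset)
    for (tr in seq_len(trials)) {
      gt <- generate_trial(sp, subject_id = ids[s], group = groups[s],
                           hand = "dominant", trial = tr)
      recordings[[length(recordings) + 1L]] <- gt$rec
      truth[[length(truth) + 1L]] <- gt$truth
    }
    meta <- rbind(meta, data.frame(
      subject_id = ids[s], group = groups[s], hand = "dominant",
      age = round(stats::rnorm(1, 72.5, 7.8)),
      sex = sample(c("M", "F"), 1),
      mmse = pmin(30, pmax(24, round(stats::rnorm(1, 28, 1.6)))),
      severity = sp$tremor_amp))
  }
  meta <- cbind(meta, synth_clinical_scores(meta$severity, meta$group == "PD"))
  structure(list(recordings = recordings, truth = truth, meta = meta),
            class = "spiral_cohort")
}

# monotone noisy transforms of latent severity; NA for controls.
# standardized within the PD group: the rank signal must live in the
# within-patient spread, not in the group contrast
synth_clinical_scores <- function(severity, is_pd) {
  ls <- log(severity)
  z <- (ls - mean(ls[is_pd])) / stats::sd(ls[is_pd])
  n <- length(z)
  noisy <- function(center, gain, noise_sd, lo, hi, integer = TRUE) {
    v <- center + gain * z + stats::rnorm(n, 0, noise_sd)
    v <- pmin(hi, pmax(lo, v))
    v <- if (integer) round(v) else round(v, 2)
    ifelse(is_pd, v, NA)
  }
  data.frame(
    updrs3 = noisy(19, 6, 12, 5, 45),
    hy = noisy(2, 0.5, 1, 1, 4),
    jankovic = noisy(1.5, 0.4, 0.8, 0, 3, integer = FALSE),
    schiess = noisy(1.5, 0.4, 0.8, 0, 3, integer = FALSE),
    kang = noisy(1.5, 0.4, 0.8, 0, 3, integer = FALSE),
    updrs2_tremor = noisy(2, 0.8, 1.6, 0, 4),
    updrs3_rest_tremor = noisy(2, 0.8, 1.6, 0, 4),
    updrs3_hands = noisy(8, 2.5, 5, 0, 20))
}

#' Write a synthetic cohort to disk in the recording CSV dialect
#'
#' One CSV per trial (`<subject>_trial<k>.csv`) plus `meta.csv`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings)
    write_recording(rec, file.path(
      dir, sprintf("%s_trial%d.csv", rec$subject_id, rec$trial)))
  utils::write.csv(cohort$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' Extract indicators for every recording of a cohort
#'
#' @param cohort a [generate_cohort()] result (or any list of
#'   [pen_recording()]s in `cohort$recordings`).
#' @param subset indicator subset passed to [compute_indicators()].
#' @param qc drop trials failing the pen-lift rule ([qc_exclude()])?
#' @return data.frame: `subject_id`, `group`, `hand`, `trial`, `excluded`,
#'   then one column per indicator.
#' @export
extract_cohort <- function(cohort, subset = indicator_names(), qc = TRUE) {
  rows <- lapply(cohort$recordings, function(rec) {
    seg <- segment_strokes(rec)
    excl <- qc_exclude(seg)
    ind <- if (excl && qc) stats::setNames(rep(NA_real_, length(subset)), subset)
           else compute_indicators(rec, subset = subset)
    cbind(data.frame(subject_id = rec$subject_id, group = rec$group,
                     hand = rec$hand, trial = rec$trial, excluded = excl),
          as.data.frame(as.list(ind), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  if (qc) out <- out[!out$excluded, , drop = FALSE]
  out
}
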