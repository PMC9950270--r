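#' Names and domains of the spiral-drawing indicator set
#'
#' The full indicator set spans seven domains: Kinematics, Force, Smoothness,
#' Tilt, Frequency, Amplitude and Regularity. Names follow the field's
#' conventions: `_A` acceleration, `_G` angular velocity, `_G_filt` angular
#' velocity filtered around its spectral peak, `_T` the EMD tremor component.
#'
#' @return `indicator_names()`: character vector of indicator column names;
#'   `indicator_domains()`: named character vector mapping each indicator to
#'   its domain.
#' @export
indicator_names <- function() names(indicator_domains())

#' @rdname indicator_names
#' @export
indicator_domains <- function() {
  c(Execution_Time = "Kinematics", Strokes_Num = "Kinematics",
    ConsPeakDiff_G_Avg = "Kinematics", ConsPeakDiff_G_CV = "Kinematics",
    F_Avg = "Force", F_CV = "Force", F_OVS = "Force",
    ConsPeakDiff_F_Avg = "Force", ConsPeakDiff_F_CV = "Force", NC_F = "Force",
    NC_A = "Smoothness", NC_G = "Smoothness",
    SPARC_G_10 = "Smoothness", SPARC_G_20 = "Smoothness",
    SPARC_G_30 = "Smoothness", SPARC_G_40 = "Smoothness",
    SPARC_G_45 = "Smoothness", SPARC_G_50 = "Smoothness",
    LDLJ_A = "Smoothness", LDLJ_G = "Smoothness",
    Tilt_Avg = "Tilt", Tilt_Var = "Tilt", Tilt_CV = "Tilt",
    `RPW_A_0-2` = "Frequency", `RPW_A_2-4` = "Frequency",
    `RPW_A_4-7` = "Frequency", `RPW_A_8-12` = "Frequency",
    `RPW_G_0-2` = "Frequency", `RPW_G_2-4` = "Frequency",
    `RPW_G_4-7` = "Frequency", `RPW_G_8-12` = "Frequency",
    RPW_G_filt_max = "Frequency", MHP_T = "Frequency",
    RMS_A = "Amplitude", RMS_G = "Amplitude", RMS_G_filt_max = "Amplitude",
    SNR_T = "Amplitude", Out_Lev_Rel_A = "Amplitude",
    Out_Lev_Rel_G = "Amplitude", AmpXOut_Lev_A = "Amplitude",
    AmpXOut_Lev_G = "Amplitude",
    ApEn_T = "Regularity", RR_T = "Regularity", DET_T = "Regularity",
    TSI_T = "Regularity", G_Rate_max = "Regularity")
}

#' Compute the spiral-drawing indicator set for one trial
#'
#' Runs the full extraction: preprocessing ([preprocess()]), stroke
#' segmentation ([segment_strokes()]), EMD tremor extraction
#' ([extract_tremor()]), Welch spectra ([welch_psd()]) and every indicator of
#' the seven domains. Time-domain indicators are computed on the concatenated
#' on-paper samples only (force is undefined mid-air); spectral and tremor
#' indicators use the contiguous span from the first to the last on-paper
#' sample, so the spectra are not corrupted by splice discontinuities.
#'
#' @param rec a [pen_recording()].
#' @param subset optional character vector of indicator names to compute
#'   (default: all). Expensive stages (EMD, recurrence) are skipped when no
#'   requested indicator needs them.
#' @param prominence_frac extrema prominence guard (see [find_extrema()]).
#' @param peak_halfwidth_hz half-width of every "interval around the peak", Hz.
#' @param band kinematic band-pass edges, Hz.
#' @return named numeric vector over `subset` (default [indicator_names()]);
#'   `NA` where an indicator is undefined for the trial.
#' @export
compute_indicators <- function(rec, subset = indicator_names(),
                               prominence_frac = 0.02, peak_halfwidth_hz = 1,
                               band = c(2, 12)) {
  want <- match.arg(subset, indicator_names(), several.ok = TRUE)
  out <- stats::setNames(rep(NA_real_, length(want)), want)
  need <- function(...) any(c(...) %in% want)
  fs <- rec$fs
  sig <- preprocess(rec, band = band)
  seg <- segment_strokes(rec)
  if (seg$n_strokes < 1) return(out)
  mask <- seg$on_paper_mask
  on <- which(mask)
  span <- on[1]:on[length(on)]
  set <- function(name, value) {
    if (name %in% want) out[[name]] <<- as.numeric(value)
  }

  ## -- Kinematics / Force / Smoothness / Tilt (on-paper samples) ------------
  set("Execution_Time", execution_time(seg, fs))
  set("Strokes_Num", seg$n_strokes)
  if (need("ConsPeakDiff_G_Avg", "ConsPeakDiff_G_CV")) {
    cpd <- cons_peak_diff(sig$gyro_mag_bp[mask], prominence_frac)
    set("ConsPeakDiff_G_Avg", cpd[["avg"]]); set("ConsPeakDiff_G_CV", cpd[["cv"]])
  }
  if (need("F_Avg", "F_CV", "F_OVS") && sum(mask) >= 10) {
    fstat <- force_stats(sig$force[mask])
    set("F_Avg", fstat[["F_Avg"]]); set("F_CV", fstat[["F_CV"]])
    set("F_OVS", fstat[["F_OVS"]])
  }
  if (need("ConsPeakDiff_F_Avg", "ConsPeakDiff_F_CV")) {
    cpf <- cons_peak_diff(sig$force[mask], prominence_frac)
    set("ConsPeakDiff_F_Avg", cpf[["avg"]]); set("ConsPeakDiff_F_CV", cpf[["cv"]])
  }
  if (need("NC_F")) set("NC_F", rate_of_changes(sig$force[mask], fs, prominence_frac))
  if (need("NC_A")) set("NC_A", rate_of_changes(sig$acc_mag_bp[mask], fs, prominence_frac))
  if (need("NC_G")) set("NC_G", rate_of_changes(sig$gyro_mag_bp[mask], fs, prominence_frac))
  sparc_names <- paste0("SPARC_G_", c(10, 20, 30, 40, 45, 50))
  if (need(sparc_names) && sum(mask) >= 2 * fs) {
    for (th in c(10, 20, 30, 40, 45, 50))
      set(paste0("SPARC_G_", th), sparc(sig$gyro_mag_bp[mask], fs, th))
  }
  if (need("LDLJ_A") && sum(mask) >= fs) set("LDLJ_A", ldlj(sig$acc_mag_bp[mask], fs))
  if (need("LDLJ_G") && sum(mask) >= fs) set("LDLJ_G", ldlj(sig$gyro_mag_bp[mask], fs))
  if (need("Tilt_Avg", "Tilt_Var", "Tilt_CV") && sum(mask) >= 10) {
    ts <- tilt_stats(sig$tilt[mask])
    set("Tilt_Avg", ts[["Tilt_Avg"]]); set("Tilt_Var", ts[["Tilt_Var"]])
    set("Tilt_CV", ts[["Tilt_CV"]])
  }

  ## -- Frequency / Amplitude (contiguous drawing span, raw norms) -----------
  spec_needed_a <- need("RPW_A_0-2", "RPW_A_2-4", "RPW_A_4-7", "RPW_A_8-12",
                        "Out_Lev_Rel_A", "AmpXOut_Lev_A")
  spec_needed_g <- need("RPW_G_0-2", "RPW_G_2-4", "RPW_G_4-7", "RPW_G_8-12",
                        "RPW_G_filt_max", "Out_Lev_Rel_G", "AmpXOut_Lev_G",
                        "RMS_G_filt_max")
  bands <- list(`0-2` = c(0, 2), `2-4` = c(2, 4), `4-7` = c(4, 7),
                `8-12` = c(8, 12))
  if (spec_needed_a && length(span) >= 250) {
    spec_a <- welch_psd(sig$acc_mag_raw[span], fs)
    for (b in names(bands))
      set(paste0("RPW_A_", b), relative_band_power(spec_a, bands[[b]]))
    ol <- outlier_level(spec_a)
    set("Out_Lev_Rel_A", ol[["Out_Lev_Rel"]])
    set("AmpXOut_Lev_A", ol[["AmpXOut_Lev"]])
  }
  if (spec_needed_g && length(span) >= 250) {
    spec_g <- welch_psd(sig$gyro_mag_raw[span], fs)
    for (b in names(bands))
      set(paste0("RPW_G_", b), relative_band_power(spec_g, bands[[b]]))
    set("RPW_G_filt_max", rpw_peak_band(spec_g, halfwidth = peak_halfwidth_hz))
    ol <- outlier_level(spec_g)
    set("Out_Lev_Rel_G", ol[["Out_Lev_Rel"]])
    set("AmpXOut_Lev_G", ol[["AmpXOut_Lev"]])
    if (need("RMS_G_filt_max")) {
      fp <- spectral_peak(spec_g, c(2, 12))
      if (!is.na(fp)) {
        gf <- butter_filtfilt(sig$gyro_mag_raw[span], fs,
                              max(0.5, fp - peak_halfwidth_hz),
                              min(fs / 2 - 0.5, fp + peak_halfwidth_hz))
        set("RMS_G_filt_max", windowed_rms(gf, fs, win_s = 1, reduce = "max"))
      }
    }
  }
  if (need("RMS_A")) set("RMS_A", windowed_rms(sig$acc_mag_raw[span], fs, 10, "mean"))
  if (need("RMS_G")) set("RMS_G", windowed_rms(sig$gyro_mag_raw[span], fs, 10, "mean"))

  ## -- Tremor (_T) and remaining Regularity indicators ----------------------
  t_names <- c("MHP_T", "SNR_T", "ApEn_T", "RR_T", "DET_T", "TSI_T")
  if (need(t_names) && length(span) >= 4 * fs) {
    trem <- extract_tremor(sig$acc_mag_raw[span], fs, band = band)
    if (!is.na(trem$peak_freq)) {
      set("MHP_T", mean_harmonic_power(trem, peak_halfwidth_hz))
      set("SNR_T", snr_tremor(trem, peak_halfwidth_hz))
      if (need("ApEn_T")) set("ApEn_T", approximate_entropy(trem$tremor))
      if (need("RR_T", "DET_T") && length(trem$tremor) >= 200) {
        rq <- recurrence_measures(trem$tremor)
        set("RR_T", rq[["RR"]]); set("DET_T", rq[["DET"]])
      }
      if (need("TSI_T"))
        set("TSI_T", tremor_stability_index(trem$tremor, fs, band = band))
    }
  }
  if (need("G_Rate_max")) set("G_Rate_max", gyro_change_rate(sig$gyro_mag_bp[span], fs))
  out
}
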