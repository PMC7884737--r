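#' Run the full hemodynamic analysis on one recording
#'
#' Chains R-peak detection, eight-beat ensemble averaging, beat summary,
#' Fourier input impedance (Z0, Zc), forward/backward wave separation
#' (RM, RI), and wave intensity (W1, W2, NW); when a diameter measurement
#' is supplied, stiffness parameter beta, percent diameter change and
#' Bramwell-Hill PWV are added.  Any stage failure is re-raised with the
#' stage name prefixed.
#'
#' @param record a [waveform_record].
#' @param diameters optional [diameter_measurement] for the same subject
#'   and condition.
#' @param n_beats_ensemble beats to average (default 8).
#' @param zc_band_hz two-element band for Zc, Hz (default `c(1, 10)`).
#' @param probe_area_cm2 aortic cross-section for flow/velocity
#'   interconversion when only one channel exists.
#' @param wi_smooth_width moving-average width for the WI derivatives
#'   (0 = off).
#' @param wi_window_fracs two fractions of ejection bounding the W1 and
#'   W2 searches (default `c(0.4, 0.6)`).
#' @param rho_kg_m3 blood density for PWV.
#' @return a named list of scalar metrics (unit-suffixed names) plus the
#'   intermediate objects in attribute `"stages"`.
#' @export
analyze_record <- function(record, diameters = NULL,
                           n_beats_ensemble = 8,
                           zc_band_hz = c(1, 10),
                           probe_area_cm2 = NULL,
                           wi_smooth_width = 0,
                           wi_window_fracs = c(0.4, 0.6),
                           rho_kg_m3 = 1060) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  seg <- stage("detect_r_peaks",
               detect_r_peaks(record$channels$ecg, record$fs_hz))
  beat <- stage("ensemble_average",
                ensemble_average(record, seg, n_beats = n_beats_ensemble,
                                 probe_area_cm2 = probe_area_cm2))
  summ <- stage("summarize_beat", summarize_beat(beat, seg))
  spec <- stage("input_impedance",
                input_impedance(beat, f_lo = zc_band_hz[1],
                                f_hi = zc_band_hz[2]))
  sep <- stage("separate_waves", separate_waves(beat, spec$zc_dyn_s_cm5))
  wi <- stage("wave_intensity",
              wave_intensity(beat, smooth_width = wi_smooth_width,
                             probe_area_cm2 = probe_area_cm2,
                             w1_frac = wi_window_fracs[1],
                             w2_frac = wi_window_fracs[2]))
  out <- list(
    subject_id = record$subject_id,
    condition = record$condition,
    hr_bpm = summ$hr_bpm,
    sbp_mmhg = summ$sbp_mmhg, dbp_mmhg = summ$dbp_mmhg,
    map_mmhg = summ$map_mmhg, pp_mmhg = summ$pp_mmhg,
    co_l_min = summ$co_l_min,
    lv_dpdt_max_mmhg_s = summ$lv_dpdt_max_mmhg_s,
    lv_dpdt_min_mmhg_s = summ$lv_dpdt_min_mmhg_s,
    dqdt_max_ml_s2 = summ$dqdt_max_ml_s2,
    dqdt_min_ml_s2 = summ$dqdt_min_ml_s2,
    z0_dyn_s_cm5 = spec$z0_dyn_s_cm5,
    zc_dyn_s_cm5 = spec$zc_dyn_s_cm5,
    pf_amp_mmhg = sep$pf_amp_mmhg, pb_amp_mmhg = sep$pb_amp_mmhg,
    rm = sep$rm, ri = sep$ri,
    w1_mmhg_m_s3 = wi$w1, w2_mmhg_m_s3 = wi$w2, nw_mmhg_m_s3 = wi$nw)
  if (!is.null(diameters)) {
    out$dmax_mm <- diameters$dmax_mm
    out$dmin_mm <- diameters$dmin_mm
    out$diameter_change_pct <- stage("diameter_change",
                                     diameter_change(diameters))
    out$beta <- stage("stiffness_beta",
                      stiffness_beta(summ$sbp_mmhg, summ$dbp_mmhg,
                                     diameters))
    out$pwv_m_s <- stage("bramwell_hill_pwv",
                         bramwell_hill_pwv(diameters,
                                           pp_mmhg = summ$pp_mmhg,
                                           rho_kg_m3 = rho_kg_m3))
  }
  attr(out, "stages") <- list(segmentation = seg, beat = beat,
                              summary = summ, impedance = spec,
                              separation = sep, wave_intensity = wi)
  out
}

#' Simulate a recording to files
#'
#' Reads a flat key-value or JSON configuration (fields of
#' [synthetic_config]), generates the recording, and writes the waveform
#' container plus a ground-truth sidecar `<out_path>.truth.json`.
#'
#' @param config_path configuration file, or a named list / a
#'   [synthetic_config] given directly.
#' @param out_path output waveform file.
#' @return invisibly, the list from [generate_recording].
#' @export
cmd_simulate <- function(config_path, out_path) {
  cfg <- if (is.character(config_path)) read_flat_config(config_path)
         else config_path
  if (!inherits(cfg, "synthetic_config")) {
    known <- names(formals(synthetic_config))
    unknown <- setdiff(names(cfg), known)
    if (length(unknown)) {
      stop("unknown synthetic configuration field(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cfg <- do.call(synthetic_config, cfg)
  }
  sim <- generate_recording(cfg)
  write_recording(sim$record, out_path)
  truth <- sim$truth
  truth_flat <- list(
    zc_true = truth$zc_true, gamma = truth$gamma,
    round_trip_delay_s = truth$round_trip_delay_s,
    diastolic_pressure_mmhg = truth$diastolic_pressure_mmhg,
    probe_area_cm2 = truth$probe_area_cm2,
    seed = truth$seed,
    r_onset_idx = truth$r_onset_idx, rr_s = truth$rr_s,
    ejection_s = truth$ejection_s,
    pf_trace = truth$pf_trace, pb_trace = truth$pb_trace)
  jsonlite::write_json(truth_flat, paste0(out_path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

#' Analyze a recording file to a metrics file
#'
#' @param recording_path waveform container file.
#' @param out_path output path; metrics are written as JSON, and as a
#'   one-row CSV alongside (`<out_path>.csv`).
#' @param diameters_path optional diameter CSV ([read_diameters]); the
#'   row matching the recording's subject and condition is used.  When
#'   absent, the beta/PWV columns are omitted and a note is logged.
#' @param config_path optional flat config overriding analysis defaults
#'   (`n_beats_ensemble`, `zc_band_lo_hz`, `zc_band_hi_hz`,
#'   `probe_area_cm2`, `wi_smooth_width`, `w1_frac`, `w2_frac`,
#'   `rho_kg_m3`).
#' @return invisibly, the metrics list.
#' @export
cmd_analyze <- function(recording_path, out_path, diameters_path = NULL,
                        config_path = NULL) {
  cfg <- if (!is.null(config_path)) read_flat_config(config_path) else list()
  record <- read_recording(recording_path)
  d <- NULL
  if (!is.null(diameters_path)) {
    dd <- read_diameters(diameters_path)
    hit <- vapply(dd, function(x) {
      x$subject_id == record$subject_id && x$condition == record$condition
    }, logical(1))
    if (!any(hit)) {
      stop("no diameter row for subject '", record$subject_id,
           "', condition '", record$condition, "'", call. = FALSE)
    }
    d <- dd[[which(hit)[1]]]
  } else {
    message("cmd_analyze: no diameter table; beta/PWV columns omitted")
  }
  defaults <- list(n_beats_ensemble = 8, zc_band_lo_hz = 1,
                   zc_band_hi_hz = 10, probe_area_cm2 = NULL,
                   wi_smooth_width = 0, w1_frac = 0.4, w2_frac = 0.6,
                   rho_kg_m3 = 1060)
  for (k in names(defaults)) {
    if (!is.null(cfg[[k]])) defaults[[k]] <- cfg[[k]]
    message("cmd_analyze: ", k, " = ",
            if (is.null(defaults[[k]])) "NULL" else defaults[[k]],
            if (is.null(cfg[[k]])) " (default)" else " (override)")
  }
  m <- analyze_record(record, diameters = d,
                      n_beats_ensemble = defaults$n_beats_ensemble,
                      zc_band_hz = c(defaults$zc_band_lo_hz,
                                     defaults$zc_band_hi_hz),
                      probe_area_cm2 = defaults$probe_area_cm2,
                      wi_smooth_width = defaults$wi_smooth_width,
                      wi_window_fracs = c(defaults$w1_frac,
                                          defaults$w2_frac),
                      rho_kg_m3 = defaults$rho_kg_m3)
  flat <- m
  attr(flat, "stages") <- NULL
  jsonlite::write_json(flat, out_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(flat[!vapply(flat, is.null, logical(1))]),
                   paste0(out_path, ".csv"), row.names = FALSE)
  invisible(m)
}

#' Compare two per-subject metrics tables
#'
#' Reads two CSVs of per-subject metrics (columns `subject_id` plus
#' numeric metrics; one file per condition), runs [build_report], and
#' writes the paired table (and correlation table, if requested) as CSV.
#'
#' @param metrics_pre_path,metrics_post_path CSV files.
#' @param out_path basename for outputs: `<out_path>_paired.csv` and
#'   `<out_path>_correlations.csv`.
#' @param correlations,correlate_with forwarded to [build_report].
#' @return invisibly, the report list.
#' @export
cmd_compare <- function(metrics_pre_path, metrics_post_path, out_path,
                        correlations = NULL, correlate_with = NULL) {
  pre <- utils::read.csv(metrics_pre_path, stringsAsFactors = FALSE)
  post <- utils::read.csv(metrics_post_path, stringsAsFactors = FALSE)
  pre$condition <- "pre"
  post$condition <- "post"
  rep <- build_report(rbind(pre, post), pre_label = "pre",
                      post_label = "post", correlations = correlations,
                      correlate_with = correlate_with)
  utils::write.csv(rep$paired, paste0(out_path, "_paired.csv"),
                   row.names = FALSE)
  if (!is.null(rep$correlations)) {
    utils::write.csv(rep$correlations,
                     paste0(out_path, "_correlations.csv"),
                     row.names = FALSE)
  }
  invisible(rep)
}
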