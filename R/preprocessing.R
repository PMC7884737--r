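#' Detect R peaks in an ECG channel
#'
#' A band-limited derivative-energy detector: the ECG is smoothed with a
#' 10 ms moving average, its squared derivative is integrated over a
#' 20 ms window, and candidate beats are taken where this energy exceeds
#' an adaptive threshold (a fraction of its global maximum), with a
#' 200 ms refractory period.  Each candidate is then refined to the local
#' ECG maximum.  This is adequate for clean laboratory signals; it is not
#' a clinical QRS detector.
#'
#' @param ecg numeric ECG vector (arbitrary units).
#' @param fs_hz sampling rate, Hz.
#' @param threshold_frac adaptive threshold as a fraction of the peak
#'   derivative energy.
#' @param refractory_s minimum separation between accepted peaks, s.
#' @return an object of class `beat_segmentation` with elements
#'   `r_peak_indices` (1-based sample indices, strictly increasing) and
#'   `rr_s` (per-beat periods, seconds).
#' @export
detect_r_peaks <- function(ecg, fs_hz, threshold_frac = 0.25,
                           refractory_s = 0.2) {
  if (length(ecg) < 3L || !any(is.finite(ecg))) {
    stop("beat segmentation failed: ECG is empty or non-finite",
         call. = FALSE)
  }
  if (max(ecg) - min(ecg) <= 0) {
    stop("beat segmentation failed: flat-line ECG (no QRS energy)",
         call. = FALSE)
  }
  ma <- function(x, w) {
    w <- max(1L, as.integer(w))
    as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  }
  s <- ma(ecg, round(0.010 * fs_hz))
  d <- c(0, diff(s))
  e <- ma(d^2, round(0.020 * fs_hz))
  e[!is.finite(e)] <- 0
  thr <- threshold_frac * max(e)
  above <- e > thr
  if (!any(above)) {
    stop("beat segmentation failed: no samples above the energy threshold",
         call. = FALSE)
  }

  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand_start <- starts[runs$values]
  cand_end <- ends[runs$values]

  refr <- round(refractory_s * fs_hz)
  half_win <- round(0.015 * fs_hz)
  peaks <- integer(0)
  for (i in seq_along(cand_start)) {
    seg <- cand_start[i]:cand_end[i]
    c0 <- seg[which.max(e[seg])]
    win <- max(1L, c0 - half_win):min(length(ecg), c0 + half_win)
    pk <- win[which.max(ecg[win])]
    if (length(peaks) == 0L || pk - peaks[length(peaks)] >= refr) {
      peaks <- c(peaks, pk)
    }
  }
  if (length(peaks) < 2L) {
    stop("beat segmentation failed: fewer than 2 R peaks found (",
         length(peaks), ")", call. = FALSE)
  }
  structure(list(r_peak_indices = peaks, rr_s = diff(peaks) / fs_hz),
            class = "beat_segmentation")
}

#' @export
print.beat_segmentation <- function(x, ...) {
  cat("beat_segmentation:", length(x$r_peak_indices), "R peaks, mean RR",
      sprintf("%.3f s (HR %.1f bpm)\n", mean(x$rr_s), 60 / mean(x$rr_s)))
  invisible(x)
}

#' Ensemble-average beats aligned at the R wave
#'
#' Beats are cut from one R peak to the next, harmonised in length by
#' linear resampling to the median RR interval, and averaged pointwise,
#' which suppresses uncorrelated beat-to-beat noise by ~1/sqrt(n_beats).
#' Ejection landmarks are located on the averaged beat with
#' [locate_ejection].
#'
#' @param record a [waveform_record].
#' @param segmentation a `beat_segmentation` from [detect_r_peaks].
#' @param n_beats number of beats to average (default 8).
#' @param probe_area_cm2 optional aortic cross-section (cm2) used to
#'   derive velocity from flow (or flow from velocity) when only one of
#'   the two channels is present.
#' @return an object of class `ensemble_beat` with elements `fs_hz`,
#'   `p_mmhg`, `q_ml_s`, `u_m_s`, `lvp_mmhg` (NULL if absent),
#'   `n_beats_averaged`, `rr_s` (periods of the averaged beats),
#'   `ejection_onset_s` and `ejection_end_s`.
#' @export
ensemble_average <- function(record, segmentation, n_beats = 8,
                             probe_area_cm2 = NULL) {
  validate_record(record, require_channels = character(0))
  idx <- segmentation$r_peak_indices
  avail <- length(idx) - 1L
  if (avail < n_beats) {
    stop("insufficient data: ", avail, " full beat(s) available, ",
         n_beats, " requested", call. = FALSE)
  }
  idx <- idx[seq_len(n_beats + 1L)]
  len <- as.integer(round(stats::median(diff(idx))))

  avg_channel <- function(x) {
    acc <- numeric(len)
    for (b in seq_len(n_beats)) {
      seg <- x[idx[b]:(idx[b + 1L] - 1L)]
      acc <- acc + stats::approx(seq(0, 1, length.out = length(seg)), seg,
                                 xout = seq(0, 1, length.out = len))$y
    }
    acc / n_beats
  }

  p <- avg_channel(record$channels$aop)
  q <- if (!is.null(record$channels$flow)) avg_channel(record$channels$flow)
  u <- if (!is.null(record$channels$velocity)) {
    avg_channel(record$channels$velocity)
  }
  lvp <- if (!is.null(record$channels$lvp)) avg_channel(record$channels$lvp)
  if (is.null(q) && !is.null(u) && !is.null(probe_area_cm2)) {
    q <- convert_units(u, "m/s", "cm/s") * probe_area_cm2
  }
  if (is.null(u) && !is.null(q) && !is.null(probe_area_cm2)) {
    u <- convert_units(q / probe_area_cm2, "cm/s", "m/s")
  }

  beat <- structure(
    list(fs_hz = record$fs_hz, p_mmhg = p, q_ml_s = q, u_m_s = u,
         lvp_mmhg = lvp, n_beats_averaged = as.integer(n_beats),
         rr_s = diff(idx) / record$fs_hz,
         ejection_onset_s = NA_real_, ejection_end_s = NA_real_),
    class = "ensemble_beat")
  lm <- tryCatch(locate_ejection(beat), error = function(e) NULL)
  if (!is.null(lm)) {
    beat$ejection_onset_s <- lm[["ejection_onset_s"]]
    beat$ejection_end_s <- lm[["ejection_end_s"]]
  }
  beat
}

#' @export
print.ensemble_beat <- function(x, ...) {
  cat(sprintf("ensemble_beat: %d samples @ %g Hz, average of %d beats\n",
              length(x$p_mmhg), x$fs_hz, x$n_beats_averaged))
  cat(sprintf("  pressure %.1f .. %.1f mmHg; ejection %.3f .. %.3f s\n",
              min(x$p_mmhg), max(x$p_mmhg),
              x$ejection_onset_s, x$ejection_end_s))
  invisible(x)
}

#' Locate the ejection window on an averaged beat
#'
#' Onset is the first time the flow (or velocity, if flow is absent)
#' rises above `onset_frac` of its beat maximum; end is the first
#' downward zero-crossing -- or fall below `end_frac` of the maximum --
#' after the flow peak.  The default thresholds (5% and 2%) are robust to
#' baseline noise and can be overridden.
#'
#' @param beat an `ensemble_beat`.
#' @param onset_frac,end_frac detection thresholds as fractions of the
#'   flow maximum.
#' @return named numeric vector `c(ejection_onset_s, ejection_end_s)`,
#'   seconds from the R peak.
#' @export
locate_ejection <- function(beat, onset_frac = 0.05, end_frac = 0.02) {
  x <- beat$q_ml_s %||% beat$u_m_s
  if (is.null(x)) {
    stop("ejection landmarks need a flow or velocity trace", call. = FALSE)
  }
  if (all(x <= 0)) {
    stop("ejection landmarks failed: flow is non-positive throughout",
         call. = FALSE)
  }
  qmax <- max(x)
  i_on <- which(x > onset_frac * qmax)[1]
  i_pk <- which.max(x)
  after <- seq(i_pk + 1L, length(x))
  i_end <- after[which(x[after] <= 0 | x[after] < end_frac * qmax)[1]]
  if (is.na(i_end)) {
    stop("ejection landmarks failed: flow never returns to baseline after ",
         "its peak", call. = FALSE)
  }
  c(ejection_onset_s = (i_on - 1L) / beat$fs_hz,
    ejection_end_s = (i_end - 1L) / beat$fs_hz)
}

#' Scalar hemodynamic summary of an averaged beat
#'
#' Computes systolic/diastolic/mean/pulse aortic pressure, heart rate
#' (from the mean RR of the averaged beats), cardiac output (time-mean
#' flow), and the extremes of LV dP/dt and aortic dQ/dt taken from
#' central differences with no smoothing.
#'
#' @param beat an `ensemble_beat`.
#' @param segmentation optional `beat_segmentation`; when supplied, heart
#'   rate uses its full RR series instead of the averaged beats'.
#' @return an object of class `beat_summary` with fields `hr_bpm`,
#'   `sbp_mmhg`, `dbp_mmhg`, `map_mmhg`, `pp_mmhg`, `co_l_min`,
#'   `lv_dpdt_max_mmhg_s`, `lv_dpdt_min_mmhg_s` (NA with attribute
#'   `lvp_missing` if no LV channel), `dqdt_max_ml_s2`, `dqdt_min_ml_s2`.
#' @export
summarize_beat <- function(beat, segmentation = NULL) {
  p <- beat$p_mmhg
  rr <- if (!is.null(segmentation)) segmentation$rr_s else beat$rr_s
  cdiff <- function(x, fs) {
    n <- length(x)
    if (n < 3L) return(0)
    (x[3:n] - x[1:(n - 2L)]) * fs / 2
  }
  dq <- if (!is.null(beat$q_ml_s)) cdiff(beat$q_ml_s, beat$fs_hz) else NA_real_
  out <- list(
    hr_bpm = 60 / mean(rr),
    sbp_mmhg = max(p),
    dbp_mmhg = min(p),
    map_mmhg = mean(p),
    pp_mmhg = max(p) - min(p),
    co_l_min = if (!is.null(beat$q_ml_s)) {
      convert_units(mean(beat$q_ml_s), "mL/s", "L/min")
    } else NA_real_,
    dqdt_max_ml_s2 = max(dq), dqdt_min_ml_s2 = min(dq))
  if (!is.null(beat$lvp_mmhg)) {
    dp <- cdiff(beat$lvp_mmhg, beat$fs_hz)
    out$lv_dpdt_max_mmhg_s <- max(dp)
    out$lv_dpdt_min_mmhg_s <- min(dp)
    out$lvp_missing <- FALSE
  } else {
    out$lv_dpdt_max_mmhg_s <- NA_real_
    out$lv_dpdt_min_mmhg_s <- NA_real_
    out$lvp_missing <- TRUE
  }
  structure(out, class = "beat_summary")
}

#' @export
print.beat_summary <- function(x, ...) {
  cat(sprintf(paste0("beat_summary: HR %.1f bpm, BP %.1f/%.1f ",
                     "(MAP %.1f, PP %.1f) mmHg, CO %.2f L/min\n"),
              x$hr_bpm, x$sbp_mmhg, x$dbp_mmhg, x$map_mmhg, x$pp_mmhg,
              x$co_l_min))
  if (isTRUE(x$lvp_missing)) {
    cat("  (no LV pressure channel: dP/dt not available)\n")
  } else {
    cat(sprintf("  LV dP/dt %+.0f / %+.0f mmHg/s\n",
                x$lv_dpdt_max_mmhg_s, x$lv_dpdt_min_mmhg_s))
  }
  invisible(x)
}
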