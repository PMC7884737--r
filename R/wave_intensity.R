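#' Wave intensity of an ensemble-averaged beat
#'
#' Wave intensity is the product of the rates of change of local pressure
#' and velocity, `WI = (dP/dt)(dU/dt)`, computed here from crude
#' sample-to-sample (forward) differences with no smoothing by default.
#' At 1000 Hz with pressure in mmHg and velocity in m/s this yields the
#' conventional units mmHg m/s^3.  Positive peaks mark net forward wave
#' energy (W1 in early systole from ventricular contraction, W2 near
#' end-ejection from active flow deceleration); the mid-systolic negative
#' excursion NW marks waves reflected back toward the heart.
#'
#' Setting `raw_increments = TRUE` returns the bare product of per-sample
#' increments `dP * dU` instead (values scale by `fs_hz^2`).
#'
#' @param beat an `ensemble_beat` with pressure and velocity (velocity is
#'   derived from flow when `probe_area_cm2` is given).
#' @param smooth_width optional moving-average width (samples, odd) for
#'   noisy inputs; 0 disables.  Applied to the derivative traces.
#' @param raw_increments report `dP * dU` rather than time-normalised
#'   derivatives.
#' @param probe_area_cm2 cross-section (cm2) for flow-to-velocity
#'   conversion when the beat lacks a velocity trace.
#' @param w1_frac,w2_frac,w2_post_s peak-search windows passed to
#'   [extract_wi_peaks].
#' @return an object of class `wave_intensity_result`: `wi_trace`,
#'   `dpdt_trace`, `dudt_trace`, `t_s` (length N-1, forward difference at
#'   sample i), `fs_hz`, and peak fields `w1`, `w1_time_s`, `w2`,
#'   `w2_time_s`, `nw`, `nw_time_s`.
#' @export
wave_intensity <- function(beat, smooth_width = 0, raw_increments = FALSE,
                           probe_area_cm2 = NULL,
                           w1_frac = 0.4, w2_frac = 0.6, w2_post_s = 0.05) {
  u <- beat$u_m_s
  if (is.null(u)) {
    if (is.null(beat$q_ml_s) || is.null(probe_area_cm2)) {
      stop("wave intensity needs a velocity trace (or flow plus ",
           "probe_area_cm2)", call. = FALSE)
    }
    u <- convert_units(beat$q_ml_s / probe_area_cm2, "cm/s", "m/s")
  }
  p <- beat$p_mmhg
  if (is.null(p)) stop("wave intensity needs a pressure trace", call. = FALSE)
  fs <- beat$fs_hz
  dp <- diff(p)
  du <- diff(u)
  if (!raw_increments) {
    dp <- dp * fs
    du <- du * fs
  }
  if (smooth_width > 1) {
    w <- as.integer(smooth_width)
    if (w %% 2L == 0L) w <- w + 1L
    sm <- function(x) {
      y <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
      y[is.na(y)] <- x[is.na(y)]
      y
    }
    dp <- sm(dp)
    du <- sm(du)
    message("wave_intensity: derivative traces smoothed (moving average, ",
            w, " samples)")
  }
  wi <- dp * du
  res <- structure(
    list(wi_trace = wi, dpdt_trace = dp, dudt_trace = du,
         t_s = (seq_along(wi) - 1L) / fs, fs_hz = fs,
         raw_increments = raw_increments,
         w1 = NA_real_, w1_time_s = NA_real_,
         w2 = NA_real_, w2_time_s = NA_real_,
         nw = NA_real_, nw_time_s = NA_real_),
    class = "wave_intensity_result")
  if (is.finite(beat$ejection_onset_s) && is.finite(beat$ejection_end_s)) {
    pk <- extract_wi_peaks(wi, fs, beat$ejection_onset_s,
                           beat$ejection_end_s,
                           w1_frac = w1_frac, w2_frac = w2_frac,
                           w2_post_s = w2_post_s)
    res[names(pk)] <- pk
  }
  res
}

#' Extract W1, W2 and the negative wave from a wave-intensity trace
#'
#' The ejection window from [locate_ejection] anchors phase-based search
#' windows: W1 is the maximum over the first `w1_frac` of ejection
#' (early systole), W2 the maximum from `w2_frac` of ejection to
#' `w2_post_s` beyond its end, and NW the minimum between the W1 and W2
#' peak times (mid systole).  Values are reported at the extrema.
#'
#' @param wi_trace numeric wave-intensity trace (one value per forward
#'   difference, i.e. length N-1 for an N-sample beat).
#' @param fs_hz sampling rate, Hz.
#' @param ejection_onset_s,ejection_end_s landmarks, seconds from beat
#'   start.
#' @param w1_frac fraction of ejection bounding the W1 search.
#' @param w2_frac fraction of ejection where the W2 search begins.
#' @param w2_post_s allowance beyond ejection end for W2, seconds.
#' @return named list `w1`, `w1_time_s`, `nw`, `nw_time_s`, `w2`,
#'   `w2_time_s`.
#' @export
extract_wi_peaks <- function(wi_trace, fs_hz, ejection_onset_s,
                             ejection_end_s,
                             w1_frac = 0.4, w2_frac = 0.6,
                             w2_post_s = 0.05) {
  n <- length(wi_trace)
  dur_s <- n / fs_hz
  if (!is.finite(ejection_onset_s) || !is.finite(ejection_end_s) ||
      ejection_onset_s < 0 || ejection_end_s <= ejection_onset_s ||
      ejection_onset_s >= dur_s) {
    stop("ejection landmarks outside the wave-intensity trace (onset ",
         format(ejection_onset_s), " s, end ", format(ejection_end_s),
         " s, trace ", format(dur_s), " s)", call. = FALSE)
  }
  idx <- function(t) min(n, max(1L, 1L + as.integer(round(t * fs_hz))))
  te <- ejection_end_s - ejection_onset_s
  i1 <- idx(ejection_onset_s):idx(ejection_onset_s + w1_frac * te)
  i2 <- idx(ejection_onset_s + w2_frac * te):idx(ejection_end_s + w2_post_s)
  w1_i <- i1[which.max(wi_trace[i1])]
  w2_i <- i2[which.max(wi_trace[i2])]
  nw_lo <- min(w1_i + 1L, n)
  nw_hi <- max(w2_i - 1L, nw_lo)
  inw <- nw_lo:nw_hi
  nw_i <- inw[which.min(wi_trace[inw])]
  list(w1 = wi_trace[w1_i], w1_time_s = (w1_i - 1L) / fs_hz,
       nw = wi_trace[nw_i], nw_time_s = (nw_i - 1L) / fs_hz,
       w2 = wi_trace[w2_i], w2_time_s = (w2_i - 1L) / fs_hz)
}

#' @export
print.wave_intensity_result <- function(x, ...) {
  un <- if (x$raw_increments) "mmHg m/s (raw increments)" else "mmHg m/s^3"
  cat("wave_intensity_result [", un, "]\n", sep = "")
  cat(sprintf("  W1 %10.1f @ %.3f s\n  NW %10.1f @ %.3f s\n  W2 %10.1f @ %.3f s\n",
              x$w1, x$w1_time_s, x$nw, x$nw_time_s, x$w2, x$w2_time_s))
  invisible(x)
}
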