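#' Configuration for the single-tube waveform simulator
#'
#' The simulator represents the proximal aorta as a lossless uniform tube
#' with characteristic impedance `zc_true` terminated by a single discrete
#' reflection site with (real) reflection coefficient `gamma` at one-way
#' transit time `round_trip_delay_s / 2`.  Per beat the forward volumetric
#' flow is a half-sine over the ejection window; forward pressure is
#' `Zc * Qf` and the backward wave is `gamma * Pf(t - round_trip_delay_s)`
#' (in `"reverberant"` mode, the full geometric re-reflection train).
#'
#' Defaults describe a large-animal preparation: heart rate ~120 bpm,
#' diastolic pressure 90 mmHg, characteristic impedance 65 dyn s cm-5,
#' peak ejection flow 350 mL/s (cardiac output ~4.7 L/min at these
#' settings), aortic cross-section 3.1 cm2 (~2 cm diameter), a modest
#' reflection (gamma 0.2) returning 60 ms after ejection onset, which at a
#' pulse wave velocity of ~4 m/s corresponds to a reflection site ~12 cm
#' downstream.
#'
#' @param heart_rate_bpm beats per minute.
#' @param n_beats number of beats to generate (>= 1).
#' @param fs_hz sampling rate, Hz.
#' @param zc_true characteristic impedance, dyn s cm-5.
#' @param gamma reflection coefficient in `[0, 1)`.
#' @param round_trip_delay_s round-trip travel time to the reflection
#'   site (2 tau), seconds; must be shorter than the cardiac cycle.
#' @param ejection_fraction_of_cycle systolic ejection duration as a
#'   fraction of the cycle, in (0, 1).
#' @param peak_flow_ml_s peak of the half-sine forward flow, mL/s.
#' @param diastolic_pressure_mmhg additive diastolic pressure level, mmHg.
#' @param probe_area_cm2 aortic cross-section used to convert flow to
#'   velocity, cm2.
#' @param rr_jitter_sd_s SD of Gaussian beat-to-beat period jitter, s.
#' @param noise_sd_pressure_mmhg,noise_sd_flow_ml_s additive white
#'   measurement noise SDs on the pressure and flow channels.
#' @param seed integer RNG seed; identical seeds give identical records.
#' @param reflection_mode `"single"` (one echo) or `"reverberant"`
#'   (geometric train of re-reflections, truncated at a relative
#'   amplitude of 1e-6).
#' @return an object of class `synthetic_config`.
#' @seealso [generate_recording]
#' @export
synthetic_config <- function(heart_rate_bpm = 120,
                             n_beats = 12,
                             fs_hz = 1000,
                             zc_true = 65,
                             gamma = 0.2,
                             round_trip_delay_s = 0.06,
                             ejection_fraction_of_cycle = 0.35,
                             peak_flow_ml_s = 350,
                             diastolic_pressure_mmhg = 90,
                             probe_area_cm2 = 3.1,
                             rr_jitter_sd_s = 0,
                             noise_sd_pressure_mmhg = 0,
                             noise_sd_flow_ml_s = 0,
                             seed = 1L,
                             reflection_mode = c("single", "reverberant")) {
  cfg <- list(heart_rate_bpm = heart_rate_bpm, n_beats = n_beats,
              fs_hz = fs_hz, zc_true = zc_true, gamma = gamma,
              round_trip_delay_s = round_trip_delay_s,
              ejection_fraction_of_cycle = ejection_fraction_of_cycle,
              peak_flow_ml_s = peak_flow_ml_s,
              diastolic_pressure_mmhg = diastolic_pressure_mmhg,
              probe_area_cm2 = probe_area_cm2,
              rr_jitter_sd_s = rr_jitter_sd_s,
              noise_sd_pressure_mmhg = noise_sd_pressure_mmhg,
              noise_sd_flow_ml_s = noise_sd_flow_ml_s,
              seed = as.integer(seed),
              reflection_mode = match.arg(reflection_mode))
  .validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

.validate_synthetic_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid synthetic configuration: field '", field,
                  "' ", why, call. = FALSE)
  }
  chk(is.numeric(cfg$fs_hz) && cfg$fs_hz > 0, "fs_hz", "must be > 0")
  chk(cfg$heart_rate_bpm > 0, "heart_rate_bpm", "must be > 0")
  chk(cfg$n_beats >= 1, "n_beats", "must be >= 1")
  chk(cfg$zc_true > 0, "zc_true", "must be > 0")
  chk(cfg$gamma >= 0 && cfg$gamma < 1, "gamma", "must lie in [0, 1)")
  cycle <- 60 / cfg$heart_rate_bpm
  chk(cfg$round_trip_delay_s >= 0 && cfg$round_trip_delay_s < cycle,
      "round_trip_delay_s", "must be >= 0 and shorter than the cycle")
  chk(cfg$ejection_fraction_of_cycle > 0 &&
        cfg$ejection_fraction_of_cycle < 1,
      "ejection_fraction_of_cycle", "must lie in (0, 1)")
  chk(cfg$peak_flow_ml_s > 0, "peak_flow_ml_s", "must be > 0")
  chk(cfg$probe_area_cm2 > 0, "probe_area_cm2", "must be > 0")
  chk(cfg$rr_jitter_sd_s >= 0, "rr_jitter_sd_s", "must be >= 0")
  chk(cfg$noise_sd_pressure_mmhg >= 0, "noise_sd_pressure_mmhg",
      "must be >= 0")
  chk(cfg$noise_sd_flow_ml_s >= 0, "noise_sd_flow_ml_s", "must be >= 0")
  invisible(cfg)
}

#' Generate a synthetic pressure/flow/velocity/ECG recording
#'
#' Simulates the single-tube transmission-line model described in
#' [synthetic_config] and returns both the "measured" record (with noise,
#' if configured) and a ground-truth sidecar holding the noise-free
#' forward and backward pressure traces and the generating parameters,
#' for recovery testing of the analysis pipeline.
#'
#' In the noise-free case the channels satisfy, at every sample and to
#' machine precision,
#' `aop - diastolic = pf + pb` and `flow = (pf - pb) / Zc`
#' (with the mmHg/CGS conversion applied).  The ECG channel carries a
#' 20 ms triangular R complex whose apex marks each beat onset.
#'
#' @param config a [synthetic_config].
#' @return a list with elements `record` (a [waveform_record]) and
#'   `truth` (class `synthetic_truth`: `zc_true`, `gamma`,
#'   `round_trip_delay_s`, `pf_trace`, `pb_trace` in mmHg, the beat onset
#'   sample indices `r_onset_idx`, per-beat periods `rr_s`, ejection
#'   duration `ejection_s`, and `seed`).
#' @export
generate_recording <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, config)
  }
  .validate_synthetic_config(config)
  cfg <- config
  set.seed(cfg$seed)

  cycle <- 60 / cfg$heart_rate_bpm
  rr <- cycle + if (cfg$rr_jitter_sd_s > 0) {
    stats::rnorm(cfg$n_beats, 0, cfg$rr_jitter_sd_s)
  } else rep(0, cfg$n_beats)
  if (any(rr <= cfg$ejection_fraction_of_cycle * cycle)) {
    stop("invalid synthetic configuration: field 'rr_jitter_sd_s' ",
         "produced a cycle shorter than the ejection window", call. = FALSE)
  }

  lead_in <- 0.05                       # room for the first R-wave upstroke
  onsets <- lead_in + cumsum(c(0, rr[-cfg$n_beats]))
  # pad the tail so late re-reflections of the last beat are captured
  total <- lead_in + sum(rr) + cfg$round_trip_delay_s
  n <- ceiling(total * cfg$fs_hz) + 1L
  t <- (seq_len(n) - 1) / cfg$fs_hz

  # forward flow: half-sine per beat over its ejection window
  qf <- numeric(n)
  onset_idx <- integer(cfg$n_beats)
  for (b in seq_len(cfg$n_beats)) {
    te <- cfg$ejection_fraction_of_cycle * rr[b]
    rel <- t - onsets[b]
    in_ej <- rel >= 0 & rel < te
    qf[in_ej] <- qf[in_ej] + cfg$peak_flow_ml_s * sin(pi * rel[in_ej] / te)
    onset_idx[b] <- which(rel >= 0)[1]
  }

  pf <- cfg$zc_true * qf / .mmhg_to_dyn_cm2   # mmHg above diastolic
  ds <- round(cfg$round_trip_delay_s * cfg$fs_hz)
  shift <- function(x, k) if (k == 0) x else c(numeric(min(k, length(x))),
                                               x[seq_len(max(0, length(x) - k))])
  if (cfg$reflection_mode == "single" || cfg$gamma == 0) {
    pb <- cfg$gamma * shift(pf, ds)
  } else {
    pb <- numeric(n)
    k <- 1L
    while (cfg$gamma^k >= 1e-6) {
      pb <- pb + cfg$gamma^k * shift(pf, k * ds)
      k <- k + 1L
    }
  }

  q <- (pf - pb) * .mmhg_to_dyn_cm2 / cfg$zc_true   # mL/s
  p <- cfg$diastolic_pressure_mmhg + pf + pb
  if (cfg$noise_sd_pressure_mmhg > 0) {
    p <- p + stats::rnorm(n, 0, cfg$noise_sd_pressure_mmhg)
  }
  if (cfg$noise_sd_flow_ml_s > 0) {
    q <- q + stats::rnorm(n, 0, cfg$noise_sd_flow_ml_s)
  }
  u <- convert_units(q / cfg$probe_area_cm2, "cm/s", "m/s")

  # 20 ms triangular R complex, apex at the beat onset sample
  ecg <- numeric(n)
  half <- round(0.010 * cfg$fs_hz)
  tri <- c(seq(0, 1, length.out = half + 1L),
           seq(1, 0, length.out = half + 1L)[-1])
  for (b in seq_len(cfg$n_beats)) {
    i0 <- onset_idx[b] - half
    sel <- seq(i0, i0 + 2L * half)
    keep <- sel >= 1L & sel <= n
    ecg[sel[keep]] <- pmax(ecg[sel[keep]], tri[keep])
  }

  rec <- waveform_record(
    fs_hz = cfg$fs_hz,
    channels = list(ecg = ecg, aop = p, flow = q, velocity = u),
    subject_id = paste0("synthetic-seed", cfg$seed),
    condition = "synthetic")
  truth <- structure(
    list(zc_true = cfg$zc_true, gamma = cfg$gamma,
         round_trip_delay_s = cfg$round_trip_delay_s,
         pf_trace = pf, pb_trace = pb,
         r_onset_idx = onset_idx, rr_s = rr,
         ejection_s = cfg$ejection_fraction_of_cycle * rr,
         diastolic_pressure_mmhg = cfg$diastolic_pressure_mmhg,
         probe_area_cm2 = cfg$probe_area_cm2, seed = cfg$seed),
    class = "synthetic_truth")
  list(record = rec, truth = truth)
}
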