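# Shared fixtures, all generated in code.

# minimal ensemble_beat built directly from traces (bypasses averaging)
make_beat <- function(p, q = NULL, u = NULL, fs = 1000, lvp = NULL,
                      onset_s = NA_real_, end_s = NA_real_, rr_s = NULL) {
  structure(
    list(fs_hz = fs, p_mmhg = p, q_ml_s = q, u_m_s = u, lvp_mmhg = lvp,
         n_beats_averaged = 1L,
         rr_s = rr_s %||% (length(p) / fs),
         ejection_onset_s = onset_s, ejection_end_s = end_s),
    class = "ensemble_beat")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# noise-free tube simulation + full pipeline stages, small and fast
run_pipeline <- function(gamma, delay = 0.06, seed = 1, ...) {
  sim <- generate_recording(synthetic_config(gamma = gamma,
                                             round_trip_delay_s = delay,
                                             seed = seed, ...))
  metrics <- analyze_record(sim$record)
  list(sim = sim, metrics = metrics, stages = attr(metrics, "stages"))
}
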