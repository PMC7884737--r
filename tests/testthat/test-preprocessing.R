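test_that("R peaks are found at the generator's beat onsets", {
  sim <- generate_recording(synthetic_config(n_beats = 10, seed = 2))
  seg <- detect_r_peaks(sim$record$channels$ecg, sim$record$fs_hz)
  expect_length(seg$r_peak_indices, 10)
  expect_true(all(abs(seg$r_peak_indices - sim$truth$r_onset_idx) <= 2))
  expect_true(all(diff(seg$r_peak_indices) > 0))
  expect_true(all(seg$rr_s > 0))
})

test_that("R-peak detection survives 10% ECG noise without extra beats", {
  set.seed(11)
  sim <- generate_recording(synthetic_config(n_beats = 10, seed = 11))
  ecg <- sim$record$channels$ecg + rnorm(length(sim$record$channels$ecg),
                                         0, 0.1)
  seg <- detect_r_peaks(ecg, 1000)
  expect_length(seg$r_peak_indices, 10)
  expect_true(all(abs(seg$r_peak_indices - sim$truth$r_onset_idx) <= 10))
})

test_that("degenerate ECG inputs raise segmentation errors", {
  expect_error(detect_r_peaks(rep(0.5, 1000), 1000), "flat-line")
  expect_error(detect_r_peaks(numeric(0), 1000), "empty")
  # single beat -> fewer than 2 peaks
  sim <- generate_recording(synthetic_config(n_beats = 1))
  expect_error(detect_r_peaks(sim$record$channels$ecg, 1000),
               "fewer than 2")
})

test_that("averaging identical beats reproduces a single beat", {
  sim <- generate_recording(synthetic_config(n_beats = 9, gamma = 0.2))
  seg <- detect_r_peaks(sim$record$channels$ecg, 1000)
  beat <- ensemble_average(sim$record, seg, 8)
  i <- seg$r_peak_indices
  one <- sim$record$channels$aop[i[1]:(i[2] - 1)]
  expect_equal(length(beat$p_mmhg), length(one))
  expect_lt(max(abs(beat$p_mmhg - one)), 1e-9 * max(abs(one)))
  expect_identical(beat$n_beats_averaged, 8L)
})

test_that("averaging is linear in its input channels", {
  sim <- generate_recording(synthetic_config(n_beats = 9))
  seg <- detect_r_peaks(sim$record$channels$ecg, 1000)
  b1 <- ensemble_average(sim$record, seg, 8)
  rec2 <- sim$record
  rec2$channels$aop <- 2 * rec2$channels$aop + 5
  b2 <- ensemble_average(rec2, seg, 8)
  expect_equal(b2$p_mmhg, 2 * b1$p_mmhg + 5, tolerance = 1e-12)
})

test_that("too few beats is an informative error", {
  sim <- generate_recording(synthetic_config(n_beats = 7))
  seg <- detect_r_peaks(sim$record$channels$ecg, 1000)
  expect_error(ensemble_average(sim$record, seg, 8),
               "6 full beat\\(s\\) available, 8 requested")
})

test_that("ejection landmarks recover a rectangular pulse and the synthetic window", {
  # rectangular flow 0.1 - 0.3 s
  q <- numeric(500)
  q[101:300] <- 100
  lm <- locate_ejection(make_beat(p = rep(100, 500), q = q))
  expect_equal(lm[["ejection_onset_s"]], 0.1, tolerance = 0.005)
  expect_equal(lm[["ejection_end_s"]], 0.3, tolerance = 0.005)

  # no-reflection synthetic beat: configured window is [0, 0.175] s
  pl <- run_pipeline(gamma = 0)
  expect_lt(abs(pl$stages$beat$ejection_onset_s - 0), 0.005)
  expect_lt(abs(pl$stages$beat$ejection_end_s - 0.175), 0.005)

  expect_error(locate_ejection(make_beat(p = rep(1, 10),
                                         q = rep(0, 10))),
               "non-positive")
})

test_that("beat summaries satisfy the pulse-pressure identity and recover CO", {
  pl <- run_pipeline(gamma = 0)
  s <- pl$stages$summary
  expect_equal(s$pp_mmhg, s$sbp_mmhg - s$dbp_mmhg)
  expect_gte(s$sbp_mmhg, s$dbp_mmhg)
  # configured stroke volume: half-sine mean 2/pi * peak * Te
  sv_ml <- 2 / pi * 350 * 0.175
  co_expected <- sv_ml * 120 / 1000
  expect_equal(s$co_l_min, co_expected, tolerance = 0.02)
  expect_equal(s$hr_bpm, 120, tolerance = 0.01)
})

test_that("a constant pressure trace gives zero PP and zero derivatives", {
  q <- pmax(sin(seq(0, 2 * pi, length.out = 500)), 0) * 100
  beat <- make_beat(p = rep(80, 500), q = q, lvp = rep(50, 500))
  s <- summarize_beat(beat)
  expect_equal(s$pp_mmhg, 0)
  expect_equal(s$lv_dpdt_max_mmhg_s, 0)
  expect_equal(s$lv_dpdt_min_mmhg_s, 0)
  expect_false(s$lvp_missing)
})

test_that("missing LV pressure is flagged, not fatal", {
  pl <- run_pipeline(gamma = 0.2)
  s <- pl$stages$summary
  expect_true(s$lvp_missing)
  expect_true(is.na(s$lv_dpdt_max_mmhg_s))
})
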