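test_that("write/read round trip is lossless and preserves metadata", {
  sim <- generate_recording(synthetic_config(n_beats = 3,
                                             noise_sd_pressure_mmhg = 1,
                                             seed = 3))
  rec <- sim$record
  rec$units[["ecg"]] <- "millivolt (custom)"
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  for (ch in names(rec$channels)) {
    fullscale <- max(abs(rec$channels[[ch]]))
    expect_lt(max(abs(back$channels[[ch]] - rec$channels[[ch]])),
              1e-9 * max(fullscale, 1))
  }
  expect_identical(back$units[["ecg"]], "millivolt (custom)")
  expect_identical(back$subject_id, rec$subject_id)
  expect_identical(back$condition, rec$condition)
  expect_equal(back$fs_hz, rec$fs_hz)
})

test_that("header-declared sampling rate and row count are honoured", {
  path <- withr::local_tempfile(fileext = ".csv")
  n <- 5000
  writeLines(c("# fs_hz=1000", "ecg,aop,flow",
               paste(rnorm(n), rnorm(n, 100), rnorm(n, 50), sep = ",")),
             path)
  rec <- read_recording(path)
  expect_equal(rec$fs_hz, 1000)
  expect_length(rec$channels$aop, n)
})

test_that("a uniform time_s column sets the rate; non-uniform time errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  t <- seq(0, 0.099, by = 0.001)
  df <- data.frame(time_s = t, ecg = rnorm(100), aop = rnorm(100, 100),
                   flow = rnorm(100, 10))
  utils::write.csv(df, path, row.names = FALSE)
  expect_equal(read_recording(path)$fs_hz, 1000, tolerance = 1e-9)

  df$time_s[50] <- df$time_s[50] + 2e-4
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_recording(path), "uniform within 1 ppm")
})

test_that("missing mandatory channels are reported by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# fs_hz=1000", "ecg,flow", "0.1,2", "0.2,3"), path)
  expect_error(read_recording(path), "aop")
  writeLines(c("# fs_hz=1000", "ecg,aop", "0.1,2", "0.2,3"), path)
  expect_error(read_recording(path), "flow.*velocity|velocity.*flow")
})

test_that("non-finite samples are rejected by default, repairable on request", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# fs_hz=1000", "ecg,aop,flow",
               "0,100,1", "1,NA,2", "0,102,3", "0,103,4"), path)
  expect_error(read_recording(path), "non-finite")
  expect_message(rec <- read_recording(path, interpolate = TRUE),
                 "interpolated 1")
  expect_equal(rec$channels$aop[2], 101)  # linear fill between 100 and 102
})

test_that("records that violate invariants cannot be written", {
  bad <- structure(list(fs_hz = 1000, t0_s = 0,
                        channels = list(ecg = numeric(0)),
                        units = c(ecg = "a.u."),
                        subject_id = "s", condition = "c"),
                   class = "waveform_record")
  expect_error(write_recording(bad, withr::local_tempfile()), "empty")
})

test_that("diameter tables are read with validation", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,condition,dmax_mm,dmin_mm",
               "g1,baseline,19.7,18.4", "g1,after_evar,19.3,18.8"), path)
  d <- read_diameters(path)
  expect_length(d, 2)
  expect_equal(d[[1]]$dmax_mm, 19.7)
  writeLines(c("subject_id,condition,dmax_mm,dmin_mm",
               "g1,baseline,18.0,18.4"), path)
  expect_error(read_diameters(path), "dmax_mm")
  writeLines("subject_id,dmax_mm", path)
  expect_error(read_diameters(path), "missing column")
})

test_that("flat key-value and JSON configurations both parse", {
  path <- withr::local_tempfile()
  writeLines(c("# a comment", "gamma: 0.3", "n_beats = 5",
               "reflection_mode: single"), path)
  cfg <- read_flat_config(path)
  expect_equal(cfg$gamma, 0.3)
  expect_equal(cfg$n_beats, 5)
  expect_identical(cfg$reflection_mode, "single")
  writeLines('{"gamma": 0.3, "n_beats": 5}', path)
  cfg2 <- read_flat_config(path)
  expect_equal(cfg2$gamma, 0.3)
})
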