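test_that("simulation is deterministic given the seed", {
  cfg <- simulation_config(30, seed = 7)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$annotations, b$annotations)
  c <- simulate_recording(simulation_config(30, seed = 8))
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("a seizure-free config yields empty annotations and broadband epochs", {
  sim <- simulate_recording(simulation_config(64, seed = 5))
  expect_equal(nrow(sim$annotations), 0)
  # no 8 s segment should carry a dominant narrowband discharge: the
  # 0.5-6 Hz band power varies only within a modest factor across segments
  fs <- sim$recording$sample_rate_hz
  seg_pow <- vapply(0:6, function(k) {
    band_power(sim$recording$data[1, (k * 8 * fs + 1):((k + 1) * 8 * fs)],
               fs, 0.5, 6)
  }, numeric(1))
  expect_lt(max(seg_pow) / stats::median(seg_pow), 3)
})

test_that("discharges appear at the configured frequency on the configured channels", {
  sim <- fixture_sim()
  fs <- sim$recording$sample_rate_hz
  idx <- (80 * fs):(120 * fs)          # inside the annotated [60, 140) event
  pk <- peak_freq(sim$recording$data[1, idx], fs)
  expect_lt(abs(pk - 2.5), 0.2)
  # unaffected channel: no narrowband peak near the discharge frequency
  pk8 <- peak_freq(sim$recording$data[8, idx], fs)
  expect_gt(abs(pk8 - 2.5), 0.2)
  # annotations equal the configured intervals
  expect_equal(sim$annotations$onset_s, 60)
  expect_equal(sim$annotations$offset_s, 140)
  # per-channel truth only lists affected channels
  expect_equal(nrow(sim$channel_annotations[["F4-C4"]]), 1)
  expect_equal(nrow(sim$channel_annotations[["C3-T3"]]), 0)
})

test_that("seizure segments carry at least 3x the in-band power of background", {
  sim <- fixture_sim()
  fs <- sim$recording$sample_rate_hz
  x <- sim$recording$data[1, ]
  seiz <- band_power(x[(80 * fs):(120 * fs)], fs, 0.5, 6)
  bg <- band_power(x[(10 * fs):(50 * fs)], fs, 0.5, 6)
  expect_gt(seiz / bg, 3)
})

test_that("invalid event tables are rejected", {
  ev_overlap <- seizure_events(c(10, 30), c(40, 60), channels = list(1L, 2L))
  expect_error(simulation_config(100, seizure_events = ev_overlap),
               "non-overlapping")
  ev_out <- seizure_events(90, 130)
  expect_error(simulation_config(100, seizure_events = ev_out),
               "within")
  ev_freq <- seizure_events(10, 30, freq_hz = 8)
  expect_error(simulation_config(100, seizure_events = ev_freq),
               "0.5")
  ev_chan <- seizure_events(10, 30, channels = list(9L))
  expect_error(simulation_config(100, seizure_events = ev_chan),
               "channel")
})

test_that("recordings round-trip through EDF within the quantization step", {
  sim <- simulate_recording(simulation_config(10, sample_rate_hz = 64,
                                              seed = 2))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(sim$recording, path)
  back <- read_edf(path)
  expect_equal(back$sample_rate_hz, 64)
  expect_identical(back$channel_labels, sim$recording$channel_labels)
  q_step <- 1000 / 65535               # physical range / digital range
  expect_lt(max(abs(back$data - sim$recording$data)), q_step)
})

test_that("annotation CSVs round-trip", {
  ann <- annotation_track(c(10.5, 100), c(40, 160.25))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  expect_equal(read_annotations(path)$offset_s, c(40, 160.25))
})
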