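test_that("the phase vocoder honours the stretch-factor length contract", {
  set.seed(1)
  # the worked audification size: 1000 s of 32 Hz EEG, factor 100
  x <- rnorm(32000)
  y <- phase_vocoder_stretch(x, 100)
  expect_lt(abs(length(y) - 100 * length(x)), 16 + 1)   # within one hop
  # identity stretch preserves duration and (approximately) the signal
  t <- (0:999) / 32
  tone <- sin(2 * pi * 4 * t)
  y1 <- phase_vocoder_stretch(tone, 1)
  expect_equal(length(y1), 1000)
  expect_gt(stats::cor(y1[100:900], tone[100:900]), 0.99)
  expect_error(phase_vocoder_stretch(rnorm(10), 100), "window")
})

test_that("stretching preserves the normalized spectral peak", {
  t <- (0:(32 * 60 - 1)) / 32
  for (f in c(2, 6)) {
    y <- phase_vocoder_stretch(sin(2 * pi * f * t), 100)
    # peak on the stretched 32 Hz grid: normalized frequency unchanged
    pk <- peak_freq(y, 32 * 100)
    expect_lt(abs(pk - f * 100), 32 * 100 / 64)   # within one analysis bin
  }
})

test_that("hemisphere channels are chosen by maximal cumulative probability", {
  labs <- neonatal_bipolar_labels()
  m <- matrix(0, nrow = 8, ncol = 10, dimnames = list(labs, NULL))
  m["F3-C3", ] <- 0.6
  m["T4-C4", ] <- 0.3
  sel <- select_hemisphere_channels(make_trace(m, labs))
  expect_equal(sel$left, "F3-C3")
  expect_equal(sel$right, "T4-C4")
  # exact tie on the right: first channel in montage order wins
  m2 <- m; m2["F4-C4", ] <- 0.3
  sel2 <- select_hemisphere_channels(make_trace(m2, labs))
  expect_equal(sel2$right, "F4-C4")
  # brute-force oracle over random traces
  set.seed(44)
  hmap <- default_hemisphere_map()
  for (i in 1:25) {
    mr <- matrix(runif(8 * 12), nrow = 8, dimnames = list(labs, NULL))
    sel_r <- select_hemisphere_channels(make_trace(mr, labs))
    for (side in c("left", "right")) {
      cand <- labs[hmap[labs] == side]
      sums <- rowSums(mr[cand, ])
      expect_equal(sel_r[[side]], cand[which.max(sums)])
    }
  }
  expect_error(
    select_hemisphere_channels(make_trace(mr, labs),
                               c("F4-C4" = "right")),
    "left")
})

test_that("a 120 s record renders to 12 s of stereo audio at 32 kHz", {
  set.seed(2)
  sim <- simulate_recording(simulation_config(120, sample_rate_hz = 32,
                                              seed = 2))
  audio <- render_stereo(sim$recording)
  expect_equal(audio$rate_hz, 32000)
  expect_equal(ncol(audio$samples), 2)
  expect_lt(abs(audio$duration_s - 12) / 12, 0.005)     # duration / 10
  expect_lte(max(abs(audio$samples)), 1)                # no clipping
})

test_that("the probability gain law scales output RMS by the gain floor", {
  t <- (0:(32 * 60 - 1)) / 32
  rec <- make_recording(rep(list(0.05 * sin(2 * pi * 3 * t)), 8), 32,
                        neonatal_bipolar_labels())
  labs <- neonatal_bipolar_labels()
  lo <- make_trace(matrix(0, 8, 14, dimnames = list(labs, NULL)), labs)
  hi <- make_trace(matrix(1, 8, 14, dimnames = list(labs, NULL)), labs)
  cfg <- audify_config(gain_floor = 0.2)
  a_lo <- render_stereo(rec, lo, cfg)
  a_hi <- render_stereo(rec, hi, cfg)
  rms <- function(a) sqrt(mean(a$samples[, 1]^2))
  expect_equal(rms(a_lo) / rms(a_hi), 0.2, tolerance = 0.01)
})

test_that("swapping the hemisphere map swaps the stereo streams exactly", {
  set.seed(3)
  sim <- simulate_recording(simulation_config(60, sample_rate_hz = 32,
                                              seed = 3))
  labs <- neonatal_bipolar_labels()
  tr <- make_trace(matrix(runif(8 * 13), 8, dimnames = list(labs, NULL)),
                   labs)
  hmap <- default_hemisphere_map()
  swapped <- ifelse(hmap == "left", "right", "left")
  names(swapped) <- names(hmap)
  a <- render_stereo(sim$recording, tr, audify_config(hemisphere_map = hmap))
  b <- render_stereo(sim$recording, tr,
                     audify_config(hemisphere_map = swapped))
  expect_identical(a$samples[, 1], b$samples[, 2])
  expect_identical(a$samples[, 2], b$samples[, 1])
  expect_equal(a$left_label, b$right_label)
})

test_that("renderings round-trip through the PCM16 WAV writer", {
  set.seed(5)
  audio <- structure(
    list(samples = cbind(runif(2000, -0.9, 0.9), runif(2000, -0.9, 0.9)),
         rate_hz = 32000, left_label = "F3-C3", right_label = "F4-C4",
         duration_s = 2000 / 32000),
    class = "audio_rendering")
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio, path)
  back <- read_wav(path)
  expect_equal(back$rate_hz, 32000)
  expect_equal(dim(back$samples), c(2000, 2))
  expect_lt(max(abs(back$samples - audio$samples)), 1 / 32767)
})
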