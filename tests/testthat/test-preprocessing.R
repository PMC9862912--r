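make_sine_trials <- function(freqs, fs = 250, dur = 12, amp = 1) {
  n <- dur * fs
  t <- seq_len(n) / fs
  data <- array(0, dim = c(length(freqs), 1, n))
  for (i in seq_along(freqs)) data[i, 1, ] <- amp * sin(2 * pi * freqs[i] * t)
  trial_set(data, labels = rep(1, length(freqs)), fs = fs,
            cue_onset_index = 2 * fs, rest_window = c(1, fs))
}

test_that("band-pass attenuates out-of-band tones and passes in-band tones", {
  ts <- make_sine_trials(c(2, 20))
  out <- bandpass(ts, preprocess_config())
  tail_idx <- 2000:3000  # steady state
  amp2 <- max(abs(out$data[1, 1, tail_idx]))
  amp20 <- max(abs(out$data[2, 1, tail_idx]))
  expect_gt(20 * log10(amp20 / amp2), 20)      # > 20 dB relative attenuation
  expect_lt(abs(20 * log10(amp20 / 1)), 1)     # in-band within 1 dB of input
})

test_that("zero input filters to zero and Nyquist violations are rejected", {
  ts <- make_sine_trials(5)
  ts$data[] <- 0
  out <- bandpass(ts)
  expect_true(all(out$data == 0))
  expect_error(bandpass(ts, preprocess_config(band_high = 130)), "Nyquist")
})

test_that("standardization recurrence matches the scalar-loop oracle", {
  set.seed(5)
  for (rep in 1:5) {
    x <- rnorm(200, sd = runif(1, 0.5, 5))
    mu0 <- runif(1, -1, 1); var0 <- runif(1, 0.5, 2)
    got <- bayesmi:::ems_channel_cpp(x, mu0, var0, 0.999, 6, 1e-8)
    want <- oracle_ems(x, mu0, var0, 0.999, 6, 1e-8)
    expect_lt(max(abs(got - want)), 1e-10)
  }
  # 10-sample toy series with printed config
  x <- c(1, 2, -1, 0.5, 3, -2, 0, 1.5, -0.5, 2.5)
  got <- as.numeric(bayesmi:::ems_channel_cpp(x, 0, 1, 0.999, 6, 1e-8))
  expect_equal(got, oracle_ems(x, 0, 1, 0.999, 6, 1e-8), tolerance = 1e-12)
})

test_that("a constant signal at its rest mean standardizes to zero", {
  out <- bayesmi:::ems_channel_cpp(rep(3.2, 50), 3.2, 0.7, 0.999, 6, 1e-8)
  expect_true(all(out == 0))
})

test_that("outliers are rectified to at most the clip bound", {
  x <- c(rnorm(100), 100)  # final sample at ~100 sigma
  got <- bayesmi:::ems_channel_cpp(x, 0, 1, 0.999, 6, 1e-8)
  expect_lte(abs(got[101]), 6 + 0.05)
})

test_that("full trial-set standardization flags and floors degenerate rest", {
  data <- array(rnorm(2 * 1 * 600), dim = c(2, 1, 600))
  data[1, 1, 1:100] <- 5  # constant rest window
  ts <- trial_set(data, c(1, 1), fs = 100, cue_onset_index = 101,
                  rest_window = c(1, 100))
  expect_warning(out <- exp_moving_standardize(ts), "floor")
  expect_true(all(is.finite(out$data)))
  expect_true(out$preprocessed)
})

test_that("crop arithmetic reproduces the stated counts and lengths", {
  cfg <- preprocess_config()
  expect_equal(n_crops_per_trial(cfg), 563L)
  expect_equal(round(cfg$crop_len_s * 250), 1000)
  starts <- cfg$crop_start_s + (seq_len(563) - 1) * cfg$crop_stride_s
  expect_equal(starts[563], 3.996)

  cfg1 <- preprocess_config(crop_start_end_s = -0.5)  # degenerate range
  expect_equal(n_crops_per_trial(cfg1), 1L)
})

test_that("cropping extracts aligned windows with inherited labels", {
  cfg <- eeg_sim_config(n_trials_per_class = 2, n_classes = 2,
                        n_channels = 2, seed = 2)
  ts <- generate_eeg(cfg)
  pc <- preprocess_config(crop_stride_s = 1.0)
  cs <- crop_trials(ts, pc)
  expect_equal(cs$n_per_trial, 5L)  # starts -0.5, 0.5, ..., 3.5
  expect_equal(dim(cs$crops), c(20, 2, 1000))
  expect_equal(cs$labels, rep(ts$labels, each = 5))
  expect_equal(unname(table(cs$trial_index)), unname(table(rep(1:4, each = 5))))
  # first crop of trial 1 starts at -0.5 s: sample cue - 125
  i0 <- ts$cue_onset_index - 125
  expect_equal(cs$crops[1, 1, ], ts$data[1, 1, i0:(i0 + 999)])
  # crop count per trial constant
  expect_equal(length(unique(table(cs$trial_index))), 1L)
})

test_that("too-short trials are rejected with a span diagnostic", {
  data <- array(rnorm(1 * 1 * 500), dim = c(1, 1, 500))
  ts <- trial_set(data, 1, fs = 250, cue_onset_index = 200,
                  rest_window = c(1, 100))
  expect_error(crop_trials(ts, preprocess_config()), "span too short")
})
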