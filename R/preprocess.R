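#' Preprocessing configuration
#'
#' Parameters of the three-stage cropped-EEG preprocessing pipeline:
#' band-pass filter, electrode-wise exponential moving standardization
#' with outlier rectification, and sliding-window crop augmentation.
#' The fixed order is filter -> clip+standardize -> crop.
#'
#' @param band_low,band_high band-pass edges (Hz); defaults 4 and 38
#'   preserve the mu and beta rhythms while rejecting drift and EMG.
#' @param filter_order Butterworth design order per edge (default 4).
#' @param zero_phase if `TRUE`, filter forward and backward
#'   (zero-phase); default is a single causal pass, which is what an
#'   online system could compute.
#' @param decay exponential-moving-standardization decay factor lambda.
#' @param clip_factor outlier rectification bound in multiples of the
#'   running sigma.
#' @param var_floor variance floor protecting the division when a rest
#'   window is (near-)constant.
#' @param crop_len_s crop length in seconds (4 s = 1000 samples at
#'   250 Hz).
#' @param crop_stride_s stride between consecutive crop starts (8 ms).
#' @param crop_start_s,crop_start_end_s first and last allowed crop
#'   start times (seconds, cue-relative).  The defaults -0.5 to 4 give
#'   563 crops per trial; interpreting the range as bounding the crop
#'   starts (rather than the whole extraction window) is what makes the
#'   central-crop interval land mid-trial.
#' @return a `preprocess_config` object.
#' @export
preprocess_config <- function(band_low = 4, band_high = 38, filter_order = 4,
                              zero_phase = FALSE, decay = 0.999,
                              clip_factor = 6, var_floor = 1e-8,
                              crop_len_s = 4.0, crop_stride_s = 0.008,
                              crop_start_s = -0.5, crop_start_end_s = 4.0) {
  stopifnot(band_low > 0, band_low < band_high, filter_order >= 1,
            decay > 0, decay < 1, clip_factor > 0, var_floor > 0,
            crop_len_s > 0, crop_stride_s > 0,
            crop_start_end_s >= crop_start_s)
  structure(list(band_low = band_low, band_high = band_high,
                 filter_order = as.integer(filter_order),
                 zero_phase = isTRUE(zero_phase), decay = decay,
                 clip_factor = clip_factor, var_floor = var_floor,
                 crop_len_s = crop_len_s, crop_stride_s = crop_stride_s,
                 crop_start_s = crop_start_s,
                 crop_start_end_s = crop_start_end_s),
            class = "preprocess_config")
}

#' Band-pass filter a trial set
#'
#' Applies a Butterworth band-pass (order `filter_order` per edge) to
#' every channel of every trial.  Causal single-pass by default;
#' `zero_phase = TRUE` uses forward-backward filtering.
#'
#' @param trials a [trial_set()].
#' @param config a [preprocess_config()].
#' @return the filtered `trial_set`.
#' @export
bandpass <- function(trials, config = preprocess_config()) {
  stopifnot(inherits(trials, "trial_set"), inherits(config, "preprocess_config"))
  if (config$band_high >= trials$fs / 2)
    stop("band edge at or above the Nyquist frequency")
  bf <- signal::butter(config$filter_order,
                       c(config$band_low, config$band_high) * 2 / trials$fs,
                       type = "pass")
  d <- trials$data
  for (tr in seq_len(dim(d)[1]))
    for (ch in seq_len(dim(d)[2])) {
      x <- d[tr, ch, ]
      d[tr, ch, ] <- if (config$zero_phase)
        as.numeric(signal::filtfilt(bf, x))
      else as.numeric(signal::filter(bf, x))
    }
  trials$data <- d
  trials
}

#' Exponential moving standardization with outlier rectification
#'
#' Per channel and trial, the starting mean and variance are computed
#' over the pre-cue rest window; then, sample by sample, the amplitude
#' is first clipped to `mean +/- clip_factor * sd` using the statistics
#' available before the current sample, the running mean and variance
#' are updated with decay `lambda`
#' (`mu_i = lambda * mu_{i-1} + (1-lambda) * x_i`,
#' `var_i = lambda * var_{i-1} + (1-lambda) * (x_i - mu_i)^2`),
#' and the output is `(x_i - mu_i) / sd_i`.
#'
#' @param trials a band-passed [trial_set()].
#' @param config a [preprocess_config()].
#' @return the standardized `trial_set` (`preprocessed = TRUE`).
#' @export
exp_moving_standardize <- function(trials, config = preprocess_config()) {
  stopifnot(inherits(trials, "trial_set"), inherits(config, "preprocess_config"))
  d <- trials$data
  rw <- trials$rest_window[1]:trials$rest_window[2]
  warned <- FALSE
  for (tr in seq_len(dim(d)[1]))
    for (ch in seq_len(dim(d)[2])) {
      x <- d[tr, ch, ]
      mu0 <- mean(x[rw])
      var0 <- stats::var(x[rw])
      if (var0 <= config$var_floor && !warned) {
        warning("rest-window variance at or below the floor; using the floor")
        warned <- TRUE
      }
      d[tr, ch, ] <- ems_channel_cpp(x, mu0, var0, config$decay,
                                     config$clip_factor, config$var_floor)
    }
  trials$data <- d
  trials$preprocessed <- TRUE
  trials
}

#' Number of crops per trial implied by a configuration
#' @param config a [preprocess_config()].
#' @return integer crop count `floor((end - start) / stride) + 1`.
#' @export
n_crops_per_trial <- function(config = preprocess_config()) {
  as.integer(floor((config$crop_start_end_s - config$crop_start_s) /
                   config$crop_stride_s + 1e-9)) + 1L
}

#' Extract sliding-window crops for data augmentation
#'
#' Cuts every trial into crops of `crop_len_s` seconds starting at
#' `crop_start_s, crop_start_s + stride, ...` up to the largest start
#' not exceeding `crop_start_end_s`.  Sample indices are
#' `round(t * fs)` relative to the cue; windows are half-open
#' `[start, start + L)`.  Every crop inherits its trial's label.
#'
#' @param trials a standardized [trial_set()].
#' @param config a [preprocess_config()].
#' @return a `crop_set`: list with `crops` (array
#'   `n_crops_total x n_channels x L`), `trial_index`, `crop_position`
#'   (1-based ordinal within trial), `start_time_s`, `labels`, `fs`,
#'   `n_per_trial`.
#' @export
crop_trials <- function(trials, config = preprocess_config()) {
  stopifnot(inherits(trials, "trial_set"), inherits(config, "preprocess_config"))
  fs <- trials$fs
  L <- round(config$crop_len_s * fs)
  if (abs(config$crop_len_s * fs - L) > 1e-6)
    stop("crop_len_s * fs must be an integer number of samples")
  n_pos <- n_crops_per_trial(config)
  starts_s <- config$crop_start_s + (seq_len(n_pos) - 1) * config$crop_stride_s
  start_idx <- trials$cue_onset_index + round(starts_s * fs)
  n_samples <- dim(trials$data)[3]
  if (min(start_idx) < 1 || max(start_idx) + L - 1 > n_samples)
    stop(sprintf(paste0("trial span too short for cropping: need samples ",
                        "%d..%d but trials have %d"),
                 min(start_idx), max(start_idx) + L - 1, n_samples))
  n_trials <- dim(trials$data)[1]
  n_ch <- dim(trials$data)[2]
  crops <- array(0, dim = c(n_trials * n_pos, n_ch, L))
  k <- 0L
  for (tr in seq_len(n_trials))
    for (p in seq_len(n_pos)) {
      k <- k + 1L
      crops[k, , ] <- trials$data[tr, , start_idx[p]:(start_idx[p] + L - 1L)]
    }
  structure(list(crops = crops,
                 trial_index = rep(seq_len(n_trials), each = n_pos),
                 crop_position = rep(seq_len(n_pos), n_trials),
                 start_time_s = rep(starts_s, n_trials),
                 labels = rep(trials$labels, each = n_pos),
                 fs = fs, n_per_trial = n_pos),
            class = "crop_set")
}

#' Subset a crop set
#' @param cropset a `crop_set`.
#' @param idx crop indices to keep.
#' @return the subset `crop_set`.
#' @export
crop_subset <- function(cropset, idx) {
  structure(list(crops = cropset$crops[idx, , , drop = FALSE],
                 trial_index = cropset$trial_index[idx],
                 crop_position = cropset$crop_position[idx],
                 start_time_s = cropset$start_time_s[idx],
                 labels = cropset$labels[idx],
                 fs = cropset$fs, n_per_trial = cropset$n_per_trial),
            class = "crop_set")
}
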