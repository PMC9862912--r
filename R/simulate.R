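#' Configuration for the synthetic ERD/ERS EEG generator
#'
#' Describes band-limited oscillatory EEG with class-dependent amplitude
#' suppression (event-related desynchronization, ERD) of the mu and beta
#' rhythms.  Each class is assigned a channel group (round-robin:
#' channel `ch` belongs to group `((ch - 1) %% n_classes) + 1`); trials
#' of class `k` attenuate the oscillatory amplitude on group-`k`
#' channels by the factor `1 - erd_depth` during the imagery window
#' `[erd_onset_s, erd_offset_s]`.
#'
#' @param n_trials_per_class trials generated per class.
#' @param n_classes number of imagery classes (2 or 4).
#' @param n_channels number of electrodes (must be >= `n_classes`).
#' @param fs sampling rate in Hz.
#' @param trial_start_s,trial_end_s trial span in seconds relative to the
#'   cue at 0; the default -1.5 to 8 s leaves a pre-cue rest segment for
#'   the standardization starting statistics and room for the last 4-s
#'   crop starting at 3.996 s.
#' @param background_noise_sd standard deviation (microvolt) of the
#'   broadband background (white + 1/f-shaped noise in equal power).
#' @param mu_band,beta_band frequency bands (Hz) of the two sensorimotor
#'   rhythms.
#' @param mu_amp,beta_amp RMS amplitude (microvolt) of each rhythm.
#' @param erd_depth fractional amplitude suppression in `[0, 1]`; 0 means
#'   no class information at all.
#' @param erd_onset_s,erd_offset_s imagery window (seconds, cue-relative).
#' @param ramp_s linear on/off ramp of the suppression envelope.
#' @param seed integer seed; identical seed and config give bit-identical
#'   output.
#' @return an `eeg_sim_config` object.
#' @export
eeg_sim_config <- function(n_trials_per_class = 20, n_classes = 2,
                           n_channels = 3, fs = 250,
                           trial_start_s = -1.5, trial_end_s = 8.0,
                           background_noise_sd = 10,
                           mu_band = c(8, 12), beta_band = c(13, 30),
                           mu_amp = 20, beta_amp = 10,
                           erd_depth = 0.8,
                           erd_onset_s = 0.5, erd_offset_s = 4.5,
                           ramp_s = 0.1, seed = 1L) {
  stopifnot(n_trials_per_class >= 1, n_classes >= 2, fs > 0,
            n_channels >= n_classes,
            erd_depth >= 0, erd_depth <= 1,
            trial_start_s < 0, trial_end_s > erd_offset_s)
  check_band <- function(b, nm) {
    if (length(b) != 2 || b[1] >= b[2])
      stop(sprintf("invalid %s band: low edge must be below high edge", nm))
    if (b[2] >= fs / 2) stop(sprintf("%s band exceeds the Nyquist frequency", nm))
  }
  check_band(mu_band, "mu"); check_band(beta_band, "beta")
  structure(list(n_trials_per_class = n_trials_per_class,
                 n_classes = as.integer(n_classes),
                 n_channels = as.integer(n_channels), fs = fs,
                 trial_start_s = trial_start_s, trial_end_s = trial_end_s,
                 background_noise_sd = background_noise_sd,
                 mu_band = mu_band, beta_band = beta_band,
                 mu_amp = mu_amp, beta_amp = beta_amp,
                 erd_depth = erd_depth,
                 erd_onset_s = erd_onset_s, erd_offset_s = erd_offset_s,
                 ramp_s = ramp_s, seed = as.integer(seed)),
            class = "eeg_sim_config")
}

#' Construct a labeled trial set
#'
#' Container for raw or preprocessed EEG trials.  `data` is a numeric
#' array `n_trials x n_channels x n_samples`; `rest_window` is the
#' pre-cue sample interval used to initialize the standardization
#' statistics.
#'
#' @param data trials array.
#' @param labels integer class ids in `1..C`, one per trial.
#' @param fs sampling rate (Hz).
#' @param cue_onset_index sample index of t = 0.
#' @param rest_window length-2 integer vector (first, last sample) of the
#'   rest segment; must precede the cue.
#' @param preprocessed logical flag.
#' @return a `trial_set` object.
#' @export
trial_set <- function(data, labels, fs, cue_onset_index, rest_window,
                      preprocessed = FALSE) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == length(labels),
            all(is.finite(data)), all(labels >= 1),
            length(rest_window) == 2, rest_window[1] >= 1,
            rest_window[2] < cue_onset_index)
  structure(list(data = data, labels = as.integer(labels), fs = fs,
                 cue_onset_index = as.integer(cue_onset_index),
                 rest_window = as.integer(rest_window),
                 preprocessed = isTRUE(preprocessed)),
            class = "trial_set")
}

# 1/f-amplitude-shaped Gaussian noise of unit variance, via FFT shaping
pink_noise <- function(n) {
  nf <- floor(n / 2)
  f <- seq_len(nf)
  amp <- 1 / sqrt(f)
  phases <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phases)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = Re(spec[nf]))
    if (nf > 1) full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
  } else {
    full[(nf + 2):n] <- Conj(spec[nf:1])
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# band-limited Gaussian noise with the requested RMS amplitude
band_noise <- function(n, fs, band, rms) {
  bf <- signal::butter(4, band * 2 / fs, type = "pass")
  burn <- round(2 * fs)
  x <- as.numeric(signal::filter(bf, rnorm(n + burn)))
  x <- x[-seq_len(burn)]              # drop filter transient
  x / stats::sd(x) * rms
}

#' Generate synthetic motor-imagery EEG trials
#'
#' Each trial is broadband background noise (white plus 1/f-shaped) with
#' superimposed band-limited mu and beta oscillations on every channel.
#' During the imagery window the oscillatory amplitude on the channel
#' group assigned to the trial's class is multiplied by
#' `1 - erd_depth`, emulating contralateral ERD.  Classes are balanced
#' and interleaved.
#'
#' @param config an [eeg_sim_config()].
#' @return a [trial_set()] with a pre-cue rest window.
#' @export
generate_eeg <- function(config) {
  stopifnot(inherits(config, "eeg_sim_config"))
  cf <- config
  n_samples <- round((cf$trial_end_s - cf$trial_start_s) * cf$fs)
  cue_idx <- round(-cf$trial_start_s * cf$fs) + 1L
  n_trials <- cf$n_trials_per_class * cf$n_classes
  labels <- rep(seq_len(cf$n_classes), cf$n_trials_per_class)
  t_rel <- (seq_len(n_samples) - cue_idx) / cf$fs
  group <- ((seq_len(cf$n_channels) - 1L) %% cf$n_classes) + 1L

  # trapezoidal suppression envelope of the imagery window
  ramp <- cf$ramp_s
  env_for <- function(depth) {
    up <- pmin(pmax((t_rel - cf$erd_onset_s) / ramp, 0), 1)
    down <- pmin(pmax((cf$erd_offset_s + ramp - t_rel) / ramp, 0), 1)
    1 - depth * pmin(up, down)
  }
  suppress <- env_for(cf$erd_depth)

  data <- with_seed(cf$seed, {
    arr <- array(0, dim = c(n_trials, cf$n_channels, n_samples))
    bg_sd <- cf$background_noise_sd / sqrt(2)
    for (tr in seq_len(n_trials)) {
      for (ch in seq_len(cf$n_channels)) {
        x <- bg_sd * rnorm(n_samples) + bg_sd * pink_noise(n_samples)
        mu_osc <- band_noise(n_samples, cf$fs, cf$mu_band, cf$mu_amp)
        beta_osc <- band_noise(n_samples, cf$fs, cf$beta_band, cf$beta_amp)
        osc <- mu_osc + beta_osc
        if (group[ch] == labels[tr]) osc <- osc * suppress
        arr[tr, ch, ] <- x + osc
      }
    }
    arr
  })

  trial_set(data, labels, cf$fs, cue_idx,
            rest_window = c(1L, cue_idx - 1L), preprocessed = FALSE)
}

#' Configuration for synthetic Monte-Carlo predictive stacks
#'
#' Fixture generator for the uncertainty and reject-option machinery: for
#' each input, `T` class-score rows are drawn from a Dirichlet
#' distribution with concentration `concentration` on the input's true
#' class and 1 on every other class.  Larger concentration gives a mean
#' closer to the one-hot vertex and (monotonically) lower dispersion;
#' `concentration = 1` gives a uniform Dirichlet (chance-level,
#' maximally dispersed) stack.
#'
#' @param n_inputs number of stacks.
#' @param n_classes number of classes C (>= 2).
#' @param n_passes rows per stack T (>= 2).
#' @param true_class class id per input (length 1 or `n_inputs`).
#' @param concentration positive dispersion control, scalar or per input.
#' @param deterministic if `TRUE`, every row equals the Dirichlet mean
#'   exactly (the zero-dispersion limit).
#' @param seed integer seed.
#' @return a `stack_sim_config` object.
#' @export
stack_sim_config <- function(n_inputs = 100, n_classes = 4, n_passes = 50,
                             true_class = 1L, concentration = 10,
                             deterministic = FALSE, seed = 1L) {
  if (n_classes < 2) stop("need at least two classes")
  if (n_passes < 2) stop("need at least two passes (sample sd must exist)")
  stopifnot(all(concentration > 0),
            length(true_class) %in% c(1L, n_inputs),
            length(concentration) %in% c(1L, n_inputs),
            all(true_class >= 1), all(true_class <= n_classes))
  structure(list(n_inputs = as.integer(n_inputs),
                 n_classes = as.integer(n_classes),
                 n_passes = as.integer(n_passes),
                 true_class = as.integer(rep_len(true_class, n_inputs)),
                 concentration = rep_len(concentration, n_inputs),
                 deterministic = isTRUE(deterministic),
                 seed = as.integer(seed)),
            class = "stack_sim_config")
}

#' Generate synthetic predictive stacks
#'
#' @param config a [stack_sim_config()].
#' @return list with `stacks` (array `T x C x n_inputs`, every row on the
#'   C-simplex) and `true_class` (integer vector).
#' @export
generate_stacks <- function(config) {
  stopifnot(inherits(config, "stack_sim_config"))
  cf <- config
  stacks <- with_seed(cf$seed, {
    arr <- array(0, dim = c(cf$n_passes, cf$n_classes, cf$n_inputs))
    for (i in seq_len(cf$n_inputs)) {
      alpha <- rep(1, cf$n_classes)
      alpha[cf$true_class[i]] <- cf$concentration[i]
      if (cf$deterministic) {
        arr[, , i] <- matrix(alpha / sum(alpha), cf$n_passes, cf$n_classes,
                             byrow = TRUE)
      } else {
        g <- matrix(rgamma(cf$n_passes * cf$n_classes,
                           shape = rep(alpha, each = cf$n_passes)),
                    cf$n_passes, cf$n_classes)
        arr[, , i] <- g / rowSums(g)
      }
    }
    arr
  })
  list(stacks = stacks, true_class = cf$true_class)
}
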