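#' Specification for the synthetic sEMG simulator
#'
#' Describes a recording session: each subject performs each gesture class
#' `n_repetitions` times; a trial is `trial_duration` seconds of active
#' signal followed by `rest_duration` seconds of rest. Active signal is
#' band-emphasised noise: white noise passed through a second-order
#' band-pass filter centred on the class's characteristic frequency, scaled
#' per channel and per subject, with additive wideband noise, then
#' multiplied by the amplifier gain. The defaults mirror a 2000 Hz
#' two-channel acquisition amplified by 1000 with 5 s active / 5 s rest
#' trials; class band centres default to an even spread over the
#' conventional 20-450 Hz sEMG band.
#'
#' @param n_subjects,n_classes,n_channels,n_repetitions design counts.
#' @param sampling_rate sampling rate in Hz (default 2000).
#' @param trial_duration,rest_duration seconds of active signal and rest per
#'   trial (defaults 5 and 5).
#' @param class_band_centers numeric vector, one characteristic frequency
#'   (Hz) per class; default spreads `n_classes` centres over 60-450 Hz.
#' @param class_channel_gains strictly positive `n_classes x n_channels`
#'   gain matrix; default gives each class a distinct channel emphasis.
#' @param subject_gain_sd sd of the log-normal per-subject gain (default 0.1).
#' @param noise_sd additive white-noise sd in signal units (default 0.05).
#' @param amplification amplifier gain applied to the whole recording
#'   (default 1000).
#' @param n_force_levels number of force levels cycled over repetitions
#'   (default 1; use 3 for an amputee-style protocol). Force scales the
#'   active amplitude by {0.5, 1, 1.5}-style factors; the class label stays
#'   the gesture.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the spec including this seed.
#' @return an object of class `emg_sim_spec`.
#' @export
emg_sim_spec <- function(n_subjects = 9, n_classes = 10, n_channels = 2,
                         n_repetitions = 6, sampling_rate = 2000,
                         trial_duration = 5.0, rest_duration = 5.0,
                         class_band_centers = NULL,
                         class_channel_gains = NULL,
                         subject_gain_sd = 0.1, noise_sd = 0.05,
                         amplification = 1000, n_force_levels = 1,
                         seed = 1L) {
  if (is.null(class_band_centers)) {
    class_band_centers <- seq(60, 450, length.out = n_classes)
  }
  if (is.null(class_channel_gains)) {
    # distinct per-class channel profile so channels carry class information
    class_channel_gains <- outer(seq_len(n_classes), seq_len(n_channels),
                                 function(c, ch) 0.5 + ((c + ch) %% n_channels + 1) / n_channels)
  }
  spec <- structure(
    list(n_subjects = as.integer(n_subjects),
         n_classes = as.integer(n_classes),
         n_channels = as.integer(n_channels),
         n_repetitions = as.integer(n_repetitions),
         sampling_rate = sampling_rate,
         trial_duration = trial_duration, rest_duration = rest_duration,
         class_band_centers = class_band_centers,
         class_channel_gains = as.matrix(class_channel_gains),
         subject_gain_sd = subject_gain_sd, noise_sd = noise_sd,
         amplification = amplification,
         n_force_levels = as.integer(n_force_levels),
         seed = as.integer(seed)),
    class = "emg_sim_spec"
  )
  validate_emg_sim_spec(spec)
  spec
}

validate_emg_sim_spec <- function(spec) {
  check_that(spec$n_classes >= 2, "invalid spec: n_classes must be >= 2")
  check_that(spec$n_subjects >= 1, "invalid spec: n_subjects must be >= 1")
  check_that(spec$n_channels >= 1, "invalid spec: n_channels must be >= 1")
  check_that(spec$n_repetitions >= 1,
             "invalid spec: n_repetitions must be >= 1")
  check_that(length(spec$class_band_centers) == spec$n_classes,
             "invalid spec: class_band_centers must have one entry per class")
  check_that(spec$sampling_rate > 2 * max(spec$class_band_centers),
             "invalid spec: sampling_rate must exceed twice the highest class band centre")
  check_that(all(dim(spec$class_channel_gains) ==
                   c(spec$n_classes, spec$n_channels)),
             "invalid spec: class_channel_gains must be n_classes x n_channels")
  check_that(all(spec$class_channel_gains >= 0),
             "invalid spec: class_channel_gains must be non-negative")
  check_that(spec$trial_duration > 0 && spec$rest_duration > 0,
             "invalid spec: durations must be positive")
  invisible(spec)
}

## band-emphasised white noise: 2nd-order Butterworth band-pass around f0
band_noise <- function(n, fs, f0, rel_bw = 0.2) {
  lo <- max(f0 * (1 - rel_bw / 2), 1) / (fs / 2)
  hi <- min(f0 * (1 + rel_bw / 2), fs / 2 - 1) / (fs / 2)
  bf <- signal::butter(2, c(lo, hi), type = "pass")
  x <- signal::filter(bf, stats::rnorm(n))
  as.numeric(x - mean(x))
}

#' Simulate a labeled surface-EMG dataset
#'
#' Generates one trial per (subject, class, repetition). Active segments are
#' zero-mean band-emphasised stochastic signal per channel — white noise
#' shaped around the class's band centre, scaled by the class-channel gain
#' matrix and a subject-level multiplicative gain, plus additive white
#' noise, all multiplied by the amplifier gain. Rest segments contain
#' amplified noise only. Identical spec (including its seed) always yields
#' an identical dataset.
#'
#' @param spec an [emg_sim_spec()].
#' @return a `labeled_signal_set`: list with `trials` (each holding a
#'   channels x samples `signal` matrix, `subject`, `class`, `repetition`,
#'   `force`, `active_samples`, `trial_id`) plus `sampling_rate`, `classes`,
#'   and the generating `spec`.
#' @export
simulate_emg_dataset <- function(spec) {
  validate_emg_sim_spec(spec)
  set.seed(spec$seed)
  fs <- spec$sampling_rate
  n_act <- round(spec$trial_duration * fs)
  n_rest <- round(spec$rest_duration * fs)
  force_scales <- if (spec$n_force_levels > 1) {
    seq(0.5, 1.5, length.out = spec$n_force_levels)
  } else 1
  subj_gain <- exp(stats::rnorm(spec$n_subjects, 0, spec$subject_gain_sd))
  trials <- list()
  id <- 0L
  for (s in seq_len(spec$n_subjects)) {
    for (cl in seq_len(spec$n_classes)) {
      for (r in seq_len(spec$n_repetitions)) {
        id <- id + 1L
        force <- ((r - 1L) %% spec$n_force_levels) + 1L
        sig <- matrix(0, spec$n_channels, n_act + n_rest)
        for (ch in seq_len(spec$n_channels)) {
          g <- spec$class_channel_gains[cl, ch] * subj_gain[s] *
            force_scales[force]
          active <- g * band_noise(n_act, fs, spec$class_band_centers[cl]) +
            stats::rnorm(n_act, 0, spec$noise_sd)
          rest <- stats::rnorm(n_rest, 0, spec$noise_sd)
          sig[ch, ] <- spec$amplification * c(active, rest)
        }
        trials[[id]] <- list(signal = sig, subject = s, class = cl,
                             repetition = r, force = force,
                             active_samples = n_act, trial_id = id)
      }
    }
  }
  structure(list(trials = trials, sampling_rate = fs,
                 classes = seq_len(spec$n_classes), spec = spec),
            class = "labeled_signal_set")
}

#' @export
print.labeled_signal_set <- function(x, ...) {
  n <- length(x$trials)
  subj <- unique(vapply(x$trials, `[[`, 0, "subject"))
  cat(sprintf(
    "Labeled signal set: %d trials, %d subjects, %d classes, %d channels @ %g Hz\n",
    n, length(subj), length(x$classes),
    if (n) nrow(x$trials[[1]]$signal) else 0, x$sampling_rate))
  invisible(x)
}

#' Generate a toy multiclass feature table
#'
#' Gaussian blobs (unit within-class sd) whose class means sit
#' `separation` apart along distinct coordinate directions, with optional
#' integer-coded columns held constant within class. Labels are balanced and
#' rows carry synthetic subject ids (round-robin) so the cross-validation
#' protocol can be exercised on toy data.
#'
#' @param n_per_class rows per class.
#' @param n_classes number of classes (>= 2).
#' @param n_features number of feature columns.
#' @param separation distance between class means (0 = indistinguishable
#'   classes).
#' @param discrete_cols integer indices of columns to make discrete
#'   (value = class index, constant within class).
#' @param n_subjects synthetic subjects to spread rows over (default 1).
#' @param seed integer seed.
#' @return a `feature_table`.
#' @export
make_toy_multiclass <- function(n_per_class, n_classes, n_features,
                                separation, discrete_cols = integer(0),
                                n_subjects = 1, seed = 1L) {
  check_that(n_classes >= 2, "n_classes must be >= 2")
  check_that(n_per_class >= 1, "n_per_class must be >= 1")
  check_that(all(discrete_cols %in% seq_len(n_features)),
             "discrete_cols must be a subset of the feature columns")
  set.seed(seed)
  cont <- setdiff(seq_len(n_features), discrete_cols)
  n <- n_per_class * n_classes
  x <- matrix(stats::rnorm(n * n_features), n, n_features)
  y <- rep(seq_len(n_classes), each = n_per_class)
  for (cl in seq_len(n_classes)) {
    rows <- which(y == cl)
    if (length(cont)) {
      dir_col <- cont[((cl - 1L) %% length(cont)) + 1L]
      x[rows, dir_col] <- x[rows, dir_col] + separation * cl
    }
    for (j in discrete_cols) x[rows, j] <- cl
  }
  discrete <- seq_len(n_features) %in% discrete_cols
  subject <- rep_len(seq_len(n_subjects), n)
  feature_table(x, paste0("c", y), discrete,
                subject = subject, trial_id = seq_len(n))
}
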