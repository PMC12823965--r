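#' Synthetic EEG configuration
#'
#' Describes a two-condition (rest vs task) multichannel EEG generator:
#' 1/f background (spectrally shaped white noise) plus narrowband-filtered
#' noise oscillators in the theta (4-7 Hz), alpha (8-12 Hz) and beta
#' (13-30 Hz) bands, with per-subject log-normal band gains. Under the
#' task condition, frontal-lobe channels get their theta amplitude
#' multiplied by `frontal_theta_gain`, all channels get alpha multiplied
#' by `alpha_suppression`, and broadband noise is mixed in with RMS
#' `irregularity_delta` times the background RMS (more irregular signal,
#' higher entropy). Everything is deterministic given the seed.
#'
#' @param montage_id `"mat19"` (19 channels, 500 Hz) or `"stew14"`
#'   (14 channels, 128 Hz); the sampling rate is fixed by the montage.
#' @param rest_duration_s,task_duration_s recording durations in seconds.
#' @param n_subjects number of subjects.
#' @param background list with `exponent` (1/f power-law exponent) and
#'   `amplitude` (background RMS, microvolts).
#' @param bands named list of `list(lo, hi, amplitude)` oscillator bands.
#' @param frontal_theta_gain task-over-rest theta amplitude multiplier on
#'   frontal channels (1 = no effect).
#' @param alpha_suppression task alpha amplitude multiplier (<= 1
#'   suppresses; 1 = no effect).
#' @param irregularity_delta broadband-noise RMS mix added under task, as
#'   a fraction of the background RMS (0 = no effect).
#' @param inter_subject_sd SD of the log-normal per-subject band gains.
#' @param seed integer seed from which all randomness is derived.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(montage_id = c("stew14", "mat19"),
                         rest_duration_s = 40, task_duration_s = 40,
                         n_subjects = 20L,
                         background = list(exponent = 1, amplitude = 20),
                         bands = list(
                           theta = list(lo = 4, hi = 7, amplitude = 5),
                           alpha = list(lo = 8, hi = 12, amplitude = 10),
                           beta = list(lo = 13, hi = 30, amplitude = 3)),
                         frontal_theta_gain = 1,
                         alpha_suppression = 1,
                         irregularity_delta = 0,
                         inter_subject_sd = 0.2,
                         seed = 1L) {
  montage_id <- match.arg(montage_id)
  stopifnot(rest_duration_s > 0, task_duration_s > 0, n_subjects >= 1,
            frontal_theta_gain > 0, alpha_suppression > 0,
            irregularity_delta >= 0, inter_subject_sd >= 0)
  structure(list(montage_id = montage_id,
                 fs = if (montage_id == "mat19") 500 else 128,
                 rest_duration_s = rest_duration_s,
                 task_duration_s = task_duration_s,
                 n_subjects = as.integer(n_subjects),
                 background = background, bands = bands,
                 frontal_theta_gain = frontal_theta_gain,
                 alpha_suppression = alpha_suppression,
                 irregularity_delta = irregularity_delta,
                 inter_subject_sd = inter_subject_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Synthetic-data presets
#'
#' `"strong"`: the workload-effect benchmark -- frontal theta gain 2.5,
#' alpha suppression 0.7, irregularity mix 0.1, 20 subjects on the
#' 14-channel montage. `"null"`: identical generator with every effect
#' switched off (gain 1, suppression 1, mix 0), so task and rest are
#' exchangeable and any classifier should sit at chance.
#'
#' @param name `"strong"` or `"null"`.
#' @param seed integer seed.
#' @return a [synth_config()].
#' @export
synth_preset <- function(name = c("strong", "null"), seed = 1L) {
  name <- match.arg(name)
  if (name == "strong")
    synth_config(frontal_theta_gain = 2.5, alpha_suppression = 0.7,
                 irregularity_delta = 0.1, seed = seed)
  else
    synth_config(seed = seed)
}

# 1/f^exponent background: white noise spectrally shaped in the frequency
# domain, rescaled to the requested RMS.
one_over_f_noise <- function(n, fs, exponent, rms) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- 0:(n - 1)
  fr <- pmin(k, n - k) * fs / n   # two-sided frequency axis
  fr[1] <- fr[2]                  # keep the DC bin finite; mean removed below
  X <- X * fr^(-exponent / 2)
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  x <- x - mean(x)
  x * rms / stats::sd(x)
}

# Narrowband oscillator: band-pass filtered white noise at the given RMS.
band_oscillator <- function(n, fs, lo, hi, rms) {
  w <- stats::rnorm(n)
  flt <- signal::butter(4L, c(lo, hi) / (fs / 2), type = "pass")
  x <- filtfilt_padded(flt$b, flt$a, w)
  x * rms / stats::sd(x)
}

# Per-subject log-normal band gains, deterministic in (seed, subject).
subject_gains <- function(config, subject) {
  set.seed(derive_seed(config$seed, paste0("gains-", subject)))
  g <- exp(stats::rnorm(length(config$bands), 0, config$inter_subject_sd))
  stats::setNames(g, names(config$bands))
}

#' Generate one synthetic recording
#'
#' @param config a [synth_config()].
#' @param subject subject identifier (e.g. `"S01"`).
#' @param condition `"rest"` or `"task"`.
#' @return an [eeg_recording()]; bitwise reproducible given
#'   `(config$seed, subject, condition)`.
#' @export
generate_record <- function(config, subject, condition = c("rest", "task")) {
  condition <- match.arg(condition)
  montage <- build_montage(config$montage_id)
  channels <- montage$channels
  frontal <- montage$mapping$frontal
  dur <- if (condition == "task") config$task_duration_s else config$rest_duration_s
  n <- round(dur * config$fs)
  gains <- subject_gains(config, subject)
  set.seed(derive_seed(config$seed, paste0("rec-", subject, "-", condition)))
  data <- matrix(0, nrow = n, ncol = length(channels))
  for (j in seq_along(channels)) {
    x <- one_over_f_noise(n, config$fs, config$background$exponent,
                          config$background$amplitude)
    for (bn in names(config$bands)) {
      b <- config$bands[[bn]]
      amp <- b$amplitude * gains[[bn]]
      if (condition == "task") {
        if (bn == "theta" && channels[j] %in% frontal)
          amp <- amp * config$frontal_theta_gain
        if (bn == "alpha") amp <- amp * config$alpha_suppression
      }
      x <- x + band_oscillator(n, config$fs, b$lo, b$hi, amp)
    }
    if (condition == "task" && config$irregularity_delta > 0)
      x <- x + stats::rnorm(n, 0, config$irregularity_delta *
                              config$background$amplitude)
    data[, j] <- x
  }
  eeg_recording(data, config$fs, channels, condition, subject)
}

#' Generate a full labeled segment set
#'
#' One rest and one task recording per subject, preprocessed with the
#' montage's dataset preset (0.5-45 Hz band-pass for `mat19`; 1 Hz
#' high-pass plus common average reference for `stew14`) and sliced into
#' 4-s windows.
#'
#' @param config a [synth_config()].
#' @param window_s window length in seconds.
#' @param preprocess apply the montage's dataset preset before slicing.
#' @return list of `eeg_segment` objects carrying condition and
#'   subject-id metadata.
#' @export
generate_dataset <- function(config, window_s = 4, preprocess = TRUE) {
  preset <- if (config$montage_id == "mat19") "mat" else "stew"
  segs <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (cond in c("rest", "task")) {
      rec <- generate_record(config, sid, cond)
      if (preprocess) rec <- preprocess_recording(rec, preset)
      segs <- c(segs, segment_record(rec, window_s = window_s))
    }
  }
  segs
}
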