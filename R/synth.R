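#' Configuration for the synthetic dataset generator
#'
#' Emulates the structure of continuously annotated wearable affect
#' datasets: multiple subjects watch the same set of video stimuli while
#' two modalities of multi-rate physiological channels are recorded
#' (modality 1, autonomic-like: blood-volume-pulse 64 Hz, electrodermal
#' 4 Hz, temperature 4 Hz, heart-rate 1 Hz; modality 2, oculomotor-like:
#' three 10 Hz channels) together with a 20 Hz continuous valence-arousal
#' annotation on a 1-9 scale. Each stimulus carries a shared latent affect
#' trace; each subject's physiology follows that trace with an individual
#' gain and lag, so only stimulus-grouped fusion across subjects recovers
#' the shared component.
#'
#' Annotation traces are neutral-heavy (default 55% of 2 s segments sit in
#' the neutral band; see [generate_latent_trace()] for the level
#' geometry), echoing the imbalance that continuous annotation produces
#' when raters release the joystick between salient scenes.
#'
#' @param n_subjects number of subjects (default 20)
#' @param n_stimuli number of video stimuli (default 8)
#' @param trial_seconds trial duration in seconds (default 120)
#' @param snr shared-latent amplitude relative to unit channel noise
#'   (default 5; 0 gives pure-noise channels carrying no affect signal)
#' @param neutral_fraction probability a latent segment is neutral
#'   (default 0.55)
#' @param segment_seconds duration of a constant latent segment (default 2)
#' @param annotation_rate annotation rate in Hz (default 20)
#' @param gain_range per-subject physiological gain, uniform (default
#'   [0.5, 1.5])
#' @param lag_range per-subject physiology-vs-annotation lag in seconds,
#'   uniform (default [0, 0.3]; large lags shift a window's physiology
#'   into the neighboring annotation window and put a hard ceiling on
#'   label recoverability)
#' @param channels1,channels2 per-modality channel specs: data.frames with
#'   columns `name`, `rate`, `bandwidth` (smoothing window, s)
#' @param modality_delay extra fixed delay per modality in seconds
#' @param seed integer seed; the whole dataset is reproducible from it
#' @return a `synth_config` list
#' @export
synth_config <- function(n_subjects = 20, n_stimuli = 8, trial_seconds = 120,
                         snr = 5, neutral_fraction = 0.55, segment_seconds = 2,
                         annotation_rate = 20,
                         gain_range = c(0.5, 1.5), lag_range = c(0, 0.3),
                         channels1 = data.frame(
                           name = c("bvp", "eda", "temp", "hr"),
                           rate = c(64, 4, 4, 1),
                           bandwidth = 0.5),
                         channels2 = data.frame(
                           name = c("pupil", "sacc_amp", "sacc_vel"),
                           rate = c(10, 10, 10),
                           bandwidth = 0.25),
                         modality_delay = c(0.3, 0.1),
                         seed = 1) {
  stopifnot(n_subjects >= 1, n_stimuli >= 1, trial_seconds > 0, snr >= 0,
            neutral_fraction >= 0, neutral_fraction <= 1, segment_seconds > 0)
  structure(list(n_subjects = n_subjects, n_stimuli = n_stimuli,
                 trial_seconds = trial_seconds, snr = snr,
                 neutral_fraction = neutral_fraction,
                 segment_seconds = segment_seconds,
                 annotation_rate = annotation_rate,
                 gain_range = gain_range, lag_range = lag_range,
                 channels1 = channels1, channels2 = channels2,
                 modality_delay = modality_delay, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a stimulus-locked latent affect trace
#'
#' Piecewise-constant valence or arousal target at the annotation rate:
#' consecutive segments of `segment_seconds` are neutral with probability
#' `neutral_fraction`, otherwise high (uniform [6.8, 8.2]) or low (uniform
#' [1.8, 2.8]) with equal probability. Neutral segments sit at uniform
#' [5.2, 5.8]: inside the three-class neutral band [3, 6) but offset from
#' the exact scale midpoint, so that every instance label is determined by
#' its segment's level rather than by sub-resolution boundary effects --
#' the property that makes the generator usable as a parameter-recovery
#' oracle. The trace is smoothed by a 0.5 s moving average to mimic
#' joystick inertia and clamped to [1, 9].
#'
#' @param config a [synth_config()]
#' @param rng_seed integer seed for this trace
#' @return numeric trace of length `trial_seconds * annotation_rate`
#' @export
generate_latent_trace <- function(config, rng_seed) {
  set.seed(rng_seed)
  n_seg <- ceiling(config$trial_seconds / config$segment_seconds)
  per_seg <- round(config$segment_seconds * config$annotation_rate)
  lev <- vapply(seq_len(n_seg), function(i) {
    if (stats::runif(1) < config$neutral_fraction) return(stats::runif(1, 5.2, 5.8))
    if (stats::runif(1) < 0.5) stats::runif(1, 6.8, 8.2) else stats::runif(1, 1.8, 2.8)
  }, numeric(1))
  trace <- rep(lev, each = per_seg)[seq_len(config$trial_seconds * config$annotation_rate)]
  w <- max(1L, as.integer(round(0.5 * config$annotation_rate)))
  trace <- moving_average(trace, w)
  pmin(pmax(trace, 1), 9)
}

# centered moving average with edge shrinkage (window w samples)
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Generate one subject-trial's channel signals from latent traces
#'
#' Each channel is a fixed linear mix of the valence and arousal latents,
#' delayed by the subject's lag plus a modality-specific delay, smoothed
#' over the channel's bandwidth, standardized over the trial, scaled by
#' `snr` times the subject gain and a per-trial channel gain jitter, and
#' corrupted with unit-variance Gaussian noise plus a slow baseline drift
#' at the channel's own sampling rate. The drift (a 10 s moving average of
#' white noise, rescaled to `drift_sd`) emulates the baseline wander of
#' wearable sensors (electrodermal level shifts, temperature drift,
#' electrode contact changes): it makes the absolute signal level within a
#' trial ambiguous, so classifiers must rely on stimulus-locked structure
#' rather than raw amplitude alone. With `snr = 0` the channels carry no
#' affect signal.
#'
#' @param v_trace,a_trace latent traces at the annotation rate
#' @param chspec one row of a channel-spec data.frame (`name`, `rate`,
#'   `bandwidth`)
#' @param mix valence weight in [0, 1] for this channel (arousal gets
#'   `1 - mix`)
#' @param gain subject gain
#' @param lag_s total delay in seconds
#' @param config a [synth_config()]
#' @param drift_sd standard deviation of the baseline drift (default 1,
#'   the same scale as the white channel noise)
#' @return numeric signal of length `trial_seconds * rate`
#' @export
generate_channels <- function(v_trace, a_trace, chspec, mix, gain, lag_s, config,
                              drift_sd = 1) {
  n_out <- as.integer(round(config$trial_seconds * chspec$rate))
  t_out <- (seq_len(n_out) - 1) / chspec$rate
  t_ann <- (seq_along(v_trace) - 1) / config$annotation_rate
  clean_ann <- mix * v_trace + (1 - mix) * a_trace
  clean <- stats::approx(t_ann, clean_ann, xout = pmax(t_out - lag_s, 0), rule = 2)$y
  w <- max(1L, as.integer(round(chspec$bandwidth * chspec$rate)))
  clean <- moving_average(clean, w)
  s <- stats::sd(clean)
  if (s > 0) clean <- (clean - mean(clean)) / s else clean <- clean * 0
  trial_gain <- stats::runif(1, 0.8, 1.25)  # electrode placement / contact
  drift <- moving_average(stats::rnorm(n_out), max(2L, as.integer(10 * chspec$rate)))
  dsd <- stats::sd(drift)
  if (dsd > 0) drift <- drift / dsd * drift_sd else drift <- drift * 0
  config$snr * gain * trial_gain * clean + drift + stats::rnorm(n_out)
}

#' Generate a synthetic two-modality affect dataset
#'
#' Draws per-stimulus latent valence/arousal traces (shared by all
#' subjects), per-subject gains and lags, and per-channel modality signals,
#' assembling `n_subjects * n_stimuli` recordings plus a manifest. With
#' `out_dir` the dataset is also written in the long-CSV layout that
#' [read_dataset()] consumes.
#'
#' @param config a [synth_config()]
#' @param out_dir optional output directory for the CSV + manifest layout
#' @param overwrite overwrite an existing `out_dir` (default FALSE)
#' @return an `emofuse_dataset`: `recordings`, `manifest`, and
#'   `truth` (latent traces per stimulus)
#' @export
generate_dataset <- function(config, out_dir = NULL, overwrite = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  traces <- lapply(seq_len(config$n_stimuli), function(t) {
    list(valence = generate_latent_trace(config, derive_seed(config$seed, paste0("latent_v_", t))),
         arousal = generate_latent_trace(config, derive_seed(config$seed, paste0("latent_a_", t))))
  })

  set.seed(derive_seed(config$seed, "subjects"))
  gains <- stats::runif(config$n_subjects, config$gain_range[1], config$gain_range[2])
  lags <- stats::runif(config$n_subjects, config$lag_range[1], config$lag_range[2])

  set.seed(derive_seed(config$seed, "channel_mix"))
  mix1 <- stats::runif(nrow(config$channels1), 0.2, 0.8)
  mix2 <- stats::runif(nrow(config$channels2), 0.2, 0.8)

  recordings <- list()
  for (s in seq_len(config$n_subjects)) {
    for (t in seq_len(config$n_stimuli)) {
      set.seed(derive_seed(config$seed, sprintf("rec_%d_%d", s, t)))
      chans <- list()
      for (j in seq_len(nrow(config$channels1))) {
        chans[[length(chans) + 1]] <- list(
          name = config$channels1$name[j], modality = 1,
          rate = config$channels1$rate[j], filter = filter_spec("none"),
          values = generate_channels(traces[[t]]$valence, traces[[t]]$arousal,
                                     config$channels1[j, ], mix1[j], gains[s],
                                     lags[s] + config$modality_delay[1], config))
      }
      for (j in seq_len(nrow(config$channels2))) {
        chans[[length(chans) + 1]] <- list(
          name = config$channels2$name[j], modality = 2,
          rate = config$channels2$rate[j], filter = filter_spec("none"),
          values = generate_channels(traces[[t]]$valence, traces[[t]]$arousal,
                                     config$channels2[j, ], mix2[j], gains[s],
                                     lags[s] + config$modality_delay[2], config))
      }
      recordings[[length(recordings) + 1]] <- structure(list(
        subject_id = sprintf("s%02d", s), stimulus_id = sprintf("v%02d", t),
        channels = chans,
        annotation = list(rate = config$annotation_rate,
                          valence = traces[[t]]$valence,
                          arousal = traces[[t]]$arousal)),
        class = "emofuse_recording")
    }
  }

  manifest <- list(
    channels = c(
      stats::setNames(lapply(seq_len(nrow(config$channels1)), function(j)
        list(modality = 1, rate = config$channels1$rate[j], filter = "none")),
        config$channels1$name),
      stats::setNames(lapply(seq_len(nrow(config$channels2)), function(j)
        list(modality = 2, rate = config$channels2$rate[j], filter = "none")),
        config$channels2$name)),
    annotation = list(rate = config$annotation_rate, lo = 1, hi = 9),
    instance_seconds = 2,
    common_rate = 32)

  ds <- structure(list(recordings = recordings, manifest = manifest,
                       truth = traces, config = config),
                  class = "emofuse_dataset")
  if (!is.null(out_dir)) write_dataset(ds, out_dir, overwrite = overwrite)
  ds
}

#' @export
print.emofuse_dataset <- function(x, ...) {
  cat(sprintf("emofuse dataset: %d recordings (%d subjects x %d stimuli)\n",
              length(x$recordings),
              length(unique(vapply(x$recordings, `[[`, "", "subject_id"))),
              length(unique(vapply(x$recordings, `[[`, "", "stimulus_id")))))
  invisible(x)
}
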