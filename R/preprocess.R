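#' Min-max normalize a signal to [0, 1]
#'
#' `(S - min S) / (max S - min S)`, applied per subject, per stimulus
#' (trial), per channel. A constant signal (a dead sensor) returns all zeros
#' with a warning rather than erroring, so one flat channel does not abort a
#' whole subject.
#'
#' @param x numeric vector, length >= 2
#' @return numeric vector in [0, 1]
#' @export
minmax_normalize <- function(x) {
  if (length(x) < 2) stop_emofuse("preprocess", "minmax_normalize needs length >= 2")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warn_emofuse("preprocess", "constant signal: min == max, returning zeros")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Construct a channel filter specification
#'
#' Supported types: `"none"`, `"lowpass"` (Butterworth low-pass, e.g. 2 Hz
#' for electrodermal activity), `"butter_bandpass"` (4th-order Butterworth
#' band-pass, e.g. blood volume pulse), `"elliptic_bandpass"` (elliptic
#' band-pass, e.g. the slow [0.005, 0.1] Hz skin-temperature band; passband
#' ripple and stopband attenuation default to 0.5 dB / 40 dB).
#'
#' @param type one of `"none"`, `"lowpass"`, `"butter_bandpass"`,
#'   `"elliptic_bandpass"`
#' @param cutoff low-pass cutoff in Hz
#' @param lo,hi band edges in Hz
#' @param order filter order (default 4)
#' @param rp,rs elliptic passband ripple / stopband attenuation in dB
#' @return a `filter_spec` list
#' @export
filter_spec <- function(type = "none", cutoff = NULL, lo = NULL, hi = NULL,
                        order = 4, rp = 0.5, rs = 40) {
  type <- match.arg(type, c("none", "lowpass", "butter_bandpass", "elliptic_bandpass"))
  structure(list(type = type, cutoff = cutoff, lo = lo, hi = hi,
                 order = order, rp = rp, rs = rs),
            class = "filter_spec")
}

#' Zero-phase filter a channel
#'
#' Designs the named filter for the channel's sampling rate and applies it
#' forward-backward (`signal::filtfilt`), preserving length and phase. Band
#' edges at or above Nyquist are clipped to 0.99x Nyquist with a warning
#' (printed lab-rate bands such as [30, 200] Hz are not realizable at
#' wearable rates); if the band collapses the filter is skipped with a
#' warning. A low-pass cutoff at or above Nyquist is an error naming the
#' channel and rates.
#'
#' @param x numeric signal
#' @param rate sampling rate in Hz
#' @param spec a [filter_spec()]
#' @param channel channel name used in messages
#' @return filtered signal, same length as `x`
#' @export
filter_channel <- function(x, rate, spec, channel = "signal") {
  if (is.null(spec) || spec$type == "none") return(x)
  nyq <- rate / 2
  if (spec$type == "lowpass") {
    if (spec$cutoff >= nyq) {
      stop_emofuse("preprocess",
                   "low-pass cutoff %g Hz >= Nyquist %g Hz for channel '%s' at %g Hz",
                   spec$cutoff, nyq, channel, rate)
    }
    flt <- signal::butter(spec$order, spec$cutoff / nyq, type = "low")
    return(as.numeric(signal::filtfilt(flt, x)))
  }
  lo <- spec$lo
  hi <- spec$hi
  if (hi >= nyq) {
    hi2 <- 0.99 * nyq
    warn_emofuse("preprocess",
                 "band edge %g Hz clipped to %g Hz (Nyquist %g Hz) for channel '%s'",
                 hi, hi2, nyq, channel)
    hi <- hi2
  }
  if (lo >= hi) {
    warn_emofuse("preprocess",
                 "band [%g, %g] Hz collapsed at %g Hz sampling; skipping filter for '%s'",
                 spec$lo, spec$hi, rate, channel)
    return(x)
  }
  w <- c(lo, hi) / nyq
  flt <- switch(spec$type,
    butter_bandpass = signal::butter(spec$order, w, type = "pass"),
    elliptic_bandpass = signal::ellip(spec$order, Rp = spec$rp, Rs = spec$rs,
                                      W = w, type = "pass"))
  as.numeric(signal::filtfilt(flt, x))
}

#' Linearly resample a signal to a new rate
#'
#' Linear interpolation on the uniform grid of `rate_out`. By default the
#' output grid spans the original sample span (`(n-1)/rate_in` seconds, so a
#' two-sample 1 Hz signal upsampled to 4 Hz yields samples at 0, 0.25, ...,
#' 1 s). `n_out` forces a specific output length (used to align channels of
#' different rates onto one trial grid); points beyond the last input sample
#' hold its value.
#'
#' @param x numeric signal, length >= 2
#' @param rate_in,rate_out rates in Hz, both > 0
#' @param n_out optional forced output length
#' @return resampled signal
#' @export
resample_linear <- function(x, rate_in, rate_out, n_out = NULL) {
  if (length(x) < 2) stop_emofuse("preprocess", "resample_linear needs >= 2 samples")
  stopifnot(rate_in > 0, rate_out > 0)
  if (is.null(n_out) && rate_in == rate_out) return(x)
  t_in <- (seq_along(x) - 1) / rate_in
  if (is.null(n_out)) n_out <- floor(t_in[length(t_in)] * rate_out) + 1
  t_out <- (seq_len(n_out) - 1) / rate_out
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}

#' Decimate a signal by an integer factor
#'
#' Down-sampling from rate `f1` to `f2` keeps the last point of every
#' length-`M` block (`M = f1/f2`): `x_out[k] = x[k*M]`, `k = 1..floor(N/M)`.
#' This emulates an A/D converter sampling the underlying continuous signal
#' at the lower rate. Non-integer `M` is an error directing the caller to
#' [resample_linear()].
#'
#' @param x numeric signal
#' @param f1,f2 rates before/after down-sampling; `f1` divisible by `f2`
#' @return decimated signal of length `floor(length(x) * f2 / f1)`
#' @export
downsample_decimate <- function(x, f1, f2) {
  m <- f1 / f2
  if (abs(m - round(m)) > 1e-9) {
    stop_emofuse("preprocess",
                 "%g is not an integer multiple of %g; use resample_linear for non-integer ratios",
                 f1, f2)
  }
  m <- as.integer(round(m))
  k <- floor(length(x) / m)
  if (k == 0) return(numeric(0))
  x[seq_len(k) * m]
}

#' Segment aligned channel matrices into fixed-length instances
#'
#' Channels must already share the common rate. Instances are contiguous,
#' non-overlapping, start at trial onset; the trailing partial window is
#' discarded so every instance has exactly `L = round(instance_seconds *
#' common_rate)` samples.
#'
#' @param mat samples x channels numeric matrix on the common rate
#' @param instance_seconds window length in seconds
#' @param common_rate common sampling rate in Hz
#' @return list with `data` (n x L x C array) and `start_s` (window onsets);
#'   zero instances (with a warning) when the trial is shorter than one
#'   window
#' @export
segment_instances <- function(mat, instance_seconds, common_rate) {
  stopifnot(instance_seconds > 0, common_rate > 0)
  L <- as.integer(round(instance_seconds * common_rate))
  n_samp <- nrow(mat)
  n_inst <- floor(n_samp / L)
  if (n_inst == 0) {
    warn_emofuse("preprocess", "trial shorter than one instance (%d < %d samples)",
                 n_samp, L)
    return(list(data = array(0, dim = c(0, L, ncol(mat))), start_s = numeric(0)))
  }
  used <- mat[seq_len(n_inst * L), , drop = FALSE]
  # samples x channels -> instances x L x channels
  arr <- aperm(array(used, dim = c(L, n_inst, ncol(mat))), c(2, 1, 3))
  list(data = arr, start_s = (seq_len(n_inst) - 1) * instance_seconds)
}

#' Discretize continuous valence-arousal means into class labels
#'
#' Labels follow the standard 1-9 scale mapping: binary Low `[1,5)` / High
#' `[5,9]`; three-class Low `[1,3)` / Neutral `[3,6)` / High `[6,9]`;
#' four-quadrant HH/HL/LL/LH from the signs of `(v >= 5, a >= 5)`. Values
#' outside [1,9] are clamped with a warning.
#'
#' @param v_mean,a_mean per-instance mean valence and arousal on [1, 9]
#' @param scheme `"binary"`, `"three_class"` or `"four_quadrant"`
#' @param task for binary/three-class, which dimension to label
#'   (`"valence"` or `"arousal"`)
#' @return factor of per-instance classes
#' @export
discretize_labels <- function(v_mean, a_mean, scheme = c("binary", "three_class", "four_quadrant"),
                              task = c("valence", "arousal")) {
  scheme <- match.arg(scheme)
  task <- match.arg(task)
  clamp <- function(x) {
    if (any(x < 1 | x > 9, na.rm = TRUE)) {
      warn_emofuse("preprocess", "annotation values outside [1, 9] clamped")
      x <- pmin(pmax(x, 1), 9)
    }
    x
  }
  v <- clamp(v_mean)
  a <- clamp(a_mean)
  if (scheme == "four_quadrant") {
    lab <- ifelse(v >= 5,
                  ifelse(a >= 5, "HH", "HL"),
                  ifelse(a >= 5, "LH", "LL"))
    return(factor(lab, levels = c("HH", "HL", "LL", "LH")))
  }
  x <- if (task == "valence") v else a
  if (scheme == "binary") {
    factor(ifelse(x < 5, "low", "high"), levels = c("low", "high"))
  } else {
    factor(ifelse(x < 3, "low", ifelse(x < 6, "neutral", "high")),
           levels = c("low", "neutral", "high"))
  }
}

#' Per-instance mean annotation over half-open windows
#'
#' Averages all annotation samples whose timestamps fall in
#' `[start, start + instance_seconds)`; timestamps are seconds from trial
#' onset, sample k sits at `(k-1)/rate`.
#'
#' @param ann numeric annotation trace
#' @param rate annotation rate in Hz
#' @param start_s instance window onsets in seconds
#' @param instance_seconds window length
#' @return numeric vector of per-window means
#' @export
window_means <- function(ann, rate, start_s, instance_seconds) {
  t_ann <- (seq_along(ann) - 1) / rate
  vapply(start_s, function(s) {
    sel <- t_ann >= s & t_ann < s + instance_seconds
    if (!any(sel)) return(NA_real_)
    mean(ann[sel])
  }, numeric(1))
}

#' Preprocess a dataset of recordings into a two-modality instance set
#'
#' The full per-trial pipeline, applied independently to every recording
#' (so it never mixes information across subjects or trials): zero-phase
#' filter each channel per the manifest, linearly resample to the common
#' rate on a shared trial grid, min-max normalize per channel, segment into
#' fixed-length instances and average the annotation trace over each
#' window. Filtering precedes normalization so filter transients cannot
#' push values outside [0, 1].
#'
#' @param dataset an `emofuse_dataset` (see [generate_dataset()] /
#'   [read_dataset()])
#' @param instance_seconds instance window length in seconds (default 2)
#' @param common_rate common sampling rate in Hz (default taken from the
#'   manifest)
#' @param decimate_to optional lower rate: after resampling to
#'   `common_rate`, channels are decimated ([downsample_decimate()]) to
#'   this rate before normalization and segmentation, emulating sensors
#'   sampling at the lower rate
#' @return an `emofuse_instances` list: `m1`, `m2` (n x L x C_j arrays in
#'   [0,1]), `index` (data.frame: subject, stimulus, start_s, v_mean,
#'   a_mean), plus `instance_seconds`, `common_rate`, `L`
#' @export
preprocess_dataset <- function(dataset, instance_seconds = NULL, common_rate = NULL,
                               decimate_to = NULL) {
  man <- dataset$manifest
  instance_seconds <- instance_seconds %||% man$instance_seconds %||% 2
  common_rate <- common_rate %||% man$common_rate
  stopifnot(!is.null(common_rate))
  eff_rate <- decimate_to %||% common_rate
  L <- as.integer(round(instance_seconds * eff_rate))

  out1 <- list(); out2 <- list(); idx <- list()
  for (rec in dataset$recordings) {
    dur <- min(vapply(rec$channels, function(ch) length(ch$values) / ch$rate, numeric(1)))
    n_out <- floor(dur * common_rate)
    mats <- list(`1` = NULL, `2` = NULL)
    for (mod in c(1, 2)) {
      chs <- Filter(function(ch) ch$modality == mod, rec$channels)
      cols <- lapply(chs, function(ch) {
        x <- filter_channel(ch$values, ch$rate, ch$filter, ch$name)
        x <- resample_linear(x, ch$rate, common_rate, n_out = n_out)
        if (!is.null(decimate_to)) x <- downsample_decimate(x, common_rate, decimate_to)
        minmax_normalize(x)
      })
      mats[[as.character(mod)]] <- do.call(cbind, cols)
    }
    seg1 <- segment_instances(mats[["1"]], instance_seconds, eff_rate)
    seg2 <- segment_instances(mats[["2"]], instance_seconds, eff_rate)
    n_inst <- min(dim(seg1$data)[1], dim(seg2$data)[1])
    if (n_inst == 0) next
    keep <- seq_len(n_inst)
    v <- window_means(rec$annotation$valence, rec$annotation$rate,
                      seg1$start_s[keep], instance_seconds)
    a <- window_means(rec$annotation$arousal, rec$annotation$rate,
                      seg1$start_s[keep], instance_seconds)
    out1[[length(out1) + 1]] <- seg1$data[keep, , , drop = FALSE]
    out2[[length(out2) + 1]] <- seg2$data[keep, , , drop = FALSE]
    idx[[length(idx) + 1]] <- data.frame(
      subject = rec$subject_id, stimulus = rec$stimulus_id,
      start_s = seg1$start_s[keep], v_mean = v, a_mean = a,
      stringsAsFactors = FALSE)
  }
  if (!length(out1)) stop_emofuse("preprocess", "no instances produced from dataset")
  bind_arr <- function(lst) {
    d <- dim(lst[[1]])
    arr <- array(0, dim = c(sum(vapply(lst, function(x) dim(x)[1], numeric(1))), d[2], d[3]))
    at <- 0
    for (x in lst) {
      n <- dim(x)[1]
      if (n) arr[at + seq_len(n), , ] <- x
      at <- at + n
    }
    arr
  }
  structure(list(m1 = bind_arr(out1), m2 = bind_arr(out2),
                 index = do.call(rbind, idx),
                 instance_seconds = instance_seconds,
                 common_rate = eff_rate, L = L),
            class = "emofuse_instances")
}

#' @export
print.emofuse_instances <- function(x, ...) {
  cat(sprintf("emofuse instance set: %d instances, L = %d (%g s @ %g Hz), C1 = %d, C2 = %d\n",
              nrow(x$index), x$L, x$instance_seconds, x$common_rate,
              dim(x$m1)[3], dim(x$m2)[3]))
  invisible(x)
}
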