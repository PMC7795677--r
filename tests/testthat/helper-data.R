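# Small synthetic fixtures shared across tests; everything is generated in
# code so the suite needs no stored data.

tiny_config <- function(seed = 11, ...) {
  synth_config(n_subjects = 3, n_stimuli = 2, trial_seconds = 24, seed = seed, ...)
}

tiny_instances <- function(seed = 11, ...) {
  preprocess_dataset(generate_dataset(tiny_config(seed = seed, ...)))
}

small_config <- function(seed = 11, ...) {
  synth_config(n_subjects = 5, n_stimuli = 3, trial_seconds = 48, seed = seed, ...)
}

# fast pipeline settings for protocol-level tests
fast_pipeline <- function(...) {
  pipeline_config(ae_max_epochs = 30L, bls = bls_config(N3 = 100L), ...)
}

# sine wave helper for filter tests
sine_wave <- function(freq, rate, seconds) {
  sin(2 * pi * freq * (seq_len(rate * seconds) - 1) / rate)
}

# mid-band amplitude of a signal relative to a reference sine
amplitude_ratio <- function(filtered, original) {
  n <- length(original)
  core <- seq(floor(n / 4), ceiling(3 * n / 4))  # avoid edge transients
  max(abs(filtered[core])) / max(abs(original[core]))
}
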