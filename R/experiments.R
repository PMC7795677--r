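#' Ablation study over pipeline components
#'
#' Evaluates four pipeline variants under the configured protocol:
#' raw instances into the classifier (`bls`), autoencoder codes into the
#' classifier (`ifl_bls`), per-stimulus CCA on raw instances (`cfe_bls`),
#' and the full pipeline (`ifl_cfe_bls`).
#'
#' @param data an `emofuse_dataset` or `emofuse_instances`
#' @param config a [pipeline_config()]; its `variant` field is overridden
#' @param variants variants to run (default all four)
#' @return data.frame with one row per variant x task: accuracy and
#'   weighted F1
#' @export
run_ablation <- function(data, config = pipeline_config(),
                         variants = c("bls", "ifl_bls", "cfe_bls", "ifl_cfe_bls")) {
  inst <- as_instances(data, config)
  rows <- list()
  for (v in variants) {
    cfg <- config
    cfg$variant <- v
    rep <- run_pipeline(inst, cfg)
    for (task in names(rep$tasks)) {
      rows[[length(rows) + 1]] <- data.frame(
        variant = v, task = task,
        accuracy = rep$tasks[[task]]$mean_accuracy,
        weighted_f1 = rep$tasks[[task]]$mean_weighted_f1,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Sweep the instance segmentation length
#'
#' Re-runs the full pipeline per requested length, re-deriving the
#' dependent hyperparameters (`omega = 2L`, `kernel = L/4`, `K = L/2`)
#' from each length. Lengths exceeding the shortest trial are skipped with
#' a warning.
#'
#' @param dataset an `emofuse_dataset`
#' @param lengths_s instance lengths in seconds
#' @param config a [pipeline_config()]
#' @return data.frame: one row per run length with per-task weighted F1
#'   and accuracy
#' @export
sweep_instance_length <- function(dataset, lengths_s, config = pipeline_config()) {
  stopifnot(inherits(dataset, "emofuse_dataset"), all(lengths_s > 0))
  shortest <- min(vapply(dataset$recordings, function(rec) {
    min(vapply(rec$channels, function(ch) length(ch$values) / ch$rate, numeric(1)))
  }, numeric(1)))
  rows <- list()
  for (len in lengths_s) {
    if (len > shortest) {
      warn_emofuse("sweep", "length %g s exceeds shortest trial (%g s); skipped", len, shortest)
      next
    }
    cfg <- pipeline_config(
      instance_seconds = len, common_rate = config$common_rate,
      scheme = config$scheme, protocol = config$protocol,
      variant = config$variant, cca_reg = config$cca_reg, bls = config$bls,
      ae_max_epochs = config$ae_max_epochs, ae_patience = config$ae_patience,
      ae_batch = config$ae_batch, seed = config$seed)
    rep <- run_pipeline(dataset, cfg)
    for (task in names(rep$tasks)) {
      rows[[length(rows) + 1]] <- data.frame(
        length_s = len, task = task,
        accuracy = rep$tasks[[task]]$mean_accuracy,
        weighted_f1 = rep$tasks[[task]]$mean_weighted_f1,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Sweep the sampling rate by decimation
#'
#' Signals are brought to the base common rate, then decimated (last point
#' of each block) to each requested rate before segmentation, emulating
#' sensors sampling at the lower rate; the full pipeline is re-run per
#' rate with hyperparameters re-derived from the resulting instance
#' length. Rates must divide the base rate.
#'
#' @param dataset an `emofuse_dataset`
#' @param rates target rates in Hz, each dividing `config$common_rate`
#' @param config a [pipeline_config()]
#' @return data.frame: one row per rate x task with accuracy and weighted
#'   F1
#' @export
sweep_sampling_rate <- function(dataset, rates, config = pipeline_config()) {
  stopifnot(inherits(dataset, "emofuse_dataset"))
  base <- config$common_rate
  bad <- rates[abs(base / rates - round(base / rates)) > 1e-9]
  if (length(bad)) {
    stop_emofuse("sweep", "rate(s) %s do not divide the base rate %g Hz; valid rates: %s",
                 paste(bad, collapse = ", "), base,
                 paste(Filter(function(r) base %% r == 0, seq_len(base)), collapse = ", "))
  }
  rows <- list()
  for (r in rates) {
    inst <- preprocess_dataset(dataset, instance_seconds = config$instance_seconds,
                               common_rate = base, decimate_to = r)
    cfg <- pipeline_config(
      instance_seconds = config$instance_seconds, common_rate = r,
      scheme = config$scheme, protocol = config$protocol,
      variant = config$variant, cca_reg = config$cca_reg, bls = config$bls,
      ae_max_epochs = config$ae_max_epochs, ae_patience = config$ae_patience,
      ae_batch = config$ae_batch, seed = config$seed)
    rep <- run_pipeline(inst, cfg)
    for (task in names(rep$tasks)) {
      rows[[length(rows) + 1]] <- data.frame(
        rate_hz = r, task = task, L = inst$L,
        accuracy = rep$tasks[[task]]$mean_accuracy,
        weighted_f1 = rep$tasks[[task]]$mean_weighted_f1,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
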