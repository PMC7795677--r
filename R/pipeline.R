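#' Derive instance-level hyperparameters from segmentation settings
#'
#' The standard rules tie everything to the instance length in samples
#' `L = instance_seconds * common_rate`: latent dimension `omega = 2L`,
#' convolution kernel `c = L/4`, canonical pairs `K = L/2` (2 s at 50 Hz
#' gives L = 100, omega = 200, c = 25, K = 50; 2 s at 32 Hz gives L = 64,
#' omega = 128, c = 16, K = 32).
#'
#' @param instance_seconds instance length in seconds
#' @param common_rate common sampling rate in Hz
#' @return list with `L`, `omega`, `kernel`, `K`
#' @export
derive_hyper <- function(instance_seconds, common_rate) {
  L <- as.integer(round(instance_seconds * common_rate))
  list(L = L, omega = 2L * L,
       kernel = max(1L, as.integer(round(L / 4))),
       K = max(1L, as.integer(round(L / 2))))
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline. Hyperparameters
#' omega, kernel and K are re-derived from `instance_seconds *
#' common_rate` via [derive_hyper()] unless given explicitly.
#'
#' @param instance_seconds instance window in seconds (default 2)
#' @param common_rate common sampling rate in Hz (default 32)
#' @param scheme label scheme: `"binary"`, `"three_class"`,
#'   `"four_quadrant"`
#' @param protocol `"losocv"` (subject-independent) or `"sd_10fold"`
#'   (subject-dependent)
#' @param variant pipeline variant, mainly for ablation: `"ifl_cfe_bls"`
#'   (full), `"cfe_bls"`, `"ifl_bls"`, `"bls"`
#' @param K canonical pairs per stimulus (default derived)
#' @param cca_reg identity regularization multiplier of the CCA
#' @param bls a [bls_config()] (its seed is re-derived per fold)
#' @param ae_max_epochs,ae_patience,ae_batch autoencoder training settings
#' @param seed master seed fanning out to all random components
#' @return an `emofuse_config` list
#' @export
pipeline_config <- function(instance_seconds = 2, common_rate = 32,
                            scheme = c("binary", "three_class", "four_quadrant"),
                            protocol = c("losocv", "sd_10fold"),
                            variant = c("ifl_cfe_bls", "cfe_bls", "ifl_bls", "bls"),
                            K = NULL, cca_reg = 1, bls = bls_config(),
                            ae_max_epochs = 30L, ae_patience = 5L,
                            ae_batch = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  protocol <- match.arg(protocol)
  variant <- match.arg(variant)
  hy <- derive_hyper(instance_seconds, common_rate)
  structure(list(instance_seconds = instance_seconds, common_rate = common_rate,
                 scheme = scheme, protocol = protocol, variant = variant,
                 L = hy$L, omega = hy$omega, kernel = hy$kernel,
                 K = K %||% hy$K, cca_reg = cca_reg, bls = bls,
                 ae_max_epochs = as.integer(ae_max_epochs),
                 ae_patience = as.integer(ae_patience),
                 ae_batch = if (is.null(ae_batch)) NULL else as.integer(ae_batch),
                 seed = as.integer(seed)),
            class = "emofuse_config")
}

# classification tasks implied by the label scheme
scheme_tasks <- function(scheme) {
  if (scheme == "four_quadrant") "quadrant" else c("valence", "arousal")
}

# per-task label factors for an instance index
instance_labels <- function(index, scheme) {
  if (scheme == "four_quadrant") {
    list(quadrant = discretize_labels(index$v_mean, index$a_mean, "four_quadrant"))
  } else {
    list(valence = discretize_labels(index$v_mean, index$a_mean, scheme, "valence"),
         arousal = discretize_labels(index$v_mean, index$a_mean, scheme, "arousal"))
  }
}

flatten_modality <- function(arr) {
  matrix(arr, dim(arr)[1], dim(arr)[2] * dim(arr)[3])
}

# train all stages on train_idx, predict test_idx; no test instance enters
# any fitting step (autoencoder, CCA, z-score, BLS)
fit_predict_fold <- function(inst, config, train_idx, test_idx, fold_label) {
  n <- nrow(inst$index)
  if (is.logical(train_idx)) train_idx <- which(train_idx)
  if (is.logical(test_idx)) test_idx <- which(test_idx)
  stopifnot(!length(intersect(train_idx, test_idx)))
  variant <- config$variant

  use_ifl <- variant %in% c("ifl_cfe_bls", "ifl_bls")
  use_cfe <- variant %in% c("ifl_cfe_bls", "cfe_bls")

  if (use_ifl) {
    codes <- list()
    for (mod in c(1, 2)) {
      X <- inst[[paste0("m", mod)]]
      sp <- ae_spec(L = inst$L, C = dim(X)[3], latent_dim = config$omega,
                    kernel = config$kernel, max_epochs = config$ae_max_epochs,
                    patience = config$ae_patience, batch_size = config$ae_batch,
                    seed = derive_seed(config$seed, paste0(fold_label, "_ae_m", mod)))
      model <- ae_build(sp)
      model <- ae_train(model, X[train_idx, , , drop = FALSE],
                        subjects = inst$index$subject[train_idx])
      codes[[mod]] <- ae_encode(model, X)
    }
    phi1 <- codes[[1]]; phi2 <- codes[[2]]
  } else {
    phi1 <- flatten_modality(inst$m1)
    phi2 <- flatten_modality(inst$m2)
  }

  if (use_cfe) {
    ft <- fit_transform_by_stimulus(phi1, phi2, inst$index$stimulus,
                                    K = config$K, train_idx = train_idx,
                                    test_idx = test_idx, reg = config$cca_reg)
    feats <- ft$features
  } else {
    feats <- cbind(phi1, phi2)
  }

  labels <- instance_labels(inst$index, config$scheme)
  cfg_bls <- config$bls
  cfg_bls$seed <- derive_seed(config$seed, paste0(fold_label, "_bls"))
  model <- bls_fit(feats[train_idx, , drop = FALSE],
                   lapply(labels, function(y) y[train_idx]), cfg_bls)
  preds <- bls_predict(model, feats[test_idx, , drop = FALSE])
  lapply(stats::setNames(names(labels), names(labels)), function(task) {
    list(truth = labels[[task]][test_idx], pred = preds[[task]]$class,
         classes = levels(labels[[task]]))
  })
}

fold_metrics <- function(fold_out) {
  lapply(fold_out, function(x) {
    cm <- confusion_matrix(x$truth, x$pred, x$classes)
    list(confusion = cm, accuracy = accuracy(cm), weighted_f1 = weighted_f1(cm),
         n_test = sum(cm))
  })
}

assemble_report <- function(per_fold, fold_ids, config, protocol) {
  tasks <- names(per_fold[[1]])
  task_reports <- lapply(stats::setNames(tasks, tasks), function(task) {
    folds <- data.frame(
      fold = fold_ids,
      accuracy = vapply(per_fold, function(f) f[[task]]$accuracy, numeric(1)),
      weighted_f1 = vapply(per_fold, function(f) f[[task]]$weighted_f1, numeric(1)),
      n_test = vapply(per_fold, function(f) f[[task]]$n_test, numeric(1)),
      stringsAsFactors = FALSE)
    conf <- Reduce(`+`, lapply(per_fold, function(f) f[[task]]$confusion))
    list(mean_accuracy = mean(folds$accuracy, na.rm = TRUE),
         mean_weighted_f1 = mean(folds$weighted_f1, na.rm = TRUE),
         folds = folds, confusion = conf)
  })
  structure(list(protocol = protocol, scheme = config$scheme,
                 variant = config$variant, tasks = task_reports,
                 config = config),
            class = "emofuse_report")
}

#' @export
print.emofuse_report <- function(x, ...) {
  cat(sprintf("emofuse %s report (%s, %s)\n", x$protocol, x$scheme, x$variant))
  for (task in names(x$tasks)) {
    t <- x$tasks[[task]]
    cat(sprintf("  %-8s accuracy %.4f  weighted F1 %.4f  (%d folds)\n",
                task, t$mean_accuracy, t$mean_weighted_f1, nrow(t$folds)))
  }
  invisible(x)
}

as_instances <- function(x, config) {
  if (inherits(x, "emofuse_instances")) return(x)
  if (inherits(x, "emofuse_dataset")) {
    return(preprocess_dataset(x, instance_seconds = config$instance_seconds,
                              common_rate = config$common_rate))
  }
  stop_emofuse("pipeline", "expected an emofuse_dataset or emofuse_instances object")
}

#' Leave-one-subject-out cross-validation
#'
#' Subject-independent evaluation: for each subject, every stage
#' (autoencoders, per-stimulus CCA, z-score, BLS) is fit on the remaining
#' subjects only and tested on the held-out subject. Reported means are
#' arithmetic means over subjects.
#'
#' @param data an `emofuse_dataset` or preprocessed `emofuse_instances`
#' @param config a [pipeline_config()]
#' @return an `emofuse_report`
#' @export
run_losocv <- function(data, config = pipeline_config()) {
  inst <- as_instances(data, config)
  subjects <- unique(inst$index$subject)
  if (length(subjects) < 2) stop_emofuse("protocol", "LOSOCV needs at least 2 subjects")
  per_fold <- lapply(subjects, function(s) {
    test_idx <- which(inst$index$subject == s)
    train_idx <- which(inst$index$subject != s)
    fold_metrics(fit_predict_fold(inst, config, train_idx, test_idx,
                                  fold_label = paste0("loso_", s)))
  })
  assemble_report(per_fold, subjects, config, "losocv")
}

#' Subject-dependent 10-fold cross-validation
#'
#' Each subject's instances are split into 10 seeded-random folds; the
#' pipeline is refit on 9 folds of that subject's own data and tested on
#' the remaining fold. Metrics are averaged per fold, then per subject,
#' then over subjects. Subjects with fewer than `n_folds` instances are
#' excluded with a warning.
#'
#' @param data an `emofuse_dataset` or `emofuse_instances`
#' @param config a [pipeline_config()]
#' @param n_folds folds per subject (default 10)
#' @return an `emofuse_report`
#' @export
run_sd_10fold <- function(data, config = pipeline_config(), n_folds = 10L) {
  inst <- as_instances(data, config)
  subjects <- unique(inst$index$subject)
  keep <- vapply(subjects, function(s) sum(inst$index$subject == s) >= n_folds, logical(1))
  if (any(!keep)) {
    warn_emofuse("protocol", "excluding %d subject(s) with fewer than %d instances",
                 sum(!keep), n_folds)
  }
  subjects <- subjects[keep]
  if (!length(subjects)) stop_emofuse("protocol", "no subject has enough instances")
  per_subject <- lapply(subjects, function(s) {
    rows <- which(inst$index$subject == s)
    set.seed(derive_seed(config$seed, paste0("sdfold_", s)))
    fold_of <- sample(rep(seq_len(n_folds), length.out = length(rows)))
    sub_inst <- list(m1 = inst$m1[rows, , , drop = FALSE],
                     m2 = inst$m2[rows, , , drop = FALSE],
                     index = inst$index[rows, , drop = FALSE],
                     instance_seconds = inst$instance_seconds,
                     common_rate = inst$common_rate, L = inst$L)
    class(sub_inst) <- "emofuse_instances"
    folds <- lapply(seq_len(n_folds), function(k) {
      fold_metrics(fit_predict_fold(sub_inst, config,
                                    train_idx = which(fold_of != k),
                                    test_idx = which(fold_of == k),
                                    fold_label = sprintf("sd_%s_f%d", s, k)))
    })
    # average this subject's folds
    tasks <- names(folds[[1]])
    lapply(stats::setNames(tasks, tasks), function(task) {
      list(confusion = Reduce(`+`, lapply(folds, function(f) f[[task]]$confusion)),
           accuracy = mean(vapply(folds, function(f) f[[task]]$accuracy, numeric(1)), na.rm = TRUE),
           weighted_f1 = mean(vapply(folds, function(f) f[[task]]$weighted_f1, numeric(1)), na.rm = TRUE),
           n_test = sum(vapply(folds, function(f) f[[task]]$n_test, numeric(1))))
    })
  })
  assemble_report(per_subject, subjects, config, "sd_10fold")
}

#' Run the configured end-to-end pipeline
#'
#' Preprocesses, fits and evaluates under the configured protocol. Two
#' runs with the same data, config and seed produce identical reports.
#'
#' @param data an `emofuse_dataset`, `emofuse_instances`, or a path to a
#'   dataset directory (see [read_dataset()])
#' @param config a [pipeline_config()]
#' @return an `emofuse_report`
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  if (is.character(data)) {
    if (!dir.exists(data)) stop_emofuse("pipeline", "dataset directory not found: %s", data)
    data <- read_dataset(data)
  }
  switch(config$protocol,
         losocv = run_losocv(data, config),
         sd_10fold = run_sd_10fold(data, config))
}
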