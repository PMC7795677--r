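#' Write a dataset to the long-CSV directory layout
#'
#' One CSV per subject-trial (`<subject>_<stimulus>.csv`, columns `time_s`,
#' `channel`, `value`; annotation traces appear as channels `valence` and
#' `arousal`) plus a `manifest.yaml` describing channel-to-modality
#' mapping, sampling rates, filter specs, annotation rate/scale and default
#' segmentation parameters.
#'
#' @param dataset an `emofuse_dataset`
#' @param dir output directory
#' @param overwrite overwrite an existing directory (default FALSE)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(dataset, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    stop_emofuse("io", "output directory '%s' exists; use overwrite = TRUE", dir)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in dataset$recordings) {
    parts <- lapply(rec$channels, function(ch) {
      data.table::data.table(
        time_s = round((seq_along(ch$values) - 1) / ch$rate, 6),
        channel = ch$name, value = round(ch$values, 8))
    })
    ann <- rec$annotation
    t_ann <- round((seq_along(ann$valence) - 1) / ann$rate, 6)
    parts[[length(parts) + 1]] <- data.table::data.table(
      time_s = t_ann, channel = "valence", value = round(ann$valence, 8))
    parts[[length(parts) + 1]] <- data.table::data.table(
      time_s = t_ann, channel = "arousal", value = round(ann$arousal, 8))
    dt <- data.table::rbindlist(parts)
    data.table::fwrite(dt, file.path(dir, sprintf("%s_%s.csv",
                                                  rec$subject_id, rec$stimulus_id)))
  }
  yaml::write_yaml(dataset$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a dataset from the long-CSV directory layout
#'
#' Inverse of [write_dataset()]: reads `manifest.yaml` and every
#' `<subject>_<stimulus>.csv`, reconstructing `emofuse_recording` objects
#' with channel modality, rate and filter taken from the manifest.
#'
#' @param dir dataset directory containing `manifest.yaml`
#' @return an `emofuse_dataset`
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.yaml")
  if (!file.exists(man_path)) stop_emofuse("io", "manifest not found: %s", man_path)
  manifest <- yaml::read_yaml(man_path)
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  parse_filter <- function(f) {
    if (is.character(f)) return(filter_spec(f))
    do.call(filter_spec, f)
  }
  recordings <- lapply(files, function(f) {
    id <- strsplit(sub("\\.csv$", "", basename(f)), "_")[[1]]
    dt <- data.table::fread(f)
    chans <- list()
    for (nm in names(manifest$channels)) {
      spec <- manifest$channels[[nm]]
      chans[[length(chans) + 1]] <- list(
        name = nm, modality = spec$modality, rate = spec$rate,
        filter = parse_filter(spec$filter),
        values = dt[dt$channel == nm, ]$value)
    }
    structure(list(
      subject_id = id[1], stimulus_id = paste(id[-1], collapse = "_"),
      channels = chans,
      annotation = list(rate = manifest$annotation$rate,
                        valence = dt[dt$channel == "valence", ]$value,
                        arousal = dt[dt$channel == "arousal", ]$value)),
      class = "emofuse_recording")
  })
  structure(list(recordings = recordings, manifest = manifest),
            class = "emofuse_dataset")
}
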