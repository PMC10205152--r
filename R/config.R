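# Pipeline configuration and artifact provenance.

#' Default pipeline configuration
#'
#' Bundles the analysis constants shared across stages: predictor rate
#' 1000 Hz, EEG rate 100 Hz, lag window -100..500 ms with a 50 ms Hamming
#' basis, five CV folds, a 1-15 Hz analysis band, and a 61 s epoch cap.
#'
#' @param ... Overrides for any field.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    predictor_fs = 1000,
    eeg_fs = 100,
    lag_start = -0.1,
    lag_end = 0.5,
    basis_window = 0.05,
    n_folds = 5,
    filter_band = c(1, 15),
    epoch_cap = 61,
    step_frac = 0.005,
    max_steps = 10000,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$predictor_fs <= 0 || cfg$eeg_fs <= 0) stopf("rates must be positive")
  if (cfg$lag_start >= cfg$lag_end) stopf("lag_start must be below lag_end")
  if (cfg$n_folds < 2) stopf("need at least 2 folds")
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' Configurations round-trip through serialization unchanged.
#'
#' @param config A [pipeline_config()]. @param path File path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_config <- function(config, path) {
  atomic_write(path, function(tmp)
    yaml::write_yaml(unclass(config), tmp))
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Write a provenance manifest next to an artifact
#'
#' Records the producing stage, the seed, the configuration, and the md5 of
#' every input and output file, so any artifact can name exactly what
#' produced it. [verify_manifest()] refuses to pass if a listed file has
#' changed.
#'
#' @param path Manifest file (JSON).
#' @param stage Pipeline stage name.
#' @param inputs,outputs Character vectors of file paths.
#' @param config A [pipeline_config()] (optional). @param seed Seed echoed
#'   into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, stage, inputs = character(0),
                           outputs = character(0), config = NULL,
                           seed = NULL) {
  hash <- function(files) {
    if (!length(files)) return(stats::setNames(list(), character(0)))
    as.list(tools::md5sum(files))
  }
  man <- list(stage = stage, seed = seed,
              config = if (!is.null(config)) unclass(config),
              inputs = hash(inputs), outputs = hash(outputs))
  atomic_write(path, function(tmp)
    jsonlite::write_json(man, tmp, auto_unbox = TRUE, digits = NA))
}

#' @rdname write_manifest
#' @export
verify_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (role in c("inputs", "outputs")) {
    files <- man[[role]]
    for (f in names(files)) {
      if (!file.exists(f)) stopf("manifest %s: missing %s '%s'",
                                 path, role, f)
      now <- unname(tools::md5sum(f))
      if (!identical(now, files[[f]])) {
        stopf("manifest %s: %s '%s' changed since it was recorded",
              path, role, f)
      }
    }
  }
  invisible(TRUE)
}
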