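#' Study run configuration
#'
#' The YAML config bundles everything a run needs beyond the images: the
#' echogenicity partition table (with colors), the classification rule
#' (class interval spans, decision margin, lake threshold), and the
#' calibration reference level. `default_study_config()` returns the
#' shipped configuration; `read_study_config()` loads a YAML file and fills
#' any missing section from the defaults.
#'
#' @return List with `partition` (`echo_partition`), `rule`
#'   (`classification_rule`), and `reference_level`.
#' @export
default_study_config <- function() {
  list(partition = build_canonical_partition(),
       rule = default_classification_rule(),
       reference_level = 200L)
}

#' @rdname default_study_config
#' @param path YAML config path. Recognized top-level keys: `partition_file`
#'   (a partition YAML as written by [write_partition_yaml()]),
#'   `classification` (`decision_margin`, `lake_threshold`, `class_ranges`
#'   as name pairs), `reference_level`.
#' @export
read_study_config <- function(path) {
  cfg <- default_study_config()
  obj <- yaml::read_yaml(path)
  if (!is.null(obj$partition_file)) {
    pf <- obj$partition_file
    if (!file.exists(pf)) pf <- file.path(dirname(path), obj$partition_file)
    cfg$partition <- read_partition_yaml(pf)
  }
  if (!is.null(obj$classification)) {
    cl <- obj$classification
    if (!is.null(cl$decision_margin)) {
      cfg$rule$decision_margin <- as.numeric(cl$decision_margin)
    }
    if (!is.null(cl$lake_threshold)) {
      cfg$rule$lake_threshold <- as.numeric(cl$lake_threshold)
    }
    if (!is.null(cl$class_ranges)) {
      cfg$rule$class_ranges <- lapply(cl$class_ranges, unlist)
    }
  }
  if (!is.null(obj$reference_level)) {
    cfg$reference_level <- as.integer(obj$reference_level)
  }
  cfg
}
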