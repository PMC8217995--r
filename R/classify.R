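#' Distribution-based edema classification rule
#'
#' Each edema type concentrates its pixel mass in a characteristic span of
#' echogenicity intervals: venous edema (VEG) in hypoechogenic IV through
#' echogenic III, lymphatic edema (LEG) in hypoechogenic II through
#' echogenic I, mixed edema (MEG) in hypoechogenic III through echogenic II,
#' and edema-free tissue (NEG) in echogenic II through hyperechogenic I.
#' The classifier scores a characterization against each class's span and
#' takes the argmax, abstaining (`INDETERMINATE`) when the top two scores
#' are closer than `decision_margin`.
#'
#' Because the four spans overlap and differ in width, raw range mass would
#' bias toward wide spans; scores are therefore density-normalized:
#' `score = range_mass / span_width_in_levels * 256`, i.e. the mass
#' concentration relative to a uniform distribution over the whole scale.
#'
#' @param decision_margin Minimum gap between the top two density scores for
#'   a confident call; default 0.05.
#' @param lake_threshold Lake-fraction level at or above which the advisory
#'   `lake_flag` is set; default 0.25.
#' @return A `classification_rule` list.
#' @export
default_classification_rule <- function(decision_margin = 0.05,
                                        lake_threshold = 0.25) {
  structure(
    list(class_ranges = list(
           VEG = c("hypoechogenic IV", "echogenic III"),
           LEG = c("hypoechogenic II", "echogenic I"),
           MEG = c("hypoechogenic III", "echogenic II"),
           NEG = c("echogenic II", "hyperechogenic I")),
         decision_margin = decision_margin,
         lake_threshold = lake_threshold),
    class = "classification_rule"
  )
}

#' Classify an edema characterization
#'
#' @param char A `tissue_characterization` from [characterize_roi()].
#' @param rule A `classification_rule`; see [default_classification_rule()].
#' @param partition The `echo_partition` the histogram was computed on.
#' @return A `classification_result`: list with `predicted` (`"VEG"`,
#'   `"LEG"`, `"MEG"`, `"NEG"`, or `"INDETERMINATE"`), `scores`
#'   (density-normalized), `evidence` (raw range masses), and `lake_flag`
#'   (advisory: lake fraction at or above the rule's threshold; never
#'   overrides the argmax).
#' @export
classify_edema <- function(char, rule = default_classification_rule(),
                           partition = build_canonical_partition()) {
  stopifnot(inherits(char, "tissue_characterization"),
            inherits(rule, "classification_rule"))
  validate_partition(partition)
  if (length(char$histogram$masses) != nrow(partition)) {
    stop("partition mismatch: histogram has ", length(char$histogram$masses),
         " intervals, partition has ", nrow(partition))
  }
  classes <- names(rule$class_ranges)
  evidence <- numeric(length(classes))
  scores <- numeric(length(classes))
  names(evidence) <- names(scores) <- classes
  for (cls in classes) {
    rng <- resolve_named_range(partition, rule$class_ranges[[cls]][1L],
                               rule$class_ranges[[cls]][2L])
    evidence[cls] <- range_mass(char$histogram, rng)
    scores[cls] <- evidence[cls] / (rng$hi - rng$lo + 1) * 256
  }
  ord <- order(scores, decreasing = TRUE)
  gap <- scores[ord[1L]] - scores[ord[2L]]
  predicted <- if (gap >= rule$decision_margin) classes[ord[1L]] else "INDETERMINATE"
  structure(
    list(predicted = predicted, scores = scores, evidence = evidence,
         lake_flag = char$lake_fraction >= rule$lake_threshold),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> predicted %s%s\n", x$predicted,
              if (x$lake_flag) " (lake flag set)" else ""))
  print(round(rbind(evidence = x$evidence, score = x$scores), 4))
  invisible(x)
}

#' End-to-end characterization and classification of one frame
#'
#' Composes the pipeline an analyst runs per frame: calibrate the frame to
#' the fascia anchor, characterize the tissue ROI (GSM, interval histogram,
#' lake fraction), and classify the edema type. Deterministic for fixed
#' inputs.
#'
#' @param image Raw [ultrasound_image].
#' @param roi Tissue `roi_mask` to characterize.
#' @param anchor A `calibration_anchor` for the frame's fascia band.
#' @param partition An `echo_partition`.
#' @param rule A `classification_rule`.
#' @param region Optional region code, carried into the characterization.
#' @return List with `characterization` and `classification`.
#' @export
characterize_and_classify <- function(image, roi, anchor,
                                      partition = build_canonical_partition(),
                                      rule = default_classification_rule(),
                                      region = NA_character_) {
  cal <- calibrate_to_fascia(image, anchor)
  char <- characterize_roi(cal, roi, partition, region = region)
  list(characterization = char,
       classification = classify_edema(char, rule, partition))
}
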