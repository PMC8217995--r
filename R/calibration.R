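#' Fascia-anchored brightness calibration
#'
#' Echo brightness depends on gain settings, so absolute levels are not
#' comparable across frames. The analyst marks a bright fascia band — a
#' structure of reliably high, stable echogenicity — and the frame is
#' rescaled so that band sits at reference level 200 on the 0-255 scale.
#' The map is a single multiplicative gain anchored at the fascia ROI's
#' median (the median resists speckle outliers): every pixel becomes
#' `round(value * reference_level / fascia_statistic)`, rounded half-up and
#' clipped to \[0,255\]. This is the simplest monotone map consistent with
#' anchoring one level.
#'
#' @param fascia_roi An `roi_mask` marking the fascia band.
#' @param reference_level Target level for the fascia, default 200.
#' @param statistic `"median"` (default) or `"mean"` fascia summary.
#' @param clip_warn_threshold Warn when more than this fraction of pixels
#'   clips at 255 (an over-bright anchor compresses the upper bands);
#'   default 0.05.
#' @return A `calibration_anchor` list.
#' @export
calibration_anchor <- function(fascia_roi, reference_level = 200L,
                               statistic = c("median", "mean"),
                               clip_warn_threshold = 0.05) {
  stopifnot(inherits(fascia_roi, "roi_mask"))
  statistic <- match.arg(statistic)
  reference_level <- as.integer(reference_level)
  if (reference_level < 1L || reference_level > 255L) {
    stop("reference_level must lie in [1,255]")
  }
  structure(list(fascia_roi = fascia_roi, reference_level = reference_level,
                 statistic = statistic,
                 clip_warn_threshold = clip_warn_threshold),
            class = "calibration_anchor")
}

#' @rdname calibration_anchor
#' @param image An [ultrasound_image] to calibrate.
#' @param anchor A `calibration_anchor` whose fascia ROI is congruent with
#'   `image`.
#' @return `calibrate_to_fascia` returns the calibrated [ultrasound_image]
#'   with a `calibration` field recording `scale_factor`, the fascia
#'   statistic before/after, and the clipped-pixel fraction. On the output,
#'   the fascia ROI's statistic equals `reference_level` up to +/-1 rounding.
#' @examples
#' img <- ultrasound_image(matrix(50L, 8, 8))
#' img$pixels[1:2, ] <- 100L   # fascia band at 100
#' roi <- roi_mask(row(img$pixels) <= 2)
#' cal <- calibrate_to_fascia(img, calibration_anchor(roi))
#' cal$pixels[3, 3]            # 100: scale factor 200/100 = 2
#' @export
calibrate_to_fascia <- function(image, anchor) {
  image <- as_ultrasound_image(image)
  stopifnot(inherits(anchor, "calibration_anchor"))
  m <- anchor$fascia_roi$mask
  if (nrow(m) != image$height_px || ncol(m) != image$width_px) {
    stop("fascia ROI dimensions do not match the image")
  }
  vals <- image$pixels[m]
  stat <- if (anchor$statistic == "median") stats::median(vals) else mean(vals)
  if (stat <= 0) {
    stop("fascia statistic is 0: anchor placed on anechoic tissue?")
  }
  scale_factor <- anchor$reference_level / stat
  scaled <- floor(image$pixels * scale_factor + 0.5)  # round half up
  clipped_frac <- mean(scaled > 255)
  out_px <- matrix(as.integer(pmin(pmax(scaled, 0), 255)),
                   nrow = image$height_px)
  if (clipped_frac > anchor$clip_warn_threshold) {
    warning(sprintf(
      "%.1f%% of pixels clipped at 255: the fascia anchor may be over-bright",
      100 * clipped_frac))
  }
  out <- ultrasound_image(out_px, pixel_spacing_mm = image$pixel_spacing_mm,
                          source_id = image$source_id)
  fascia_after <- if (anchor$statistic == "median") {
    stats::median(out_px[m])
  } else {
    mean(out_px[m])
  }
  out$calibration <- list(scale_factor = scale_factor,
                          fascia_statistic_before = stat,
                          fascia_statistic_after = fascia_after,
                          reference_level = anchor$reference_level,
                          clipped_fraction = clipped_frac)
  out
}
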