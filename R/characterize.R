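#' Gray Scale Median of a region
#'
#' The GSM is the median pixel brightness of the ROI on the 0-255 scale, the
#' standard scalar echogenicity summary. Even pixel counts return the mean
#' of the two middle order statistics (the usual sample-median convention).
#'
#' @param image An [ultrasound_image].
#' @param roi An `roi_mask` congruent with the image.
#' @return The median brightness, a real in \[0,255\].
#' @examples
#' img <- ultrasound_image(matrix(c(10L, 20L), 1, 2))
#' compute_gsm(img, roi_mask(matrix(TRUE, 1, 2)))   # 15
#' @export
compute_gsm <- function(image, roi) {
  stats::median(roi_pixels(image, roi))
}

roi_pixels <- function(image, roi) {
  image <- as_ultrasound_image(image)
  stopifnot(inherits(roi, "roi_mask"))
  if (nrow(roi$mask) != image$height_px || ncol(roi$mask) != image$width_px) {
    stop("ROI dimensions do not match the image")
  }
  image$pixels[roi$mask]
}

#' Echogenicity-interval histogram of a region
#'
#' Tallies the ROI's pixels into the partition's intervals and normalizes by
#' the pixel count, giving the per-interval mass fractions that the group
#' distributions and the classifier work on.
#'
#' @inheritParams compute_gsm
#' @param partition An `echo_partition` (default canonical 14 intervals).
#' @return An `echo_histogram`: list with `raw_counts`, `masses` (fractions
#'   summing to 1), `n_pixels`, and `interval_names`.
#' @export
compute_histogram <- function(image, roi, partition = build_canonical_partition()) {
  validate_partition(partition)
  px <- roi_pixels(image, roi)
  idx <- findInterval(px, partition$lo)
  counts <- tabulate(idx, nbins = nrow(partition))
  structure(
    list(raw_counts = counts, masses = counts / length(px),
         n_pixels = length(px), interval_names = partition$name),
    class = "echo_histogram"
  )
}

#' @export
print.echo_histogram <- function(x, ...) {
  cat(sprintf("<echo_histogram> %d pixels over %d intervals\n",
              x$n_pixels, length(x$masses)))
  print(data.frame(interval = x$interval_names, count = x$raw_counts,
                   mass = round(x$masses, 4)), row.names = FALSE)
  invisible(x)
}

#' Pixel-mass fraction inside a named interval range
#'
#' @param hist An `echo_histogram`.
#' @param range An `echo_range` from [resolve_named_range()], resolved
#'   against the same partition.
#' @return Fraction of ROI pixels whose brightness falls in the range.
#' @export
range_mass <- function(hist, range) {
  stopifnot(inherits(hist, "echo_histogram"), inherits(range, "echo_range"))
  if (range$to_idx > length(hist$masses)) {
    stop("partition mismatch: range resolved against a different partition")
  }
  sum(hist$masses[range$from_idx:range$to_idx])
}

#' Full tissue characterization of an ROI
#'
#' Bundles the GSM, the 14-interval histogram, and the lymphatic-lake
#' fraction: the share of pixels with brightness in \[0,40\], the band that
#' hypoechogenic lake lumina occupy. The lake bound is kept numeric rather
#' than expressed through interval names.
#'
#' @inheritParams compute_histogram
#' @param region Optional region code (`"DF"`, `"MPL"`, `"MML"`, `"MDL"`).
#' @return A `tissue_characterization`: list with `gsm`, `histogram`,
#'   `lake_fraction`, `region`.
#' @export
characterize_roi <- function(image, roi,
                             partition = build_canonical_partition(),
                             region = NA_character_) {
  px <- roi_pixels(image, roi)
  structure(
    list(gsm = stats::median(px),
         histogram = compute_histogram(image, roi, partition),
         lake_fraction = mean(px <= 40L),
         region = region),
    class = "tissue_characterization"
  )
}

#' @export
print.tissue_characterization <- function(x, ...) {
  cat(sprintf("<tissue_characterization> GSM %.1f, lake fraction %.3f%s\n",
              x$gsm, x$lake_fraction,
              if (is.na(x$region)) "" else paste0(", region ", x$region)))
  invisible(x)
}
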