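#' Construct an ultrasound image object
#'
#' The package's pixel container: an integer matrix of brightness values on
#' the 0-255 grayscale (row = depth line, column = lateral position), plus
#' optional physical pixel spacing and a source label.
#'
#' @param pixels Integer matrix with values in \[0,255\].
#' @param pixel_spacing_mm Optional positive pixel edge length in mm.
#' @param source_id Text label for provenance (file name, phantom id, ...).
#' @return An `ultrasound_image` list with fields `pixels`, `height_px`,
#'   `width_px`, `pixel_spacing_mm`, `source_id`.
#' @export
ultrasound_image <- function(pixels, pixel_spacing_mm = NULL, source_id = "") {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (any(!is.finite(pixels))) stop("pixels must be finite")
  if (any(pixels != floor(pixels))) stop("pixels must be integer-valued")
  if (any(pixels < 0 | pixels > 255)) stop("pixel values must lie in [0,255]")
  if (!is.null(pixel_spacing_mm)) stopifnot(pixel_spacing_mm > 0)
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, height_px = nrow(pixels), width_px = ncol(pixels),
         pixel_spacing_mm = pixel_spacing_mm, source_id = source_id),
    class = "ultrasound_image"
  )
}

#' @rdname ultrasound_image
#' @param x Matrix or `ultrasound_image`.
#' @export
as_ultrasound_image <- function(x) {
  if (inherits(x, "ultrasound_image")) return(x)
  if (is.matrix(x)) return(ultrasound_image(x))
  stop("cannot coerce to ultrasound_image")
}

#' @export
print.ultrasound_image <- function(x, ...) {
  cat(sprintf("<ultrasound_image> %d x %d px, brightness [%d, %d]%s\n",
              x$height_px, x$width_px, min(x$pixels), max(x$pixels),
              if (nzchar(x$source_id)) paste0(", source '", x$source_id, "'") else ""))
  invisible(x)
}

#' Read an 8/16-bit grayscale frame
#'
#' Decodes a single-frame PNG or TIFF into the 0-255 brightness domain.
#' 16-bit inputs are linearly rescaled to \[0,255\] and rounded. Color inputs
#' are accepted only when all color channels are identical (a gray image
#' stored as RGB); genuinely colorized frames are rejected because overlays
#' corrupt the raw echo brightness. An opaque alpha channel is dropped.
#'
#' @param path Path to the image file.
#' @param dialect One of `"png"`, `"tiff"`; inferred from the file extension
#'   by default. `"dicom"` is recognized but unsupported: convert secondary
#'   captures to PNG/TIFF upstream.
#' @return An [ultrasound_image].
#' @export
load_grayscale_image <- function(path, dialect = c("auto", "png", "tiff", "dicom")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, png = "png", tif = , tiff = "tiff", dcm = "dicom",
                      stop("cannot infer image dialect from extension '", ext, "'"))
  }
  if (dialect == "dicom") {
    stop("DICOM input is not supported; export the secondary capture as PNG or TIFF")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- switch(dialect,
                png = png::readPNG(path),
                tiff = tiff::readTIFF(path, all = TRUE))
  if (dialect == "tiff") {
    if (length(arr) > 1L) stop("multi-frame input: expected a single frame")
    arr <- arr[[1L]]
  }
  plane <- collapse_to_gray(arr)
  # readers normalize to [0,1] regardless of bit depth, so one rescale rule
  # covers 8- and 16-bit input
  px <- matrix(as.integer(round(plane * 255)), nrow = nrow(plane))
  ultrasound_image(px, source_id = basename(path))
}

collapse_to_gray <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  if (length(dim(arr)) != 3L) stop("unsupported image layout")
  nch <- dim(arr)[3L]
  if (nch == 2L) return(arr[, , 1L])                      # gray + alpha
  if (nch %in% c(3L, 4L)) {
    rgb <- arr[, , 1:3]
    if (any(rgb[, , 1L] != rgb[, , 2L]) || any(rgb[, , 1L] != rgb[, , 3L])) {
      stop("non-grayscale input: RGB channels differ (colorized frame?)")
    }
    return(arr[, , 1L])
  }
  stop("unsupported channel count: ", nch)
}

#' Write an ultrasound image as an 8-bit grayscale PNG
#'
#' Exact inverse of [load_grayscale_image()] for 8-bit data: a write/read
#' round trip reproduces the pixel grid.
#'
#' @param image An [ultrasound_image].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_grayscale_image <- function(image, path) {
  image <- as_ultrasound_image(image)
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Region-of-interest masks
#'
#' A mask is a logical matrix congruent with its image. It is read either
#' from an 8-bit binary PNG (non-zero = selected) or built from a JSON
#' polygon `{"vertices": [[r, c], ...]}` in continuous 0-based image
#' coordinates. Polygon rasterization includes a pixel iff its center
#' `(row + 0.5, col + 0.5)` lies inside the polygon (even-odd rule), so a
#' rectangle `(0,0)-(10,10)` selects exactly the 10 x 10 pixel block.
#'
#' @param path Path to a mask PNG or polygon JSON (by extension).
#' @param image The paired [ultrasound_image]; dimensions must match.
#' @return An `roi_mask`: list with logical matrix `mask` and `n_selected`.
#' @export
load_roi_mask <- function(path, image) {
  image <- as_ultrasound_image(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    poly <- jsonlite::fromJSON(path)
    if (is.null(poly$vertices)) stop("polygon JSON must contain 'vertices'")
    verts <- matrix(as.numeric(t(poly$vertices)), ncol = 2L, byrow = TRUE)
    return(roi_from_polygon(verts, image))
  }
  plane <- collapse_to_gray(png::readPNG(path))
  if (nrow(plane) != image$height_px || ncol(plane) != image$width_px) {
    stop("dimension mismatch: mask is ", nrow(plane), "x", ncol(plane),
         ", image is ", image$height_px, "x", image$width_px)
  }
  roi_mask(plane > 0.5)
}

#' @rdname load_roi_mask
#' @param mask Logical matrix (TRUE = pixel selected).
#' @export
roi_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  n <- sum(mask)
  if (n == 0L) stop("empty ROI: mask selects no pixels")
  structure(list(mask = mask, n_selected = n), class = "roi_mask")
}

#' @rdname load_roi_mask
#' @param vertices Numeric matrix (n x 2) of polygon vertices `(row, col)` in
#'   continuous 0-based coordinates.
#' @export
roi_from_polygon <- function(vertices, image) {
  image <- as_ultrasound_image(image)
  stopifnot(is.matrix(vertices), ncol(vertices) == 2L, nrow(vertices) >= 3L)
  h <- image$height_px; w <- image$width_px
  centers_r <- rep(seq_len(h) - 0.5, times = w)
  centers_c <- rep(seq_len(w) - 0.5, each = h)
  inside <- point_in_polygon(centers_r, centers_c, vertices[, 1L], vertices[, 2L])
  roi_mask(matrix(inside, nrow = h, ncol = w))
}

# even-odd ray casting; the (y1 > p) != (y2 > p) crossing test makes edges
# half-open, so shared borders between adjacent polygons never double-count
point_in_polygon <- function(pr, pc, vr, vc) {
  n <- length(vr)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (vr[i] > pr) != (vr[j] > pr)
    xint <- (vc[j] - vc[i]) * (pr - vr[i]) / (vr[j] - vr[i]) + vc[i]
    inside <- xor(inside, crosses & (pc < xint))
    j <- i
  }
  inside
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d, %d pixels selected\n",
              nrow(x$mask), ncol(x$mask), x$n_selected))
  invisible(x)
}

#' Limb/region metadata record
#'
#' Carries the scan's anatomical region code and optional clinical labels.
#' Regions: dorsal forefoot (DF), mid-proximal leg (MPL), mid-medial leg
#' (MML), mid-distal leg (MDL). Clinical staging (Mowlem phase for
#' lymphedema, CEAP clinical class for venous disease) is metadata only.
#'
#' @param limb_id Text identifier.
#' @param side `"left"` or `"right"`.
#' @param region One of `"DF"`, `"MPL"`, `"MML"`, `"MDL"`.
#' @param group_label Optional group: `"VEG"`, `"LEG"`, `"MEG"`, `"NEG"`.
#' @param mowlem Optional lymphedema phase `"I"`, `"II"`, `"III"`.
#' @param ceap Optional CEAP clinical class 0-6.
#' @return A `limb_record` list.
#' @export
limb_record <- function(limb_id, side = c("left", "right"),
                        region = c("DF", "MPL", "MML", "MDL"),
                        group_label = NA_character_,
                        mowlem = NA_character_, ceap = NA_integer_) {
  side <- match.arg(side)
  region <- match.arg(region)
  if (!is.na(group_label)) {
    group_label <- match.arg(group_label, c("VEG", "LEG", "MEG", "NEG"))
  }
  if (!is.na(mowlem)) mowlem <- match.arg(mowlem, c("I", "II", "III"))
  if (!is.na(ceap)) stopifnot(ceap %in% 0:6)
  structure(list(limb_id = as.character(limb_id), side = side, region = region,
                 group_label = group_label, mowlem = mowlem,
                 ceap = as.integer(ceap)),
            class = "limb_record")
}

#' Write the per-limb characterization report
#'
#' One CSV row per (limb, region): identity columns, GSM, lake fraction, the
#' 14 interval-mass fractions in partition order, the predicted class, and
#' the per-class range-mass evidence. Floats use fixed 6-decimal formatting,
#' so re-running on identical input yields a byte-identical file.
#'
#' @param records List of entries, each a list with elements `limb`
#'   ([limb_record]), `characterization` (from [characterize_roi()]), and
#'   optionally `classification` (from [classify_edema()]).
#' @param path Output CSV path.
#' @return Number of data rows written.
#' @export
write_report <- function(records, path) {
  if (length(records) == 0L) stop("no records to write")
  part_names <- records[[1L]]$characterization$histogram$interval_names
  mass_cols <- paste0("mass_", gsub("[ -]", "_", part_names))
  classes <- c("VEG", "LEG", "MEG", "NEG")
  header <- c("limb_id", "side", "region", "group_label", "gsm",
              "lake_fraction", mass_cols, "predicted",
              paste0("evidence_", classes))
  fmt <- function(x) sprintf("%.6f", x)
  lines <- vapply(records, function(rec) {
    lr <- rec$limb
    ch <- rec$characterization
    cl <- rec$classification
    pred <- if (is.null(cl)) "" else cl$predicted
    ev <- if (is.null(cl)) rep("", 4L) else fmt(unname(cl$evidence[classes]))
    paste(c(csv_quote(lr$limb_id), lr$side, lr$region,
            ifelse(is.na(lr$group_label), "", lr$group_label),
            fmt(ch$gsm), fmt(ch$lake_fraction), fmt(ch$histogram$masses),
            pred, ev),
          collapse = ",")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = ","), lines), con, sep = "\r\n",
             useBytes = TRUE)
  length(lines)
}

csv_quote <- function(x) {
  needs <- grepl('[",\r\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Read a characterization report written by [write_report()]
#'
#' @param path CSV path.
#' @return A data frame with one row per (limb, region).
#' @export
read_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(limb_id = "character"))
}
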