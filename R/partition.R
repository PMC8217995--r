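#' Canonical echogenicity partition of the 0-255 brightness axis
#'
#' B-mode tissue characterization works on the 256-level grayscale. The
#' brightness axis is structured twice over: five coarse *color bands*
#' (non-echogenic \[0,4\], low echogenicity \[5,60\], echogenic \[61,132\],
#' high echogenicity \[133,210\], saturation \[211,255\]) used for
#' pseudocolor rendering, and a finer 14-interval partition used for
#' pixel-mass histograms. The canonical 14 intervals subdivide the color
#' bands into equal-width sub-intervals (any remainder goes to the earliest
#' sub-intervals): the non-echogenic and saturation bands stay whole, low
#' echogenicity splits into hypoechogenic I-IV, echogenic into
#' echogenic I-III, and high echogenicity into hyperechogenic I-V.
#'
#' Intervals that fall entirely inside one of the Lal reference tissue bands
#' (blood 0-4, fat 8-26, muscle 41-76, fibrosis 112-196, calcium 211-255)
#' carry that band's tissue tag as an annotation; tags never affect binning.
#'
#' @return An `echo_partition`: a data frame with columns `name`, `lo`, `hi`
#'   (inclusive integer bounds), `band`, and `tissue_tag`, one row per
#'   interval in brightness order, with the color-band table attached as
#'   attribute `color_bands`.
#' @examples
#' part <- build_canonical_partition()
#' nrow(part)          # 14
#' part$name[1]        # "non-echogenic"
#' @export
build_canonical_partition <- function() {
  bands <- color_band_table()
  split_band <- function(lo, hi, n, stem, roman) {
    width <- hi - lo + 1L
    base <- width %/% n
    sizes <- rep(base, n)
    extra <- width %% n
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    his <- lo - 1L + cumsum(sizes)
    los <- c(lo, head(his, -1L) + 1L)
    names <- if (n == 1L) stem else paste(stem, as.character(utils::as.roman(seq_len(n))))
    data.frame(name = names, lo = los, hi = his, stringsAsFactors = FALSE)
  }
  pieces <- list(
    split_band(0L, 4L, 1L, "non-echogenic"),
    split_band(5L, 60L, 4L, "hypoechogenic"),
    split_band(61L, 132L, 3L, "echogenic"),
    split_band(133L, 210L, 5L, "hyperechogenic"),
    split_band(211L, 255L, 1L, "saturation")
  )
  part <- do.call(rbind, pieces)
  part$band <- rep(bands$band, c(1L, 4L, 3L, 5L, 1L))
  part$tissue_tag <- lal_tissue_tag(part$lo, part$hi)
  class(part) <- c("echo_partition", "data.frame")
  attr(part, "color_bands") <- bands
  part
}

#' @keywords internal
color_band_table <- function() {
  data.frame(
    band = c("non-echogenic", "low echogenicity", "echogenic",
             "high echogenicity", "saturation"),
    lo = c(0L, 5L, 61L, 133L, 211L),
    hi = c(4L, 60L, 132L, 210L, 255L),
    r = c(0L, 0L, 0L, 255L, 255L),
    g = c(0L, 0L, 200L, 165L, 255L),
    b = c(0L, 255L, 0L, 0L, 255L),
    stringsAsFactors = FALSE
  )
}

# Lal reference bands for carotid-plaque tissue classes; a partition interval
# inherits a tag only when fully nested inside one band.
lal_tissue_tag <- function(lo, hi) {
  lal <- data.frame(
    tag = c("blood", "fat", "muscle", "fibrosis", "calcium"),
    lo = c(0L, 8L, 41L, 112L, 211L),
    hi = c(4L, 26L, 76L, 196L, 255L)
  )
  vapply(seq_along(lo), function(i) {
    inside <- lal$lo <= lo[i] & hi[i] <= lal$hi
    if (any(inside)) lal$tag[which(inside)[1L]] else "unassigned"
  }, character(1))
}

validate_partition <- function(partition) {
  stopifnot(inherits(partition, "echo_partition"))
  if (partition$lo[1L] != 0L || partition$hi[nrow(partition)] != 255L ||
      any(partition$lo[-1L] != partition$hi[-nrow(partition)] + 1L)) {
    stop("partition must cover [0,255] contiguously without gaps or overlaps")
  }
  invisible(partition)
}

#' @export
print.echo_partition <- function(x, ...) {
  cat(sprintf("<echo_partition> %d intervals on [0,255]\n", nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Locate the echogenicity interval containing a brightness level
#'
#' @param partition An `echo_partition`.
#' @param brightness Integer vector of brightness levels in \[0,255\].
#' @return One-row data frame per level (rows of `partition`), in input order.
#' @examples
#' part <- build_canonical_partition()
#' locate_interval(part, 3)$name    # "non-echogenic"
#' @export
locate_interval <- function(partition, brightness) {
  validate_partition(partition)
  if (any(!is.finite(brightness)) || any(brightness < 0 | brightness > 255)) {
    stop("brightness out of range [0,255]")
  }
  idx <- findInterval(brightness, partition$lo)
  partition[idx, , drop = FALSE]
}

#' Resolve a named span of consecutive echogenicity intervals
#'
#' Group-level results are stated as spans such as "hypoechogenic IV through
#' echogenic III"; this resolves interval names to the covered brightness
#' range.
#'
#' @param partition An `echo_partition`.
#' @param from_name,to_name Interval names; `from_name` must not come after
#'   `to_name` in partition order.
#' @return An `echo_range`: list with `from_name`, `to_name`, `from_idx`,
#'   `to_idx`, `lo`, `hi`.
#' @examples
#' part <- build_canonical_partition()
#' r <- resolve_named_range(part, "hypoechogenic IV", "echogenic III")
#' c(r$lo, r$hi)   # 47 132
#' @export
resolve_named_range <- function(partition, from_name, to_name) {
  validate_partition(partition)
  from_idx <- match(from_name, partition$name)
  to_idx <- match(to_name, partition$name)
  if (is.na(from_idx)) stop("unknown interval name: ", from_name)
  if (is.na(to_idx)) stop("unknown interval name: ", to_name)
  if (from_idx > to_idx) stop("inverted range: '", from_name, "' comes after '", to_name, "'")
  structure(
    list(from_name = from_name, to_name = to_name,
         from_idx = from_idx, to_idx = to_idx,
         lo = partition$lo[from_idx], hi = partition$hi[to_idx]),
    class = "echo_range"
  )
}

#' @export
print.echo_range <- function(x, ...) {
  cat(sprintf("<echo_range> '%s' .. '%s' = brightness [%d, %d]\n",
              x$from_name, x$to_name, x$lo, x$hi))
  invisible(x)
}

#' Pseudocolor rendering of a calibrated frame
#'
#' Paints each pixel with the RGB triple of its color band, so the five
#' echogenicity amplitudes are separable by eye (the unaided eye resolves
#' only about 16 of the 256 gray tones).
#'
#' @param image An [ultrasound_image] (should be calibrated first so the
#'   bands carry their intended tissue meaning).
#' @param partition An `echo_partition` carrying the color-band table.
#' @return Integer array `height x width x 3` of RGB values in \[0,255\],
#'   with the legend (band table) attached as attribute `legend`.
#' @export
colorize <- function(image, partition = build_canonical_partition()) {
  image <- as_ultrasound_image(image)
  validate_partition(partition)
  bands <- attr(partition, "color_bands")
  idx <- findInterval(image$pixels, bands$lo)
  out <- array(0L, dim = c(image$height_px, image$width_px, 3L))
  out[, , 1L] <- bands$r[idx]
  out[, , 2L] <- bands$g[idx]
  out[, , 3L] <- bands$b[idx]
  attr(out, "legend") <- bands
  out
}

#' Write / read an echogenicity partition as a YAML table
#'
#' The partition (name, bounds, tissue tag) plus the color-band table are
#' serialized so a study config can override the canonical table.
#'
#' @param partition An `echo_partition`.
#' @param path File path for the YAML table.
#' @return `write_partition_yaml` returns `path` invisibly;
#'   `read_partition_yaml` returns an `echo_partition`.
#' @export
write_partition_yaml <- function(partition, path) {
  validate_partition(partition)
  bands <- attr(partition, "color_bands")
  obj <- list(
    intervals = lapply(seq_len(nrow(partition)), function(i) {
      list(name = partition$name[i], lo = partition$lo[i], hi = partition$hi[i],
           band = partition$band[i], tissue_tag = partition$tissue_tag[i])
    }),
    color_bands = lapply(seq_len(nrow(bands)), function(i) {
      list(band = bands$band[i], lo = bands$lo[i], hi = bands$hi[i],
           rgb = c(bands$r[i], bands$g[i], bands$b[i]))
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_partition_yaml
#' @export
read_partition_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  part <- do.call(rbind, lapply(obj$intervals, function(iv) {
    data.frame(name = iv$name, lo = as.integer(iv$lo), hi = as.integer(iv$hi),
               band = iv$band, tissue_tag = iv$tissue_tag,
               stringsAsFactors = FALSE)
  }))
  bands <- do.call(rbind, lapply(obj$color_bands, function(b) {
    data.frame(band = b$band, lo = as.integer(b$lo), hi = as.integer(b$hi),
               r = as.integer(b$rgb[1]), g = as.integer(b$rgb[2]),
               b = as.integer(b$rgb[3]), stringsAsFactors = FALSE)
  }))
  class(part) <- c("echo_partition", "data.frame")
  attr(part, "color_bands") <- bands
  validate_partition(part)
  part
}
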