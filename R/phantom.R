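#' Shipped phantom profiles for the four edema classes
#'
#' Each profile prescribes a 14-interval target mass vector that places the
#' class's cohort-level pixel fraction inside its characteristic interval
#' span, spread uniformly over the span's intervals, with the remainder
#' spread uniformly over the other intervals:
#' venous (VEG) 88.31% in hypoechogenic IV..echogenic III, lymphatic (LEG)
#' 71.73% in hypoechogenic II..echogenic I, mixed (MEG) 76.17% in
#' hypoechogenic III..echogenic II, control (NEG) 84.87% in
#' echogenic II..hyperechogenic I.
#'
#' Morphology follows the class: lymphatic and mixed phantoms carve
#' vertically oriented hypoechoic "lymphatic lakes"; venous and mixed
#' phantoms cluster their mid-brightness mass into granular patches.
#'
#' @param edema_class `"VEG"`, `"LEG"`, `"MEG"`, or `"NEG"`.
#' @param height_px,width_px Frame size (default 256 x 256); the top
#'   `fascia_rows` rows hold a synthetic fascia band, the rest is tissue.
#' @param fascia_rows Rows of the built-in fascia band (median exactly 200,
#'   so fascia calibration of a phantom is an identity map); default 16.
#' @param seed RNG seed stored in the spec; default 1.
#' @return A `phantom_spec` list: `edema_class`, `target_masses`,
#'   `class_range` (interval-name pair), dimensions, `lake_params`
#'   (`n_lakes`, `axis_ratio`, minor diameter range in px, lumen brightness
#'   ceiling 40), `granularity_px`, `speckle_sigma`, `seed`.
#' @examples
#' spec <- default_class_profile("VEG")
#' sum(spec$target_masses)   # 1
#' @export
default_class_profile <- function(edema_class = c("VEG", "LEG", "MEG", "NEG"),
                                  height_px = 256L, width_px = 256L,
                                  fascia_rows = 16L, seed = 1L) {
  edema_class <- match.arg(edema_class)
  prof <- switch(edema_class,
    VEG = list(frac = 0.8831, range = c("hypoechogenic IV", "echogenic III"),
               n_lakes = 0L, granularity_px = 4L),
    LEG = list(frac = 0.7173, range = c("hypoechogenic II", "echogenic I"),
               n_lakes = 6L, granularity_px = 1L),
    MEG = list(frac = 0.7617, range = c("hypoechogenic III", "echogenic II"),
               n_lakes = 3L, granularity_px = 4L),
    NEG = list(frac = 0.8487, range = c("echogenic II", "hyperechogenic I"),
               n_lakes = 0L, granularity_px = 1L))
  part <- build_canonical_partition()
  rng <- resolve_named_range(part, prof$range[1L], prof$range[2L])
  in_range <- seq(rng$from_idx, rng$to_idx)
  masses <- rep((1 - prof$frac) / (nrow(part) - length(in_range)), nrow(part))
  masses[in_range] <- prof$frac / length(in_range)
  structure(
    list(edema_class = edema_class, target_masses = masses,
         class_range = prof$range,
         height_px = as.integer(height_px), width_px = as.integer(width_px),
         fascia_rows = as.integer(fascia_rows),
         lake_params = list(n_lakes = prof$n_lakes, axis_ratio = 3,
                            minor_diameter_px = c(3, 10),
                            lumen_max_brightness = 40L),
         granularity_px = prof$granularity_px,
         speckle_sigma = 0.15, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> class %s, %d x %d px, %d lakes, seed %d\n",
              x$edema_class, x$height_px, x$width_px,
              x$lake_params$n_lakes, x$seed))
  invisible(x)
}

# run code under a given seed, leaving the caller's RNG state untouched
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# separable circular box blur, two passes: cheap smooth random field whose
# level sets drive the granular spatial arrangement
smooth_field <- function(h, w, granularity_px) {
  z <- matrix(stats::rnorm(h * w), h, w)
  k <- rep(1 / (2 * granularity_px + 1), 2 * granularity_px + 1)
  blur <- function(m) {
    m <- apply(m, 2L, function(col) as.numeric(stats::filter(col, k, circular = TRUE)))
    t(apply(m, 1L, function(row) as.numeric(stats::filter(row, k, circular = TRUE))))
  }
  blur(blur(z))
}

#' Generate one synthetic B-mode phantom
#'
#' Pixels are assigned echogenicity intervals by multinomial sampling from
#' the spec's target mass vector, then a brightness uniform within their
#' interval, so the interval-mass contract holds exactly up to sampling
#' noise. Spatial arrangement follows the class morphology:
#' * lakes — vertically elongated ellipses whose pixels are filled only
#'   with labels from intervals lying wholly inside the lake lumen band
#'   (brightness at most 40), mimicking hypoechoic lymphatic lakes;
#' * granularity — remaining labels are laid out along a smoothed random
#'   field so similar brightness clusters into patches of roughly
#'   `granularity_px` scale (venous/mixed classes), or placed at random.
#'
#' Multiplicative log-normal speckle is applied and re-quantized with an
#' interval-preserving correction: a speckled pixel that would leave its
#' assigned interval is resampled uniformly within it, so texture never
#' breaks the mass contract. A fascia band (median exactly 200) occupies
#' the top rows. Fixed seed gives an identical image.
#'
#' @param spec A `phantom_spec`, typically from [default_class_profile()].
#' @return A `phantom_image`: list with `image` ([ultrasound_image]),
#'   `fascia_roi` and `tissue_roi` (`roi_mask`), `lake_mask` (logical,
#'   full-frame), `empirical_masses` (the generator's own interval tally —
#'   the recovery oracle), and `truth` (the spec).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (abs(sum(spec$target_masses) - 1) > 1e-9) {
    stop("target_masses must sum to 1")
  }
  part <- build_canonical_partition()
  th <- spec$height_px - spec$fascia_rows
  w <- spec$width_px
  if (th < 8L) stop("frame too small for the fascia band plus tissue")
  n <- th * w
  n_lakes <- spec$lake_params$n_lakes
  lake_ivals <- which(part$hi <= spec$lake_params$lumen_max_brightness)
  if (n_lakes >= 1L && sum(spec$target_masses[lake_ivals]) <= 0) {
    stop("infeasible lakes: no target mass at or below brightness ",
         spec$lake_params$lumen_max_brightness)
  }

  with_seed(spec$seed, {
    labels <- sample.int(nrow(part), n, replace = TRUE,
                         prob = spec$target_masses)

    lake_mask <- matrix(FALSE, th, w)
    if (n_lakes >= 1L) {
      rr <- row(lake_mask); cc <- col(lake_mask)
      dmin <- spec$lake_params$minor_diameter_px[1L] / 2
      dmax <- spec$lake_params$minor_diameter_px[2L] / 2
      for (i in seq_len(n_lakes)) {
        b <- stats::runif(1, dmin, dmax)
        a <- b * spec$lake_params$axis_ratio
        r0 <- stats::runif(1, a + 1, th - a)
        c0 <- stats::runif(1, b + 1, w - b)
        lake_mask <- lake_mask | (((rr - r0) / a)^2 + ((cc - c0) / b)^2 <= 1)
      }
    }
    lake_pos <- which(lake_mask)
    eligible <- which(labels %in% lake_ivals)
    if (length(lake_pos) > length(eligible)) {
      lake_pos <- lake_pos[seq_along(eligible)]
      lake_mask[] <- FALSE
      lake_mask[lake_pos] <- TRUE
    }

    lab_at <- integer(n)
    if (length(lake_pos) > 0L) {
      chosen <- eligible[sample.int(length(eligible), length(lake_pos))]
      lab_at[lake_pos] <- labels[chosen]
      rest_labels <- labels[-chosen]
    } else {
      rest_labels <- labels
    }
    rest_pos <- if (length(lake_pos) > 0L) seq_len(n)[-lake_pos] else seq_len(n)
    if (spec$granularity_px > 1L) {
      field <- smooth_field(th, w, spec$granularity_px)
      lab_at[rest_pos[order(field[rest_pos])]] <- sort(rest_labels)
    } else {
      lab_at[rest_pos] <- rest_labels
    }

    lo <- part$lo[lab_at]
    width <- part$hi[lab_at] - lo + 1L
    v <- lo + floor(stats::runif(n) * width)
    s <- floor(v * exp(stats::rnorm(n, 0, spec$speckle_sigma)) + 0.5)
    viol <- s < lo | s > part$hi[lab_at]
    s[viol] <- lo[viol] + floor(stats::runif(sum(viol)) * width[viol])
    tissue <- matrix(as.integer(s), th, w)

    nf <- spec$fascia_rows * w
    fascia_vals <- rep(200L, nf)
    k <- floor(nf * 0.4)  # strict majority stays at 200 => median exactly 200
    jitter_idx <- sample.int(nf, k)
    fascia_vals[jitter_idx] <- sample(185:215, k, replace = TRUE)
    fascia <- matrix(fascia_vals, spec$fascia_rows, w)

    img <- ultrasound_image(rbind(fascia, tissue),
                            source_id = sprintf("phantom-%s-seed%d",
                                                spec$edema_class, spec$seed))
    rows <- row(img$pixels)
    full_lake <- matrix(FALSE, spec$height_px, w)
    full_lake[(spec$fascia_rows + 1):spec$height_px, ] <- lake_mask
    structure(
      list(image = img,
           fascia_roi = roi_mask(rows <= spec$fascia_rows),
           tissue_roi = roi_mask(rows > spec$fascia_rows),
           lake_mask = full_lake,
           empirical_masses = tabulate(lab_at, nbins = nrow(part)) / n,
           truth = spec),
      class = "phantom_image"
    )
  })
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("<phantom_image> class %s, %d x %d px, %d lake px, seed %d\n",
              x$truth$edema_class, x$image$height_px, x$image$width_px,
              sum(x$lake_mask), x$truth$seed))
  invisible(x)
}

#' Generate a phantom cohort for one edema class
#'
#' Produces `n` phantoms with seeds `base_seed .. base_seed + n - 1`. To
#' mimic inter-limb variability, each phantom's class range mass is jittered
#' by a uniform +/-`jitter` (default 0.02) around the shipped profile value
#' before generation (in-range and out-of-range masses rescaled to keep the
#' vector summing to 1); the jitter stream is seeded with `base_seed + n` so
#' it never replays a phantom's own pixel stream.
#'
#' @inheritParams default_class_profile
#' @param n Cohort size (>= 1).
#' @param base_seed First phantom seed.
#' @param jitter Half-width of the per-phantom range-mass jitter.
#' @param ... Passed to [default_class_profile()] (e.g. frame size).
#' @return List of `n` `phantom_image` objects.
#' @export
generate_cohort <- function(edema_class, n, base_seed, jitter = 0.02, ...) {
  if (n < 1L) stop("cohort size must be >= 1")
  u <- with_seed(base_seed + n, stats::runif(n, -jitter, jitter))
  part <- build_canonical_partition()
  lapply(seq_len(n), function(i) {
    spec <- default_class_profile(edema_class, seed = base_seed + i - 1L, ...)
    rng <- resolve_named_range(part, spec$class_range[1L], spec$class_range[2L])
    in_range <- seq(rng$from_idx, rng$to_idx)
    p <- sum(spec$target_masses[in_range])
    p2 <- min(max(p + u[i], 0.01), 0.99)
    spec$target_masses[in_range] <- spec$target_masses[in_range] * p2 / p
    spec$target_masses[-in_range] <- spec$target_masses[-in_range] * (1 - p2) / (1 - p)
    generate_phantom(spec)
  })
}

#' Run the analysis pipeline over a phantom cohort
#'
#' Convenience wrapper used by recovery checks and reporting: each phantom
#' is calibrated to its own fascia band, characterized on its tissue ROI,
#' and classified.
#'
#' @param cohort List of `phantom_image` objects.
#' @param partition An `echo_partition`.
#' @param rule A `classification_rule`.
#' @return A data frame with one row per phantom: `edema_class` (truth),
#'   `seed`, `gsm`, `lake_fraction`, `class_range_mass` (pipeline mass in
#'   the generating class's interval span), and `predicted`.
#' @export
characterize_cohort <- function(cohort,
                                partition = build_canonical_partition(),
                                rule = default_classification_rule()) {
  rows <- lapply(cohort, function(ph) {
    anchor <- calibration_anchor(ph$fascia_roi)
    res <- characterize_and_classify(ph$image, ph$tissue_roi, anchor,
                                     partition, rule)
    rng <- resolve_named_range(partition, ph$truth$class_range[1L],
                               ph$truth$class_range[2L])
    data.frame(edema_class = ph$truth$edema_class,
               seed = ph$truth$seed,
               gsm = res$characterization$gsm,
               lake_fraction = res$characterization$lake_fraction,
               class_range_mass = range_mass(res$characterization$histogram, rng),
               predicted = res$classification$predicted,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
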