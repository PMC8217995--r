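# Independent oracles and small fixture builders shared across test files.

# per-interval tally by explicit bound comparison, one interval at a time
brute_histogram_counts <- function(px, partition) {
  vapply(seq_len(nrow(partition)), function(i) {
    sum(px >= partition$lo[i] & px <= partition$hi[i])
  }, integer(1))
}

# median by explicit sort + mean-of-middles
sort_median <- function(px) {
  s <- sort(px)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

rand_image <- function(h, w) {
  ultrasound_image(matrix(sample(0:255, h * w, replace = TRUE), h, w))
}

full_mask <- function(image) {
  roi_mask(matrix(TRUE, image$height_px, image$width_px))
}

# deterministic pixel vector realizing a 14-interval mass vector: each
# interval's quota is spread evenly over its brightness levels
pixels_from_masses <- function(masses, n, partition = build_canonical_partition()) {
  counts <- round(masses * n)
  counts[1L] <- counts[1L] + (n - sum(counts))  # absorb rounding drift
  unlist(lapply(seq_len(nrow(partition)), function(i) {
    if (counts[i] <= 0L) return(integer(0))
    levels <- partition$lo[i]:partition$hi[i]
    levels[(seq_len(counts[i]) - 1L) %% length(levels) + 1L]
  }))
}

char_from_pixels <- function(px) {
  w <- length(px)
  img <- ultrasound_image(matrix(as.integer(px), 1L, w))
  characterize_roi(img, roi_mask(matrix(TRUE, 1L, w)))
}
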