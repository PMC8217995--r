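part <- build_canonical_partition()
rule <- default_classification_rule()

# build a characterization whose histogram puts `frac` of mass uniformly over
# the named span and the rest uniformly over the remaining brightness levels
char_with_concentration <- function(frac, lo, hi, n = 20000) {
  levels_in <- lo:hi
  levels_out <- setdiff(0:255, levels_in)
  n_in <- round(frac * n)
  px <- c(levels_in[(seq_len(n_in) - 1L) %% length(levels_in) + 1L],
          levels_out[(seq_len(n - n_in) - 1L) %% length(levels_out) + 1L])
  char_from_pixels(px)
}

test_that("group-typical mass concentrations classify to their class", {
  veg <- char_with_concentration(0.8831, 47, 132)
  expect_equal(classify_edema(veg, rule, part)$predicted, "VEG")
  neg <- char_with_concentration(0.8487, 85, 148)
  expect_equal(classify_edema(neg, rule, part)$predicted, "NEG")
  leg <- char_with_concentration(0.7173, 19, 84)
  expect_equal(classify_edema(leg, rule, part)$predicted, "LEG")
  meg <- char_with_concentration(0.7617, 33, 108)
  expect_equal(classify_edema(meg, rule, part)$predicted, "MEG")
})

test_that("a uniform brightness distribution is indeterminate", {
  px <- rep(0:255, each = 4)
  res <- classify_edema(char_from_pixels(px), rule, part)
  expect_equal(res$predicted, "INDETERMINATE")
  # density normalization makes all four scores ~1 for uniform input
  expect_lt(max(res$scores) - min(res$scores), rule$decision_margin)
})

test_that("evidence is the raw range mass and scores are density-normalized", {
  veg <- char_with_concentration(0.8831, 47, 132)
  res <- classify_edema(veg, rule, part)
  rng <- resolve_named_range(part, "hypoechogenic IV", "echogenic III")
  expect_equal(unname(res$evidence["VEG"]), range_mass(veg$histogram, rng))
  expect_equal(unname(res$scores["VEG"]),
               unname(res$evidence["VEG"]) / (132 - 47 + 1) * 256)
  expect_true(all(res$scores >= 0))
})

test_that("boosting the predicted class's range mass never flips the call away", {
  set.seed(8)
  for (rep in 1:20) {
    masses <- as.vector(stats::rgamma(14, 1))
    masses <- masses / sum(masses)
    px <- pixels_from_masses(masses, 5000)
    res <- classify_edema(char_from_pixels(px), rule, part)
    if (res$predicted == "INDETERMINATE") next
    span <- rule$class_ranges[[res$predicted]]
    rng <- resolve_named_range(part, span[1], span[2])
    idx <- rng$from_idx:rng$to_idx
    boosted <- masses
    boosted[idx] <- boosted[idx] * 1.5
    boosted <- boosted / sum(boosted)
    res2 <- classify_edema(char_from_pixels(pixels_from_masses(boosted, 5000)),
                           rule, part)
    expect_equal(res2$predicted, res$predicted)
  }
})

test_that("the lake flag is advisory and thresholded on lake fraction", {
  lakey <- char_from_pixels(c(rep(10L, 300), rep(100L, 700)))
  res <- classify_edema(lakey, rule, part)
  expect_true(res$lake_flag)  # 30% of pixels at or below 40
  dry <- char_from_pixels(rep(100L, 1000))
  expect_false(classify_edema(dry, rule, part)$lake_flag)
})

test_that("the end-to-end pipeline types phantoms by their generating class", {
  veg <- generate_phantom(default_class_profile("VEG", seed = 7))
  res <- characterize_and_classify(veg$image, veg$tissue_roi,
                                   calibration_anchor(veg$fascia_roi),
                                   part, rule, region = "MPL")
  expect_equal(res$classification$predicted, "VEG")
  expect_equal(res$characterization$region, "MPL")

  neg <- generate_phantom(default_class_profile("NEG", seed = 7))
  res_neg <- characterize_and_classify(neg$image, neg$tissue_roi,
                                       calibration_anchor(neg$fascia_roi),
                                       part, rule)
  expect_equal(res_neg$classification$predicted, "NEG")

  # deterministic: the same inputs give identical outputs
  rerun <- characterize_and_classify(neg$image, neg$tissue_roi,
                                     calibration_anchor(neg$fascia_roi),
                                     part, rule)
  expect_identical(rerun, res_neg)
})

test_that("histograms from a different partition are rejected", {
  coarse <- char_from_pixels(rep(100L, 100))
  coarse$histogram$masses <- coarse$histogram$masses[1:5]
  expect_error(classify_edema(coarse, rule, part), "partition mismatch")
})
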