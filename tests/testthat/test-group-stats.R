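test_that("degenerate all-identical groups carry no evidence", {
  vals <- list(VEG = rep(10, 4), LEG = rep(10, 4),
               MEG = rep(10, 4), NEG = rep(10, 4))
  rep_ <- compare_groups(vals)
  expect_equal(rep_$omnibus_p, 1)
  expect_equal(rep_$levene_p, 1)
  expect_true(all(rep_$pairwise_p == 1))
  expect_length(rep_$pairwise_p, 6)
})

test_that("a huge group separation is detected and flagged pairwise", {
  set.seed(12)
  vals <- list(A = rnorm(20, 40, 5), B = rnorm(20, 120, 5))
  rep_ <- compare_groups(vals)
  expect_lt(rep_$omnibus_p, 0.001)
  expect_lt(rep_$pairwise_p[["A-B"]], 0.001)
  expect_equal(rep_$groups$n_limbs, c(20L, 20L))
})

test_that("the variance-homogeneity gate picks the matched test pair", {
  set.seed(13)
  homo <- list(A = rnorm(30, 50, 5), B = rnorm(30, 55, 5), C = rnorm(30, 60, 5))
  r1 <- compare_groups(homo)
  expect_gt(r1$levene_p, 0.05)
  expect_equal(r1$omnibus, "ANOVA")
  expect_equal(r1$posthoc, "Tukey-HSD")

  hetero <- list(A = rnorm(30, 50, 1), B = rnorm(30, 50, 25), C = rnorm(30, 50, 1))
  r2 <- compare_groups(hetero)
  expect_lte(r2$levene_p, 0.05)
  expect_equal(r2$omnibus, "Kruskal-Wallis")
  expect_equal(r2$posthoc, "Dunn")
  expect_true(all(r2$pairwise_p >= 0 & r2$pairwise_p <= 1))
})

test_that("Dunn's z^2 equals the tie-corrected Kruskal-Wallis H for two groups", {
  # independent oracle: with k = 2, the Dunn variance term reduces to the
  # KW tie correction, so the squared z must reproduce stats::kruskal.test
  set.seed(14)
  for (rep in 1:10) {
    y <- c(sample(0:30, 25, replace = TRUE), sample(10:40, 20, replace = TRUE))
    g <- factor(rep(c("a", "b"), c(25, 20)))
    p_dunn <- dunn_test(y, g, adjust = "none")
    kw <- stats::kruskal.test(y, g)
    expect_equal(unname(p_dunn["a-b"]),
                 stats::pchisq(unname(kw$statistic), 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("pairwise results are consistent under group relabeling", {
  set.seed(15)
  vals <- list(A = rnorm(15, 50, 10), B = rnorm(15, 60, 10), C = rnorm(15, 45, 10))
  r1 <- compare_groups(vals)
  r2 <- compare_groups(vals[c("C", "A", "B")])
  expect_equal(r1$omnibus_p, r2$omnibus_p)
  expect_equal(r1$pairwise_p[["A-B"]], r2$pairwise_p[["A-B"]], tolerance = 1e-9)
  expect_equal(r1$pairwise_p[["A-C"]], r2$pairwise_p[["C-A"]], tolerance = 1e-9)
})

test_that("the omnibus test holds its nominal size on null data", {
  set.seed(16)
  rejections <- 0L
  n_sim <- 200L
  for (i in seq_len(n_sim)) {
    vals <- list(A = rnorm(15, 80, 8), B = rnorm(15, 80, 8),
                 C = rnorm(15, 80, 8), D = rnorm(15, 80, 8))
    if (compare_groups(vals)$omnibus_p <= 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / n_sim, 0.01)
  expect_lte(rejections / n_sim, 0.10)
})

test_that("invalid inputs are rejected", {
  expect_error(compare_groups(list(A = 1:5)), "2")
  expect_error(compare_groups(list(A = 1:5, B = 3)), "at least 2 values")
  expect_error(compare_groups(list(A = c(1, NA, 3), B = 1:3)), "non-finite")
  expect_error(compare_groups(list(1:3, 4:6)), "named")
})

test_that("group comparison runs off a written report", {
  set.seed(17)
  records <- unlist(lapply(c("VEG", "NEG"), function(cls) {
    lapply(1:5, function(i) {
      ph <- generate_phantom(default_class_profile(cls, height_px = 96L,
                                                   width_px = 96L,
                                                   seed = i + ifelse(cls == "VEG", 0L, 50L)))
      char <- characterize_roi(calibrate_to_fascia(ph$image,
                                                   calibration_anchor(ph$fascia_roi)),
                               ph$tissue_roi, region = "MML")
      list(limb = limb_record(paste0(cls, i), "left", "MML", group_label = cls),
           characterization = char,
           classification = classify_edema(char))
    })
  }), recursive = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(records, path)
  rep_ <- compare_groups_from_report(path, region = "MML")
  # VEG mass sits near GSM ~86, NEG near ~110: clearly separated
  expect_lt(rep_$omnibus_p, 0.01)
  expect_equal(sort(rep_$groups$group), c("NEG", "VEG"))
})
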