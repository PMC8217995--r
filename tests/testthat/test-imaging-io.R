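test_that("8-bit PNG write/read round trip reproduces the pixel grid exactly", {
  set.seed(11)
  img <- rand_image(32, 48)
  path <- withr::local_tempfile(fileext = ".png")
  write_grayscale_image(img, path)
  back <- load_grayscale_image(path)
  expect_identical(back$pixels, img$pixels)
  expect_equal(back$height_px, 32)
  expect_equal(back$width_px, 48)
})

test_that("16-bit TIFF input is rescaled to [0,255]", {
  path <- withr::local_tempfile(fileext = ".tiff")
  tiff::writeTIFF(matrix(1, 4, 4), path, bits.per.sample = 16L)
  img <- load_grayscale_image(path)
  expect_true(all(img$pixels == 255L))
  # half scale maps near the middle of the 8-bit range
  tiff::writeTIFF(matrix(32768 / 65535, 4, 4), path, bits.per.sample = 16L)
  expect_true(all(abs(load_grayscale_image(path)$pixels - 128L) <= 1L))
})

test_that("colorized RGB frames are rejected, gray-as-RGB is accepted", {
  path <- withr::local_tempfile(fileext = ".png")
  rgb <- array(0.5, dim = c(8, 8, 3))
  rgb[1, 1, 1] <- 1  # R differs from G at one pixel
  png::writePNG(rgb, path)
  expect_error(load_grayscale_image(path), "non-grayscale")

  gray3 <- array(rep(matrix(0:63 / 255, 8, 8), 3), dim = c(8, 8, 3))
  png::writePNG(gray3, path)
  expect_identical(load_grayscale_image(path)$pixels, matrix(0:63, 8, 8))
})

test_that("unsupported or missing inputs fail loudly", {
  expect_error(load_grayscale_image("x.dcm"), "DICOM")
  expect_error(load_grayscale_image("does-not-exist.png"), "not found")
})

test_that("binary mask PNGs load congruent with the image", {
  img <- rand_image(16, 16)
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(1, 16, 16), path)
  roi <- load_roi_mask(path, img)
  expect_equal(roi$n_selected, 256L)

  png::writePNG(matrix(0, 16, 16), path)
  expect_error(load_roi_mask(path, img), "empty ROI")

  png::writePNG(matrix(1, 8, 16), path)
  expect_error(load_roi_mask(path, img), "dimension mismatch")
})

test_that("polygon ROIs rasterize by the pixel-center rule", {
  img <- rand_image(100, 100)
  rect <- matrix(c(0, 0, 0, 10, 10, 10, 10, 0), ncol = 2, byrow = TRUE)
  roi <- roi_from_polygon(rect, img)
  # oracle: brute-force count of pixel centers inside the rectangle
  inside <- 0L
  for (r in 0:99) for (cc in 0:99) {
    if (r + 0.5 > 0 && r + 0.5 < 10 && cc + 0.5 > 0 && cc + 0.5 < 10) {
      inside <- inside + 1L
    }
  }
  expect_equal(inside, 100L)
  expect_equal(roi$n_selected, inside)
  expect_true(all(which(roi$mask, arr.ind = TRUE) <= 10))

  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(vertices = rect), path)
  expect_equal(load_roi_mask(path, img)$n_selected, 100L)
})

test_that("polygon rasterization agrees with an independent point-in-polygon oracle", {
  skip_if_not_installed("pracma")
  set.seed(21)
  img <- rand_image(40, 40)
  for (rep in 1:5) {
    # star-shaped polygon around a random center: simple, non-convex
    k <- 7
    ang <- sort(runif(k, 0, 2 * pi))
    rad <- runif(k, 4, 16)
    ctr <- runif(2, 15, 25)
    verts <- cbind(ctr[1] + rad * sin(ang), ctr[2] + rad * cos(ang))
    roi <- roi_from_polygon(verts, img)
    centers_r <- rep(seq_len(40) - 0.5, times = 40)
    centers_c <- rep(seq_len(40) - 0.5, each = 40)
    oracle <- pracma::inpolygon(centers_r, centers_c, verts[, 1], verts[, 2],
                                boundary = FALSE)
    expect_equal(as.vector(roi$mask), oracle)
  }
})

test_that("reports have one row per record, normalized masses, and stable bytes", {
  set.seed(31)
  records <- lapply(1:7, function(i) {
    img <- rand_image(20, 20)
    char <- characterize_roi(img, full_mask(img), region = "MPL")
    list(limb = limb_record(sprintf("L%02d", i), "left", "MPL",
                            group_label = "VEG"),
         characterization = char,
         classification = classify_edema(char))
  })
  path <- withr::local_tempfile(fileext = ".csv")
  expect_equal(write_report(records, path), 7L)
  df <- read_report(path)
  expect_equal(nrow(df), 7L)
  expect_equal(df$limb_id, sprintf("L%02d", 1:7))  # input order preserved
  mass_cols <- grep("^mass_", names(df))
  expect_length(mass_cols, 14L)
  # columns carry 6-decimal formatting, so the row sum is exact to ~1e-5
  expect_true(all(abs(rowSums(df[, mass_cols]) - 1) < 1e-5))

  path2 <- withr::local_tempfile(fileext = ".csv")
  write_report(records, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
  expect_error(write_report(list(), path), "no records")
})
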