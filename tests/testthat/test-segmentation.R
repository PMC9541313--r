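test_that("maximum projection behaves like a per-pixel maximum", {
  a <- pixel_image(matrix(runif(16 * 16), 16, 16), 1)
  b <- pixel_image(matrix(runif(16 * 16), 16, 16), 1)
  zero <- pixel_image(matrix(0, 16, 16), 1)
  expect_equal(max_project(list(a))$intensities, a$intensities)
  expect_equal(max_project(list(a, zero))$intensities, a$intensities)
  mp <- max_project(list(a, b))$intensities
  expect_true(all(mp >= a$intensities) && all(mp >= b$intensities))
  bad <- pixel_image(matrix(0, 17, 16), 1)
  expect_error(max_project(list(a, bad)), "mismatched")
})

test_that("preprocessing normalizes into [0, 1] and flags constant input", {
  img <- pixel_image(matrix(runif(20 * 20, 0, 4000), 20, 20), 1)
  wp <- preprocess_image(img)
  expect_true(all(wp$intensities >= 0 & wp$intensities <= 1))
  const <- pixel_image(matrix(7, 20, 20), 1)
  wc <- preprocess_image(const)
  expect_true(all(wc$intensities == 0))
  expect_true(isTRUE(attr(wc, "constant_input")))
})

test_that("preprocessed walls are brighter than interiors on clean renders", {
  s <- grid_series(3, 4)
  r <- render_snapshot(s$snapshots[[1]]$cells,
                       render_params(noise_sd = 0))
  wp <- preprocess_image(r$image)
  wall <- prothallus:::cpp_boundary_mask(r$labels$labels)
  interior <- r$labels$labels > 0 & !wall
  expect_gt(mean(wp$intensities[wall]), mean(wp$intensities[interior]))
})

test_that("a clean two-cell render segments into its truth cells", {
  s <- grid_series(1, 2)
  r <- render_snapshot(s$snapshots[[1]]$cells, rp_clean(pixel_size = 0.5))
  seg <- segment_cells(preprocess_image(r$image))
  expect_equal(max(seg$labels), 2)
  m <- match_labels(r$labels, seg)
  expect_equal(nrow(m), 2)
  expect_true(all(m$iou >= 0.95))
})

test_that("a flat wall probability with a mask gives one cell per blob", {
  wp <- pixel_image(matrix(0, 30, 30), 1)
  mask <- matrix(FALSE, 30, 30)
  mask[8:22, 8:22] <- TRUE
  seg <- segment_cells(wp, mask = mask)
  expect_equal(max(seg$labels), 1)
  expect_equal(sum(seg$labels > 0), sum(mask))
  expect_error(segment_cells(wp), "no tissue mask")
})

test_that("segmentation is deterministic bit for bit", {
  s <- grid_series(4, 5, seed = 3)
  r <- render_snapshot(s$snapshots[[1]]$cells, render_params(rng_seed = 8))
  a <- segment_cells(preprocess_image(r$image))
  b <- segment_cells(preprocess_image(r$image))
  expect_identical(a, b)
})

test_that("rotating a render by 90 degrees preserves the cell count", {
  s <- grid_series(4, 5, seed = 4)
  r <- render_snapshot(s$snapshots[[1]]$cells, render_params(rng_seed = 9))
  seg0 <- segment_cells(preprocess_image(r$image))
  rot <- r$image
  rot$intensities <- t(rot$intensities)[ncol(rot$intensities):1, ]
  seg90 <- segment_cells(preprocess_image(rot))
  expect_equal(max(seg90$labels), max(seg0$labels))
})

test_that("segmentation agrees with truth on clean renders of a meristem", {
  s <- grid_series(5, 8, windows = 1, seed = 6)
  r <- render_snapshot(s$snapshots[[2]]$cells, render_params(noise_sd = 0))
  seg <- segment_cells(preprocess_image(r$image))
  ev <- evaluate_segmentation(r$labels, seg)
  expect_gte(ev$match_fraction, 0.99)
  expect_gte(ev$pixel_agreement, 0.95)
})

test_that("cell areas scale with pixel size and conserve totals", {
  m <- matrix(0L, 20, 20)
  m[5:14, 5:14] <- 1L
  expect_equal(quantify_areas(lm_from_matrix(m, 1))$area, 100)
  expect_equal(quantify_areas(lm_from_matrix(m, 0.5))$area, 25)
  s <- grid_series(3, 4)
  r <- render_snapshot(s$snapshots[[1]]$cells, render_params())
  cells <- quantify_areas(r$labels)
  ps <- r$labels$pixel_size
  expect_equal(sum(cells$area), sum(r$labels$labels > 0) * ps^2)
  expect_equal(nrow(cells), max(r$labels$labels))
  # boundary polygons enclose roughly the measured area
  expect_true(all(vapply(cells$boundary, nrow, integer(1)) >= 4))
})

test_that("empty label maps quantify to an empty record table", {
  m <- matrix(0L, 16, 16)
  expect_equal(nrow(quantify_areas(lm_from_matrix(m))), 0)
})

test_that("the area colour map hits its documented endpoints", {
  expect_equal(as.vector(area_colormap(0)), c(0, 0, 1))  # exact blue at 0
  expect_equal(as.vector(area_colormap(1)), c(1, 0, 0))  # exact red at cap
  m <- matrix(0L, 16, 16)
  m[2:6, 2:6] <- 1L   # area 25
  m[9:14, 9:14] <- 2L # area 36
  lm <- lm_from_matrix(m, 1)
  cells <- quantify_areas(lm)
  ov <- colorize_areas(cells, lm, cap = 50)
  expect_equal(attr(ov, "cap"), 50)
  px1 <- ov[3, 3, ]
  expect_equal(px1, as.vector(area_colormap(25 / 50)))
  # area at cap/2 maps to the ramp midpoint
  expect_equal(as.vector(area_colormap(0.5)),
               as.vector(area_colormap(25 / 50)))
  # saturation above the cap
  cells2 <- cells
  cells2$area <- c(10000, 60)
  ov2 <- colorize_areas(cells2, lm, cap = 50)
  expect_equal(ov2[3, 3, ], c(1, 0, 0))
})
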