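test_that("binarization separates particle intensities and is idempotent", {
  sp <- scene_spec(fiber_count = 8, distractor_disks = 3, pore_density = 0.05,
                   pixel_size = 0.0625, seed = 11)
  sim <- simulate_scene(sp)
  mask <- binarize(sim$image, 110)
  expect_identical(mask, sim$mask)

  # already-binary input maps to itself
  bin_img <- micrograph(matrix(as.integer(mask) * 255L, nrow(mask), ncol(mask)),
                        pixel_size = sp$pixel_size)
  expect_identical(binarize(bin_img, 110), mask)

  # all-background image -> empty mask; threshold above the range too
  bg <- micrograph(matrix(20L, 50, 60), pixel_size = 0.1)
  expect_false(any(binarize(bg, 110)))
  expect_false(any(binarize(sim$image, 300)))

  expect_error(binarize(sim$image, NaN), "finite")
  expect_error(micrograph(matrix(20L, 2, 2), 0.1, gain = Inf), "finite")
})

test_that("brightness/contrast transform is applied before thresholding", {
  px <- matrix(c(40L, 100L), 1, 2)
  img <- micrograph(px, 0.1, gain = 2, offset = -30)
  # transformed: 50, 170 -> threshold 110 keeps only the second pixel
  expect_identical(as.vector(binarize(img, 110)), c(FALSE, TRUE))
})

test_that("8-connected labeling keeps diagonal fibers whole and splits true gaps", {
  m <- matrix(FALSE, 6, 6)
  diag(m) <- TRUE            # pure diagonal line
  expect_equal(max(label_components(m)), 1L)
  m2 <- matrix(FALSE, 5, 9)
  m2[1:2, 1:3] <- TRUE
  m2[4:5, 6:9] <- TRUE       # separated by more than one pixel
  expect_equal(max(label_components(m2)), 2L)
})

test_that("extraction returns one measurement per component and partitions area", {
  m <- matrix(FALSE, 40, 40)
  m[5:10, 5:20] <- TRUE
  m[25:35, 30:34] <- TRUE
  parts <- extract_particles(m, 0.5)
  expect_equal(nrow(parts), 2L)
  expect_equal(sum(parts$pixel_count) + attr(parts, "discarded_pixels"), sum(m))

  expect_equal(nrow(extract_particles(matrix(FALSE, 10, 10), 1)), 0L)

  # sub-floor components are discarded but accounted for
  m3 <- matrix(FALSE, 10, 10)
  m3[2, 2:3] <- TRUE                       # 2 px < floor of 4
  m3[6:8, 6:8] <- TRUE
  parts3 <- extract_particles(m3, 1, min_pixels = 4)
  expect_equal(nrow(parts3), 1L)
  expect_equal(attr(parts3, "discarded_pixels"), 2L)
  expect_equal(sum(parts3$pixel_count) + attr(parts3, "discarded_pixels"),
               sum(m3))
})

test_that("a crowded scene of non-overlapping shapes is fully recovered", {
  sp <- scene_spec(field_um = c(128, 96), pixel_size = 0.0625,
                   fiber_count = 30, distractor_disks = 10,
                   distractor_blobs = 10, seed = 21)
  sim <- simulate_scene(sp)
  parts <- extract_particles(binarize(sim$image, 110), sp$pixel_size)
  expect_equal(nrow(parts), 50L)
  expect_equal(nrow(sim$truth), 50L)
})

test_that("Feret measurement matches the analytic rectangle and square", {
  # axis-aligned 96 x 8 px rectangle at 0.03125 um/px
  m <- matrix(FALSE, 120, 20)
  m[11:106, 6:13] <- TRUE
  p <- extract_particles(m, 0.03125)
  expect_equal(p$length_um, 3.0, tolerance = 2 * 0.03125 / 3.0)
  expect_equal(p$width_um, 0.25, tolerance = 1e-9)
  expect_equal(p$aspect_ratio, 12, tolerance = 0.05)
  expect_equal(p$area_um2, 96 * 8 * 0.03125^2, tolerance = 1e-12)

  # single pixel measures one pixel in both directions
  single <- measure_component(3L, 7L, 0.5)
  expect_equal(single$length_um, 0.5)
  expect_equal(single$width_um, 0.5)
  expect_equal(single$aspect_ratio, 1)

  # square: max Feret is the diagonal, min the side -> never a fiber
  k <- 20
  sq <- measure_component(rep(1:k, k), rep(1:k, each = k), 1)
  expect_equal(sq$length_um, k * sqrt(2), tolerance = 2 / (k * sqrt(2)))
  expect_equal(sq$width_um, k, tolerance = 1e-9)
  expect_lt(sq$aspect_ratio, 3)
})

test_that("measurement agrees with the brute-force oracle on rotated shapes", {
  # the same rectangle upright and at 45 degrees
  for (theta in c(0, pi / 4)) {
    msk <- rasterize_shape(60, 60, "rect", 30, 30, 40, 6, theta)
    idx <- which(msk, arr.ind = TRUE)
    meas <- measure_component(idx[, 1], idx[, 2], 1)
    oracle <- brute_feret(idx[, 1], idx[, 2])
    expect_equal(meas$length_um, unname(oracle["max"]), tolerance = 1e-9)
    expect_equal(meas$width_um, unname(oracle["min"]), tolerance = 1e-9)
  }
  up <- rasterize_shape(60, 60, "rect", 30, 30, 40, 6, 0)
  rot <- rasterize_shape(60, 60, "rect", 30, 30, 40, 6, pi / 4)
  iu <- which(up, arr.ind = TRUE); ir <- which(rot, arr.ind = TRUE)
  mu <- measure_component(iu[, 1], iu[, 2], 1)
  mr <- measure_component(ir[, 1], ir[, 2], 1)
  expect_equal(mr$length_um, mu$length_um, tolerance = 2 / mu$length_um)
  expect_equal(mr$width_um, mu$width_um, tolerance = 2 / mu$width_um)
})

test_that("detection is exactly invariant under 90-degree rotation", {
  sp <- scene_spec(fiber_count = 12, distractor_disks = 4,
                   pixel_size = 0.0625, seed = 31)
  sim <- simulate_scene(sp)
  parts <- apply_fiber_criteria(
    extract_particles(binarize(sim$image, 110), sp$pixel_size))
  rot_px <- t(sim$image$pixels)[ncol(sim$image$pixels):1, , drop = FALSE]
  rot_img <- micrograph(rot_px, sp$pixel_size)
  parts_rot <- apply_fiber_criteria(
    extract_particles(binarize(rot_img, 110), sp$pixel_size))
  expect_equal(nrow(parts_rot), nrow(parts))
  expect_equal(sort(parts_rot$length_um), sort(parts$length_um))
  expect_equal(sort(parts_rot$width_um), sort(parts$width_um))
  expect_equal(sum(parts_rot$is_fiber), sum(parts$is_fiber))
})

test_that("fiber criteria use aspect ratio and width but no length floor", {
  df <- data.frame(particle_id = c("a", "b", "c"), fov_id = "f",
                   length_um = c(6, 9, 2), width_um = c(1, 3.5, 0.4),
                   aspect_ratio = c(6, 9 / 3.5, 5),
                   area_um2 = 1, pixel_count = 100L,
                   centroid_row = 0, centroid_col = 0,
                   touches_border = FALSE, stringsAsFactors = FALSE)
  out <- apply_fiber_criteria(df)
  # 6 x 1 um fiber in; 9 x 3.5 um out (AR < 3 and too wide);
  # 2 x 0.4 um in despite being shorter than 5 um
  expect_identical(out$is_fiber, c(TRUE, FALSE, TRUE))

  # border fibers keep their verdict but are not counted by default
  df$touches_border <- c(TRUE, FALSE, FALSE)
  out2 <- apply_fiber_criteria(df)
  expect_identical(out2$is_fiber, c(TRUE, FALSE, TRUE))
  expect_identical(out2$counted, c(FALSE, FALSE, TRUE))
  expect_identical(apply_fiber_criteria(df, include_border = TRUE)$counted,
                   c(TRUE, FALSE, TRUE))
})

test_that("detected fiber count does not drop as pixel size shrinks", {
  sp <- scene_spec(field_um = c(64, 48), pixel_size = 0.16,
                   fiber_count = 25,
                   fiber_width = c(meanlog = log(0.12), sdlog = 0.7),
                   seed = 41)
  truth <- with_fixed_seed(sp$seed, empscan:::draw_scene_truth(sp))
  counts <- vapply(c(0.16, 0.0625, 0.03125), function(px) {
    rend <- render_scene(truth, sp, pixel_size = px)
    parts <- apply_fiber_criteria(extract_particles(binarize(rend$image, 110), px))
    sum(parts$counted)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_lt(counts[1], counts[3]) # sub-pixel fibers appear at 2000X
})
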