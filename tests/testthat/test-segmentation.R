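test_that("ROI extraction zeroes exactly the outside voxels", {
  v <- volume_image(array(100, c(20, 20, 20)))
  all_true <- binary_mask(array(TRUE, c(20, 20, 20)))
  expect_equal(as.vector(extract_region(v, all_true)), as.vector(v))
  all_false <- binary_mask(array(FALSE, c(20, 20, 20)))
  expect_true(all(extract_region(v, all_false) == 0))
  half <- array(FALSE, c(20, 20, 20)); half[1:10, , ] <- TRUE
  out <- extract_region(v, binary_mask(half))
  expect_equal(sum(out == 100), prod(c(10, 20, 20)))
  expect_error(extract_region(v, binary_mask(array(TRUE, c(10, 20, 20)))),
               "shape")
})

test_that("gray-map transformation rescales percentiles to [0, 1]", {
  ramp <- volume_image(array(seq(0, 100, length.out = 40^3), c(40, 40, 40)))
  out <- transform_gray(ramp, 0, 100)
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  expect_lt(abs(mean(out) - 0.5), 0.01)
  expect_warning(res <- transform_gray(volume_image(array(7, c(16, 16, 16)))),
                 "degenerate")
  expect_true(all(res == 0))
  expect_equal(voxel_size(out), voxel_size(ramp))
})

test_that("tubularity enhancement prefers tubes over background and blobs", {
  zero <- volume_image(array(0, c(32, 32, 32)))
  expect_true(all(enhance_vessels(zero) == 0))

  h <- 4.5
  sp <- phantom_spec(grid_shape = c(64, 48, 48), seed = 1)
  ax <- (24 + 0.5) * h
  tn <- tube_network(c(5 * h, ax, ax), c(59 * h, ax, ax), radius_um = 3 * h)
  ras <- rasterize(tn, sp)
  resp <- enhance_vessels(transform_gray(ras$volume, 0, 100),
                          scales_um = h * c(2, 3, 4))
  centre <- resp[15:50, 25, 25]
  bg <- resp[, 5, 5]
  expect_gt(mean(centre), 5 * mean(bg) + 1e-12)

  # solid ball: interior response below the tube centerline response
  ball <- array(0, c(48, 48, 48))
  co <- expand.grid(x = 1:48, y = 1:48, z = 1:48)
  r2 <- (co$x - 24)^2 + (co$y - 24)^2 + (co$z - 24)^2
  ball[r2 <= 100] <- 100
  bresp <- enhance_vessels(transform_gray(volume_image(ball), 0, 100),
                           scales_um = h * c(2, 3, 4))
  interior <- bresp[r2 <= 36]
  expect_lt(mean(interior), mean(centre))
})

test_that("threshold segmentation is exact, monotone and records provenance", {
  v <- array(0, c(20, 20, 20)); v[5:10, 5:10, 5:10] <- 100
  vol <- volume_image(v)
  m <- threshold_segment(vol, "fixed", 50)
  expect_identical(as.vector(m), as.vector(v == 100))
  expect_equal(attr(m, "provenance")$threshold, 50)
  expect_equal(sum(threshold_segment(vol, "fixed", 100)), 0L)

  # monotone: raising the threshold never adds voxels
  set.seed(3)
  noisy <- volume_image(array(stats::rnorm(16^3, 50, 20), c(16, 16, 16)))
  thrs <- c(20, 40, 60, 80)
  counts <- vapply(thrs,
                   function(t) sum(threshold_segment(noisy, "fixed", t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))

  expect_error(threshold_segment(volume_image(array(1, c(16, 16, 16))),
                                 "otsu"), "degenerate")
})

test_that("otsu separates a two-Gaussian mixture almost perfectly", {
  set.seed(11)
  n <- 40^3
  labels_true <- stats::runif(n) < 0.2
  v <- ifelse(labels_true, stats::rnorm(n, 200, 10), stats::rnorm(n, 20, 10))
  vol <- volume_image(array(v, c(40, 40, 40)))
  m <- threshold_segment(vol, "otsu")
  misclassified <- mean(as.vector(m) != labels_true)
  expect_lt(misclassified, 0.01)
})

test_that("region growing honours the homogeneity tolerance", {
  # homogeneous isolated component recovered exactly
  v <- array(0, c(24, 24, 24))
  v[4:8, 4:8, 4:8] <- 100       # component A
  v[15:20, 15:20, 15:20] <- 100 # component B (no seed)
  vol <- volume_image(v)
  mask <- threshold_segment(vol, "fixed", 50)
  grown <- region_grow(mask, vol, seeds = matrix(c(5, 5, 5), 1), tol = 10)
  expect_identical(which(as.logical(grown)), which(v == 100 &
    slice.index(v, 1) <= 8))

  # tol = 0 on noisy data: no growth beyond the seed-connected mask voxels
  set.seed(5)
  nv <- volume_image(array(v + stats::rnorm(length(v), 0, 1), dim(v)))
  g0 <- region_grow(mask, nv, seeds = matrix(c(5, 5, 5), 1), tol = 0)
  lab <- label_components(mask)
  seed_comp <- lab == lab[5, 5, 5]
  expect_true(all(which(as.logical(g0)) %in% which(seed_comp)))

  # gap bridging: a 1-voxel dip splits the threshold mask; growing with a
  # tolerance spanning the dip rejoins it into one component
  tube <- array(0, c(30, 8, 8))
  tube[3:28, 3:5, 3:5] <- 100
  tube[15, , ] <- tube[15, , ] * 0.55 # intensity dip
  tv <- volume_image(tube)
  tm <- threshold_segment(tv, "fixed", 60)
  expect_gt(max(label_components(tm)), 1)
  bridged <- region_grow(tm, tv, seeds = matrix(c(4, 4, 4), 1), tol = 60)
  expect_equal(max(label_components(bridged)), 1)

  expect_warning(region_grow(binary_mask(array(FALSE, dim(v))), vol,
                             seeds = NULL, tol = 1), "no seeds")
  expect_error(region_grow(mask, vol, seeds = matrix(c(99, 1, 1), 1),
                           tol = 1), "outside")
})

test_that("segmentation chain preserves grid metadata", {
  s <- clean_tree_spec(n_levels = 1L, seed = 2L, grid = c(64L, 64L, 64L))
  ph <- simulate_phantom(s)
  m <- segment_vessels(ph$clean_volume)
  expect_equal(dim(m), dim(ph$clean_volume))
  expect_equal(voxel_size(m), voxel_size(ph$clean_volume))
  expect_true(!is.null(attr(m, "provenance")$threshold$threshold))
})
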