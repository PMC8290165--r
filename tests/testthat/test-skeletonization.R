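test_that("a one-voxel-wide line is already a skeleton", {
  ln <- line_skeleton(10)
  out <- skeletonize(binary_mask(array(as.logical(ln), dim(ln)),
                                 voxel_size(ln)))
  expect_identical(as.vector(out), as.vector(ln))
})

test_that("a solid cylinder thins to a single path with two endpoints", {
  h <- 4.5
  sp <- phantom_spec(grid_shape = c(60, 40, 40), seed = 1)
  ax <- (19 + 0.5) * h
  tn <- tube_network(c(3 * h, ax, ax), c(57 * h, ax, ax), radius_um = 3 * h)
  mask <- rasterize(tn, sp)$mask
  sk <- skeletonize(mask)
  # subset of the mask, unit width, one component
  expect_true(all(which(as.logical(sk)) %in% which(as.logical(mask))))
  expect_no_2x2x2_block(sk)
  expect_equal(max(label_components(sk)), 1L)
  cls <- classify_voxels(sk)
  expect_equal(unname(cls$counts["terminal"]), 2L)
  expect_equal(unname(cls$counts["junction"]), 0L)
})

test_that("component count and loops survive thinning", {
  # two disjoint bricks -> two skeleton components
  a <- array(FALSE, c(40, 20, 20))
  a[3:15, 5:9, 5:9] <- TRUE
  a[25:37, 5:9, 5:9] <- TRUE
  sk <- skeletonize(binary_mask(a))
  expect_equal(max(label_components(sk)), 2L)

  # rasterized torus keeps its single loop: cycle rank 1
  tor <- torus_network(c(112.5, 112.5, 112.5), 67.5, 9)
  mask <- rasterize(tor, phantom_spec(grid_shape = c(50, 50, 50),
                                      seed = 1))$mask
  g <- build_graph(skeletonize(mask))
  expect_equal(cycle_rank(g), 1L)

  expect_warning(out <- skeletonize(binary_mask(array(FALSE, c(16, 16, 16)))),
                 "empty")
  expect_equal(sum(out), 0L)
})

test_that("spur pruning removes short arms, is idempotent, keeps components", {
  sk <- y_skeleton(arm = 3)                    # arms of 3 voxels each
  expect_identical(prune_spurs(sk, 0), sk)     # zero threshold = identity

  # Y with two long arms and one short arm: pruning above the short arm's
  # length leaves a single junction-free path
  long_y <- fix_skel(rbind(
    cbind(11:18, 10L, 3L),                       # long +x arm
    cbind(10L - (1:8), 10L + (1:8), 3L),         # long diagonal arm
    cbind(10L - (1:3), 10L - (1:3), 3L),         # short diagonal arm
    c(10L, 10L, 3L)),                            # center
    dm = c(20L, 20L, 6L))
  pruned <- prune_spurs(long_y, 25)
  cls <- classify_voxels(pruned)
  expect_equal(unname(cls$counts["terminal"]), 2L)
  expect_equal(unname(cls$counts["junction"]), 0L)
  expect_equal(max(label_components(pruned)), 1L)

  # idempotence
  expect_identical(prune_spurs(pruned, 25), pruned)

  # a component that is itself a short bare path is never removed
  short_path <- line_skeleton(3)
  expect_identical(prune_spurs(short_path, 100), short_path)
})

test_that("clean tree phantoms keep their terminals and stay acyclic", {
  s <- clean_tree_spec(n_levels = 2L, seed = 17L, grid = c(128L, 128L, 128L))
  net <- generate_tree(s)
  mask <- rasterize(net, s)$mask
  sk <- prune_spurs(skeletonize(mask), 3 * 4.5)
  cls <- classify_voxels(sk)
  n_terminals_truth <- sum(net$nodes$kind %in% c("terminal", "root"))
  expect_equal(unname(cls$counts["terminal"]), n_terminals_truth)
  expect_equal(cycle_rank(build_graph(sk)), 0L)
})
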