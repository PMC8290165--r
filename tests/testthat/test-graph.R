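test_that("voxel classification follows the 26-neighbor rule", {
  cls <- classify_voxels(line_skeleton(10))
  expect_equal(unname(cls$counts["terminal"]), 2L)
  expect_equal(unname(cls$counts["chain"]), 8L)

  iso <- fix_skel(c(5L, 5L, 3L), dm = c(10L, 10L, 6L))
  ci <- classify_voxels(iso)
  expect_equal(unname(ci$counts["singleton"]), 1L)
  expect_equal(ci$n_singletons, 1L)

  cy <- classify_voxels(y_skeleton(3))
  expect_equal(unname(cy$counts["terminal"]), 3L)
  expect_equal(unname(cy$counts["junction"]), 1L)
})

test_that("junction clusters merge to single deterministic nodes", {
  # two 26-adjacent junction voxels -> one bifurcation node, cluster_size 2;
  # arms leave diagonally so they touch only their own centre voxel
  dumbbell <- fix_skel(rbind(
    c(8L, 8L, 3L), c(9L, 8L, 3L),                       # junction pair
    c(7L, 9L, 3L), c(6L, 10L, 3L), c(5L, 11L, 3L),      # NW arm from left
    c(7L, 7L, 3L), c(6L, 6L, 3L), c(5L, 5L, 3L),        # SW arm from left
    c(10L, 9L, 3L), c(11L, 10L, 3L), c(12L, 11L, 3L),   # NE arm from right
    c(10L, 7L, 3L), c(11L, 6L, 3L), c(12L, 5L, 3L)),    # SE arm from right
    dm = c(16L, 16L, 6L))
  lab <- classify_voxels(dumbbell)
  expect_equal(unname(lab$counts["junction"]), 2L)
  nodes <- merge_junction_clusters(lab)
  bif <- nodes$nodes[nodes$nodes$kind == "bifurcation", ]
  expect_equal(nrow(bif), 1L)
  expect_equal(bif$cluster_size, 2L)

  # plus sign: one junction node, four terminals
  np <- merge_junction_clusters(classify_voxels(plus_skeleton(4)))
  expect_equal(sum(np$nodes$kind == "bifurcation"), 1L)
  expect_equal(sum(np$nodes$kind == "terminal"), 4L)

  # determinism of representatives and ids
  a <- merge_junction_clusters(classify_voxels(plus_skeleton(4)))
  expect_identical(a$nodes, np$nodes)
})

test_that("edge tracing recovers paths, stars and multiplicities", {
  g_line <- build_graph(line_skeleton(10))
  expect_equal(nrow(g_line$nodes), 2L)
  expect_equal(nrow(g_line$edges), 1L)
  expect_equal(g_line$edges$chain_voxel_count, 8L)
  expect_equal(g_line$edges$length_um, 9 * 4.5)

  g_y <- build_graph(y_skeleton(3))
  expect_equal(nrow(g_y$nodes), 4L)
  expect_equal(nrow(g_y$edges), 3L)
  expect_equal(sort(g_y$nodes$degree), c(1L, 1L, 1L, 3L))

  g_plus <- build_graph(plus_skeleton(4))
  expect_equal(nrow(g_plus$nodes), 5L)
  expect_equal(nrow(g_plus$edges), 4L)

  # theta: two junctions joined by three chains -> one simple edge of
  # multiplicity 3, cycle rank 2
  g_theta <- build_graph(ring_skeleton(chord = TRUE))
  expect_equal(nrow(g_theta$nodes), 2L)
  expect_equal(nrow(g_theta$edges), 1L)
  expect_equal(g_theta$edges$multiplicity, 3L)
  expect_equal(cycle_rank(g_theta), 2L)

  # pure ring: anchor node with a recorded self-loop, empty simple set
  g_ring <- build_graph(ring_skeleton(chord = FALSE))
  expect_equal(nrow(g_ring$self_loops), 1L)
  expect_equal(nrow(g_ring$edges), 0L)
  expect_equal(cycle_rank(g_ring), 1L)
})

test_that("handshake and forest identities hold on every build", {
  fixtures <- list(line_skeleton(10), y_skeleton(3), plus_skeleton(4),
                   ring_skeleton(TRUE), ring_skeleton(FALSE))
  for (sk in fixtures) {
    g <- build_graph(sk)
    expect_equal(sum(g$nodes$degree), 2L * nrow(g$edges))
  }
  # forest-shaped skeletons: |edges| = |nodes| - |components| exactly
  for (sk in list(line_skeleton(10), y_skeleton(3), plus_skeleton(4))) {
    g <- build_graph(sk)
    expect_equal(sum(g$edges$multiplicity) + nrow(g$self_loops),
                 nrow(g$nodes) - g$n_components)
  }
})

test_that("adjacency matrices are symmetric 0/1 with degree row sums", {
  g2 <- graph_from_edges(2, rbind(c(1, 2)))
  expect_equal(as.matrix(to_adjacency(g2)),
               matrix(c(0, 1, 1, 0), 2, dimnames = list(1:2, 1:2)))
  g3 <- graph_from_edges(3, matrix(integer(0), ncol = 2))
  expect_true(all(as.matrix(to_adjacency(g3)) == 0))
  for (seed in 1:100) {
    g <- random_vascular_graph(sample(3:20, 1), 0.3, seed)
    A <- as.matrix(to_adjacency(g))
    expect_identical(A, t(A))
    expect_true(all(diag(A) == 0))
    expect_equal(unname(rowSums(A)), as.numeric(g$nodes$degree))
  }
})

test_that("graph construction from a clean phantom matches ground truth", {
  s <- clean_tree_spec(n_levels = 2L, seed = 21L, grid = c(96L, 96L, 96L))
  net <- generate_tree(s)
  sk <- prune_spurs(skeletonize(rasterize(net, s)$mask), 3 * 4.5)
  g <- build_graph(sk)
  expect_equal(nrow(g$nodes), nrow(net$nodes))
  expect_equal(nrow(g$edges), nrow(net$edges))
  truth_deg <- table(factor(c(net$edges$u, net$edges$v),
                            levels = net$nodes$id))
  expect_equal(sort(as.integer(truth_deg)), sort(g$nodes$degree))
  # identical rebuild gives identical coordinates and ids
  g2 <- build_graph(sk)
  expect_identical(g$nodes, g2$nodes)
  expect_identical(g$edges, g2$edges)
})
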