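test_that("binary tree node/edge counts follow the closed form", {
  s0 <- phantom_spec(n_levels = 0, seed = 2)
  net0 <- generate_tree(s0)
  expect_equal(nrow(net0$nodes), 2L)
  expect_equal(nrow(net0$edges), 1L)

  # depth-3 full binary tree: 1 root + 7 bifurcations + 8 terminals
  net3 <- generate_tree(clean_tree_spec(n_levels = 3L, seed = 5L,
                                        grid = c(160L, 160L, 160L)))
  expect_equal(nrow(net3$nodes), 16L)
  expect_equal(nrow(net3$edges), 15L)
  expect_equal(sum(net3$nodes$kind == "bifurcation"), 7L)
  expect_equal(sum(net3$nodes$kind == "terminal"), 8L)
  expect_equal(network_components(net3), 1L)
})

test_that("ground-truth networks are forests with consistent geometry", {
  for (seed in c(1, 7, 23)) {
    s <- phantom_spec(n_levels = 4, n_trees = 2, dropout_prob = 0.2,
                      tortuosity_amplitude = 0.2, seed = seed)
    net <- generate_tree(s)
    # forest: edges = nodes - components
    expect_equal(nrow(net$edges),
                 nrow(net$nodes) - network_components(net))
    expect_true(all(net$nodes$radius_um > 0))
    # polylines start/end at incident node positions
    for (k in seq_len(nrow(net$edges))) {
      pl <- net$edges$polyline[[k]]
      un <- net$nodes[net$nodes$id == net$edges$u[k], ]
      vn <- net$nodes[net$nodes$id == net$edges$v[k], ]
      expect_lt(sum(abs(pl[1, ] - c(un$x_um, un$y_um, un$z_um))), 1e-8)
      expect_lt(sum(abs(pl[nrow(pl), ] - c(vn$x_um, vn$y_um, vn$z_um))),
                1e-8)
    }
    # whole network inside the grid
    ext <- s$grid_shape * s$voxel_size_um
    all_pts <- do.call(rbind, net$edges$polyline)
    expect_true(all(all_pts >= 0) && all(sweep(all_pts, 2, ext) <= 0))
  }
})

test_that("same spec and seed give bit-identical phantoms", {
  s <- phantom_preset("tumor_like", seed = 42, grid_shape = c(48, 48, 48))
  a <- simulate_phantom(s)
  b <- simulate_phantom(s)
  expect_identical(a$volume, b$volume)
  expect_identical(a$mask, b$mask)
  expect_identical(a$network$edges$length_um, b$network$edges$length_um)
  s2 <- phantom_preset("tumor_like", seed = 43, grid_shape = c(48, 48, 48))
  expect_false(identical(as.vector(simulate_phantom(s2)$volume),
                         as.vector(a$volume)))
})

test_that("dropout reduces the expected terminal count", {
  n_term <- function(dropout, seed) {
    s <- phantom_spec(n_levels = 5, dropout_prob = dropout, seed = seed,
                      grid_shape = c(160, 160, 160), branch_length_mean = 60,
                      branch_length_sd = 0, tortuosity_amplitude = 0)
    sum(generate_tree(s)$nodes$kind == "terminal")
  }
  with_dropout <- vapply(1:50, function(s) n_term(0.99, s), numeric(1))
  without <- n_term(0, 1)
  expect_lt(mean(with_dropout), without)
})

test_that("undersized grids are rejected", {
  expect_error(phantom_spec(grid_shape = c(8, 8, 8)), "grid")
  expect_error(phantom_spec(root_radius = 200, grid_shape = c(32, 32, 32)),
               "grid too small")
  expect_error(phantom_spec(dropout_prob = 1.0), "dropout_prob")
})

test_that("rasterization draws exact tubes", {
  sp <- phantom_spec(grid_shape = c(60, 52, 52), seed = 1)
  # empty network -> all-zero mask
  empty <- tube_network(c(10, 10, 10), c(20, 10, 10), 5)
  empty$edges <- empty$edges[0, ]
  expect_equal(sum(rasterize(empty, sp)$mask), 0L)

  # axis-aligned cylinder spanning the full grid: voxel count ~ pi r^2 L
  h <- sp$voxel_size_um
  axis_y <- (26 + 0.5) * h # through voxel centres
  tn <- tube_network(c(-2 * h, axis_y, axis_y), c(62 * h, axis_y, axis_y),
                     radius_um = 3 * h)
  m <- rasterize(tn, sp)$mask
  analytic <- pi * 3^2 * 60
  expect_lt(abs(sum(m) - analytic) / analytic, 0.15)

  # a 2-level clean tree rasterizes to one 6-connected component
  net <- generate_tree(clean_tree_spec(n_levels = 2L, seed = 3L,
                                       grid = c(128L, 128L, 128L)))
  mk <- rasterize(net, clean_tree_spec(n_levels = 2L, seed = 3L,
                                       grid = c(128L, 128L, 128L)))$mask
  expect_equal(max(label_components(mk, connectivity = 6)), 1L)
})

test_that("additive noise has the requested spread and determinism", {
  v <- volume_image(array(0, c(100, 100, 100)))
  expect_identical(add_noise(v, 0, seed = 1), v)
  n1 <- add_noise(v, 5, seed = 7)
  expect_lt(abs(stats::sd(n1) - 5) / 5, 0.02) # 1e6 voxels
  expect_identical(n1, add_noise(v, 5, seed = 7))
  expect_error(add_noise(v, -1, seed = 1), "noise_sd")
  clipped <- add_noise(v, 5, seed = 7, clip_range = c(0, 255))
  expect_gte(min(clipped), 0)
})

test_that("phenotype presets separate in scale and tortuosity", {
  n_nodes <- matrix(NA_real_, 10, 2)
  tort <- matrix(NA_real_, 10, 2)
  for (i in 1:10) {
    for (j in 1:2) {
      ph <- c("normal", "tumor_like")[j]
      net <- generate_tree(phantom_preset(ph, seed = 300 + i))
      n_nodes[i, j] <- nrow(net$nodes)
      tort[i, j] <- network_tortuosity(net)
    }
  }
  expect_lt(mean(n_nodes[, 2]), mean(n_nodes[, 1]))
  expect_gt(mean(tort[, 2]), mean(tort[, 1]))
})

test_that("arcade anastomoses add loops only when requested", {
  s <- clean_tree_spec(n_levels = 3L, seed = 9L, grid = c(160L, 160L, 160L))
  net <- generate_tree(s)
  expect_identical(add_anastomoses(net, 0, seed = 1), net)
  arc <- add_anastomoses(net, 1, seed = 1)
  # depth-3 tree has 3 interior sibling pairs (gen-1 and two gen-2 parents)
  expect_equal(nrow(arc$edges), nrow(net$edges) + 3L)
  # loops now present: edges > nodes - components
  expect_gt(nrow(arc$edges), nrow(arc$nodes) - network_components(arc))
})
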