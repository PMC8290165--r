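k4_graph <- function() graph_from_edges(4, t(utils::combn(4, 2)))
star5_graph <- function() graph_from_edges(5, cbind(1, 2:5))
triangle_pendant <- function() {
  graph_from_edges(4, rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4)))
}
path3_graph <- function() graph_from_edges(3, rbind(c(1, 2), c(2, 3)))

test_that("clustering coefficient matches closed forms", {
  expect_equal(clustering_coefficient(k4_graph()), 1)
  expect_equal(clustering_coefficient(star5_graph()), 0)
  expect_equal(clustering_coefficient(triangle_pendant()), 7 / 12)
  expect_error(clustering_coefficient(graph_from_edges(0,
    matrix(integer(0), ncol = 2))), "empty")
})

test_that("average path length matches closed forms in both conventions", {
  expect_equal(as.numeric(average_path_length(path3_graph(),
                                              "connected_pairs")), 4 / 3)
  expect_equal(as.numeric(average_path_length(path3_graph(), "zero_fill")),
               4 / 3)
  expect_equal(as.numeric(average_path_length(k4_graph(), "zero_fill")), 1)
  two_edges <- graph_from_edges(4, rbind(c(1, 2), c(3, 4)))
  expect_equal(as.numeric(average_path_length(two_edges,
                                              "connected_pairs")), 1)
  expect_equal(as.numeric(average_path_length(two_edges, "zero_fill")),
               1 / 3)
  expect_equal(attr(average_path_length(two_edges, "zero_fill"),
                    "convention"), "zero_fill")
  edgeless <- graph_from_edges(3, matrix(integer(0), ncol = 2))
  expect_error(average_path_length(edgeless, "connected_pairs"),
               "reachable")
})

test_that("network structure entropy matches closed forms", {
  for (n in c(3, 5, 8)) {
    cyc <- graph_from_edges(n, cbind(seq_len(n), c(seq_len(n)[-1], 1)))
    ent <- network_structure_entropy(cyc)
    expect_equal(ent$E, log(n))
    expect_equal(ent$NSE, 1)
  }
  s5 <- network_structure_entropy(star5_graph())
  expect_equal(s5$E, 2 * log(2))
  expect_equal(s5$NSE, 2 * log(2) / log(5))
  single <- network_structure_entropy(graph_from_edges(2, rbind(c(1, 2))))
  expect_equal(single$E, log(2))
  expect_equal(single$NSE, 1)
  # degree-0 nodes are excluded with a warning
  with_iso <- graph_from_edges(3, rbind(c(1, 2)))
  expect_warning(e2 <- network_structure_entropy(with_iso), "degree-0")
  expect_equal(e2$n_positive, 2L)
  expect_error(network_structure_entropy(
    graph_from_edges(3, matrix(integer(0), ncol = 2))), "edgeless")
})

test_that("metrics agree with brute-force oracles on random graphs", {
  for (seed in 1:30) {
    n <- sample(4:50, 1)
    g <- random_vascular_graph(n, stats::runif(1, 0.05, 0.4), seed)
    expect_equal(clustering_coefficient(g), oracle_cc(g), tolerance = 1e-12)
    expect_equal(as.numeric(average_path_length(g, "zero_fill")),
                 oracle_apl(g, "zero_fill"), tolerance = 1e-12)
    expect_equal(as.numeric(average_path_length(g, "connected_pairs")),
                 oracle_apl(g, "connected_pairs"), tolerance = 1e-12)
    ent <- suppressWarnings(network_structure_entropy(g))
    oent <- oracle_entropy(g)
    expect_equal(ent$E, oent$E, tolerance = 1e-12)
    expect_equal(ent$NSE, oent$NSE, tolerance = 1e-12)
    expect_true(ent$NSE >= 0 && ent$NSE <= 1)
    expect_true(clustering_coefficient(g) >= 0 &&
                  clustering_coefficient(g) <= 1)
  }
})

test_that("metrics are invariant under node relabeling", {
  g <- random_vascular_graph(20, 0.2, 99)
  perm <- sample(20)
  el <- cbind(perm[g$edges$u], perm[g$edges$v])
  g2 <- graph_from_edges(20, el)
  expect_equal(clustering_coefficient(g), clustering_coefficient(g2))
  expect_equal(as.numeric(average_path_length(g, "zero_fill")),
               as.numeric(average_path_length(g2, "zero_fill")))
  expect_equal(suppressWarnings(network_structure_entropy(g))$NSE,
               suppressWarnings(network_structure_entropy(g2))$NSE)
})

test_that("summarize_network fills every field and survives JSON round trip", {
  sk <- y_skeleton(3)
  g <- build_graph(sk)
  mask <- binary_mask(array(as.logical(sk), dim(sk)), voxel_size(sk))
  rep <- summarize_network(g, mask, specimen_id = "y1")
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$n_nodes, 4L)
  expect_equal(rep$n_edges, 3L)
  expect_equal(rep$n_components, 1L)
  expect_equal(rep$segmented_vascular_volume_um3, sum(sk) * 4.5^3)
  expect_equal(rep$APL, rep$APL_zero_fill)

  tmp <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(rep, tmp)
  back <- read_metrics_json(tmp)
  expect_equal(as.data.frame(back)[, sapply(rep, is.numeric)],
               as.data.frame(rep)[, sapply(rep, is.numeric)],
               tolerance = 1e-12)
})

test_that("volume-node regression recovers exact linear relations", {
  reports <- tibble::tibble(n_nodes = c(2, 4, 6, 8) * 10,
                            segmented_vascular_volume_um3 = c(1, 2, 3, 4) * 10)
  fit <- volume_node_regression(reports)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r, 1)
  # replication invariance of the OLS fit
  fit2 <- volume_node_regression(dplyr::bind_rows(reports, reports))
  expect_equal(fit2$slope, fit$slope)
  expect_equal(fit2$intercept, fit$intercept)
  expect_error(volume_node_regression(
    tibble::tibble(n_nodes = 1:3, segmented_vascular_volume_um3 = rep(5, 3))),
    "constant")
})

test_that("observed volume-node correlation beats its permutation null", {
  set.seed(42)
  vol <- stats::runif(12, 1e5, 1e6)
  nodes <- 50 + 2e-4 * vol + stats::rnorm(12, 0, 10)
  obs <- abs(stats::cor(vol, nodes))
  null_r <- replicate(500, abs(stats::cor(vol, sample(nodes))))
  expect_gt(obs, mean(null_r) + 3 * stats::sd(null_r))
})
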