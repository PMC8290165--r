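#' Clustering coefficient
#'
#' Mean over all N nodes of the local coefficient `2 e_i / (k_i (k_i - 1))`,
#' where `k_i` is the number of neighbors of node i in the simple edge set
#' and `e_i` the number of edges among those neighbors. Nodes with fewer
#' than two neighbors have an undefined local ratio and contribute 0 (the
#' standard convention, which keeps the result in \[0, 1\]). Self-loops and
#' parallel-edge multiplicities are excluded.
#'
#' @param graph a `vascular_graph`.
#' @return clustering coefficient in \[0, 1\].
#' @export
clustering_coefficient <- function(graph) {
  n <- nrow(graph$nodes)
  if (n < 1) stop("empty graph: clustering coefficient undefined")
  if (nrow(graph$edges) == 0) return(0)
  A <- to_adjacency(graph)
  k <- Matrix::rowSums(A)
  # e_i = number of edges among neighbors of i = (A^3)_ii / 2
  tri2 <- Matrix::diag(A %*% A %*% A) # = 2 e_i
  local <- ifelse(k >= 2, tri2 / (k * (k - 1)), 0)
  sum(local) / n
}

#' Average shortest path length
#'
#' Mean of the shortest hop distance `d_ij` (minimum number of edges linking
#' i and j) over unordered node pairs, under two disconnected-pair
#' conventions: `"connected_pairs"` averages over reachable pairs only;
#' `"zero_fill"` divides the sum over reachable pairs by the total pair
#' count `N(N-1)/2`, so unreachable pairs contribute 0. `zero_fill` is the
#' default for the package's phantom reports because heavily fragmented
#' vascular networks otherwise have no single defined mean; the convention
#' used is attached to the result. Hop distances are computed on the simple
#' edge set.
#'
#' @param graph a `vascular_graph` with at least 2 nodes.
#' @param convention `"zero_fill"` or `"connected_pairs"`.
#' @return APL in hops, with attribute `convention`.
#' @export
average_path_length <- function(graph,
                                convention = c("zero_fill",
                                               "connected_pairs")) {
  convention <- match.arg(convention)
  n <- nrow(graph$nodes)
  if (n < 2) stop("APL needs at least two nodes")
  if (nrow(graph$edges) == 0) {
    if (convention == "connected_pairs") {
      stop("no reachable pair: connected-pairs APL undefined")
    }
    return(structure(0, convention = convention))
  }
  d <- igraph::distances(as_igraph(graph))
  ut <- d[upper.tri(d)]
  reach <- is.finite(ut) & ut > 0
  if (convention == "connected_pairs") {
    if (!any(reach)) stop("no reachable pair: connected-pairs APL undefined")
    val <- mean(ut[reach])
  } else {
    val <- sum(ut[reach]) / (n * (n - 1) / 2)
  }
  structure(val, convention = convention)
}

#' Network structure entropy and its normalization
#'
#' Degree-based node-importance entropy: `I_i = D_i / sum(D)` over the
#' degree-positive nodes, `E = -sum(I_i ln I_i)` in nats, and the
#' normalization `NSE = (E - E_min) / (E_max - E_min)` with `E_min = 0` and
#' `E_max = ln N'`, where `N'` counts the degree-positive nodes (the uniform
#' distribution maximizes the entropy at `ln N'`). Degree-0 nodes carry no
#' importance mass (the `0 ln 0 = 0` limit) and are excluded from `N'` with
#' a warning; degrees come from the simple edge set.
#'
#' An alternative star-graph normalization (`E_min` = entropy of the star on
#' N' nodes) is available via `e_min`.
#'
#' @param graph a `vascular_graph` with >= 2 nodes and >= 1 edge.
#' @param e_min `"zero"` (default) or `"star"`.
#' @return list with `E` (nats), `NSE` in \[0, 1\], and `n_positive`.
#' @export
network_structure_entropy <- function(graph, e_min = c("zero", "star")) {
  e_min <- match.arg(e_min)
  n <- nrow(graph$nodes)
  if (n < 2) stop("entropy needs at least two nodes")
  deg <- graph$nodes$degree
  if (sum(deg) == 0) stop("edgeless graph: node importance undefined")
  if (any(deg == 0)) {
    warning(sprintf("%d degree-0 node(s) excluded from the entropy sum",
                    sum(deg == 0)))
  }
  dpos <- deg[deg > 0]
  I <- dpos / sum(dpos)
  E <- -sum(I * log(I))
  np <- length(dpos)
  emax <- log(np)
  emin <- 0
  if (e_min == "star" && np >= 3) {
    s <- 2 * (np - 1)
    Is <- c((np - 1) / s, rep(1 / s, np - 1))
    emin <- -sum(Is * log(Is))
  }
  nse <- if (emax - emin > 0) (E - emin) / (emax - emin) else 1
  list(E = E, NSE = nse, n_positive = np)
}

#' Per-specimen metrics report
#'
#' Computes the three topological metrics plus network-scale summaries for
#' one specimen: clustering coefficient, zero-fill and connected-pairs APL,
#' entropy and NSE, node/edge/component counts, and the segmented vascular
#' volume (foreground voxel count times voxel volume).
#'
#' @param graph a `vascular_graph`.
#' @param mask the specimen's segmented [binary_mask()] (same specimen).
#' @param apl_convention convention reported in the `APL` column.
#' @param specimen_id optional identifier.
#' @return A one-row tibble (`metrics_report`): specimen_id, CC, APL,
#'   apl_convention, APL_connected_pairs, E, NSE, n_nodes, n_edges,
#'   n_self_loops, n_components, segmented_vascular_volume_um3.
#' @export
summarize_network <- function(graph, mask, apl_convention = "zero_fill",
                              specimen_id = NA_character_) {
  n <- nrow(graph$nodes)
  if (n == 0) stop("empty graph: nothing to summarize")
  nse <- network_structure_entropy(graph)
  apl_zero <- average_path_length(graph, "zero_fill")
  apl_conn <- tryCatch(
    as.numeric(average_path_length(graph, "connected_pairs")),
    error = function(e) NA_real_)
  vol <- sum(as.logical(mask)) * voxel_size(mask)^3
  out <- tibble::tibble(
    specimen_id = specimen_id,
    CC = clustering_coefficient(graph),
    APL = if (apl_convention == "zero_fill") as.numeric(apl_zero) else apl_conn,
    apl_convention = apl_convention,
    APL_zero_fill = as.numeric(apl_zero),
    APL_connected_pairs = apl_conn,
    E = nse$E,
    NSE = nse$NSE,
    n_nodes = n,
    n_edges = nrow(graph$edges),
    n_self_loops = nrow(graph$self_loops),
    n_components = graph$n_components,
    segmented_vascular_volume_um3 = vol)
  class(out) <- c("metrics_report", class(out))
  out
}

#' Node count versus segmented vascular volume regression
#'
#' Ordinary least squares of node count on segmented vascular volume across
#' specimens; differences in network scale between specimens are expected to
#' follow this linear relationship.
#'
#' @param reports a tibble of stacked metrics reports (>= 3 rows) with
#'   columns `n_nodes` and `segmented_vascular_volume_um3`.
#' @return A one-row tibble: slope, intercept, r (Pearson), n.
#' @export
volume_node_regression <- function(reports) {
  stopifnot(nrow(reports) >= 3)
  x <- reports$segmented_vascular_volume_um3
  y <- reports$n_nodes
  if (stats::sd(x) == 0) stop("constant predictor: regression undefined")
  fit <- stats::lm(y ~ x)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(x, y),
                 n = length(x))
}

#' Metrics for a whole phantom or specimen, end to end
#'
#' Runs the full analysis chain on a grayscale volume: segmentation
#' ([segment_vessels()]), skeletonization ([skeletonize()] +
#' [prune_spurs()]), graph construction ([build_graph()]) and
#' [summarize_network()].
#'
#' @param volume a [volume_image()].
#' @param roi optional ROI mask.
#' @param scales_um vesselness scales.
#' @param prune_um spur-pruning threshold (um); default 3 voxel edges.
#' @param apl_convention APL reporting convention.
#' @param specimen_id identifier for the report row.
#' @param grow_tol region-growing tolerance (see [segment_vessels()]).
#' @return list with `report` (a `metrics_report` row), `graph`, `mask`,
#'   and `skeleton`.
#' @export
analyze_volume <- function(volume, roi = NULL, scales_um = NULL,
                           prune_um = NULL, apl_convention = "zero_fill",
                           specimen_id = NA_character_, grow_tol = 0.25) {
  h <- voxel_size(volume)
  if (is.null(prune_um)) prune_um <- 3 * h
  mask <- segment_vessels(volume, roi = roi, scales_um = scales_um,
                          grow_tol = grow_tol)
  skel <- skeletonize(mask)
  if (prune_um > 0) skel <- prune_spurs(skel, prune_um)
  graph <- build_graph(skel)
  report <- summarize_network(graph, mask, apl_convention = apl_convention,
                              specimen_id = specimen_id)
  list(report = report, graph = graph, mask = mask, skeleton = skel)
}
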