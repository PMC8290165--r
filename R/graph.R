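#' Classify skeleton voxels by their 26-neighbor count
#'
#' Labels every centerline voxel by the number of centerline voxels among
#' its 26 neighbors: 1 neighbor = terminal, 2 = chain, more than 2 =
#' junction. Isolated voxels (0 neighbors) are labeled terminal singletons
#' and counted separately.
#'
#' @param skeleton a [skeleton_volume()].
#' @return list with `labels` (integer array: 0 background, 1 terminal,
#'   2 chain, 3 junction, 4 singleton), `n_singletons`, `counts` (named
#'   vector) and `voxel_size_um`.
#' @export
classify_voxels <- function(skeleton) {
  m <- array(as.logical(skeleton), dim(skeleton))
  cnt <- cpp_count_neighbors26(m, as.integer(dim(m)))
  lab <- array(0L, dim(m))
  lab[m & cnt == 1] <- 1L
  lab[m & cnt == 2] <- 2L
  lab[m & cnt > 2] <- 3L
  lab[m & cnt == 0] <- 4L
  counts <- c(terminal = sum(lab == 1L), chain = sum(lab == 2L),
              junction = sum(lab == 3L), singleton = sum(lab == 4L))
  list(labels = lab, n_singletons = unname(counts["singleton"]),
       counts = counts, voxel_size_um = voxel_size(skeleton))
}

# lexicographic (z, y, x) order key for tie-breaking, 0-based coords
zyx_order <- function(coords0) {
  order(coords0[, 3], coords0[, 2], coords0[, 1])
}

#' Merge junction voxel clusters into single bifurcation nodes
#'
#' A bifurcation in a voxel skeleton usually consists of several mutually
#' adjacent voxels with more than two neighbors; each 26-connected component
#' of junction voxels becomes one bifurcation node so that one anatomical
#' bifurcation corresponds to one graph node. The representative coordinate
#' is the component voxel nearest its centroid (ties broken by smallest
#' (z, y, x)). Every terminal (and singleton) voxel is its own node.
#'
#' @param labels result of [classify_voxels()].
#' @return list with `nodes` tibble (id, x, y, z 0-based voxel indices,
#'   kind, cluster_size) and `node_grid` (integer array mapping member
#'   voxels to node ids).
#' @export
merge_junction_clusters <- function(labels) {
  lab <- labels$labels
  dm <- dim(lab)
  node_grid <- array(0L, dm)
  rows <- list()
  nid <- 0L

  # junction clusters
  jmask <- lab == 3L
  if (any(jmask)) {
    comp <- cpp_label3d(array(jmask, dm), as.integer(dm), 26L)
    for (cid in seq_len(max(comp))) {
      vox <- which(comp == cid)
      co <- arrayInd(vox, dm) - 1L
      centroid <- colMeans(co)
      d2 <- rowSums(sweep(co, 2, centroid)^2)
      cand <- which(d2 == min(d2))
      if (length(cand) > 1) cand <- cand[zyx_order(co[cand, , drop = FALSE])[1]]
      nid <- nid + 1L
      rows[[nid]] <- tibble::tibble(id = nid, x = co[cand, 1], y = co[cand, 2],
                                    z = co[cand, 3], kind = "bifurcation",
                                    cluster_size = length(vox))
      node_grid[vox] <- nid
    }
  }
  # terminal and singleton voxels, in deterministic (z, y, x) order
  for (lv in c(1L, 4L)) {
    vox <- which(lab == lv)
    if (!length(vox)) next
    co <- arrayInd(vox, dm) - 1L
    ord <- zyx_order(co)
    for (i in ord) {
      nid <- nid + 1L
      rows[[nid]] <- tibble::tibble(id = nid, x = co[i, 1], y = co[i, 2],
                                    z = co[i, 3],
                                    kind = if (lv == 1L) "terminal" else "singleton",
                                    cluster_size = 1L)
      node_grid[vox[i]] <- nid
    }
  }
  nodes <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(id = integer(), x = integer(), y = integer(),
                   z = integer(), kind = character(), cluster_size = integer())
  list(nodes = nodes, node_grid = node_grid)
}

#' Trace edges along two-neighbor chains
#'
#' Walks every maximal chain of two-neighbor voxels between node voxels and
#' emits one edge per chain, with the interior voxel count and the physical
#' length (step lengths 1, sqrt(2), sqrt(3) x voxel size summed over the
#' voxel path including both node endpoints). Directly 26-adjacent nodes
#' yield an edge of chain length 0. Chains that close on the node they left
#' are recorded as self-loops and excluded from the simple edge set;
#' parallel chains between the same node pair collapse to one simple edge
#' with a multiplicity attribute. Chain cycles that touch no node voxel (a
#' pure ring) get one anchor node of kind "cycle" and a recorded self-loop.
#'
#' @param labels result of [classify_voxels()].
#' @param nodes result of [merge_junction_clusters()].
#' @return A `vascular_graph`.
#' @export
trace_edges <- function(labels, nodes) {
  lab <- labels$labels
  dm <- dim(lab)
  h <- labels$voxel_size_um
  node_grid <- nodes$node_grid
  node_tbl <- nodes$nodes
  if (!identical(dim(node_grid), dm)) stop("labels/nodes inconsistent")

  visited <- array(FALSE, dm) # chain voxels already consumed
  edges <- list()
  loops <- list()

  emit <- function(u, v, path_idx) {
    co <- arrayInd(path_idx, dm)
    len <- sum(step_lengths(co, h))
    n_chain <- length(path_idx) - 2L
    if (u == v) {
      loops[[length(loops) + 1L]] <<-
        tibble::tibble(node = u, chain_voxel_count = n_chain, length_um = len)
    } else {
      uu <- min(u, v)
      vv <- max(u, v)
      edges[[length(edges) + 1L]] <<-
        tibble::tibble(u = uu, v = vv,
                       chain_voxel_count = n_chain, length_um = len)
    }
  }

  node_voxels <- which(node_grid > 0L)
  direct_seen <- character(0)
  for (sv in node_voxels) {
    uid <- node_grid[sv]
    for (nb in neighbor_indices26(sv, dm)) {
      if (lab[nb] == 0L) next
      if (node_grid[nb] > 0L) {
        vid <- node_grid[nb]
        if (vid == uid) next # intra-cluster adjacency
        key <- paste(min(uid, vid), max(uid, vid), sep = "-")
        if (key %in% direct_seen) next
        direct_seen <- c(direct_seen, key)
        emit(uid, vid, c(sv, nb))
        # adjust: direct adjacency has 0 interior voxels
        k <- length(edges)
        if (k && edges[[k]]$u == min(uid, vid) && edges[[k]]$v == max(uid, vid))
          edges[[k]]$chain_voxel_count <- 0L
      } else if (lab[nb] == 2L && !visited[nb]) {
        # walk the chain
        path <- c(sv, nb)
        visited[nb] <- TRUE
        prev <- sv
        cur <- nb
        repeat {
          nxt <- setdiff(neighbor_indices26(cur, dm), prev)
          nxt <- nxt[lab[nxt] != 0L]
          # prefer a node voxel ending; otherwise continue on the chain
          endv <- nxt[node_grid[nxt] > 0L]
          if (length(endv)) {
            path <- c(path, endv[1])
            emit(uid, node_grid[endv[1]], path)
            break
          }
          nxt <- nxt[lab[nxt] == 2L & !visited[nxt]]
          if (!length(nxt)) {
            # dangling chain end (shouldn't occur in valid skeletons)
            emit(uid, uid, c(path, path[length(path) - 1]))
            break
          }
          visited[nxt[1]] <- TRUE
          path <- c(path, nxt[1])
          prev <- cur
          cur <- nxt[1]
        }
      }
    }
  }

  # node-free chain cycles (e.g. a torus skeleton): anchor node + self-loop
  remaining <- which(lab == 2L & !visited)
  if (length(remaining)) {
    rm_mask <- array(FALSE, dm)
    rm_mask[remaining] <- TRUE
    comp <- cpp_label3d(rm_mask, as.integer(dm), 26L)
    for (cid in seq_len(max(comp))) {
      vox <- which(comp == cid)
      co <- arrayInd(vox, dm) - 1L
      anchor <- vox[zyx_order(co)[1]]
      nid <- max(node_tbl$id, 0L) + 1L
      aco <- arrayInd(anchor, dm) - 1L
      node_tbl <- dplyr::bind_rows(
        node_tbl,
        tibble::tibble(id = nid, x = aco[1], y = aco[2], z = aco[3],
                       kind = "cycle", cluster_size = 1L))
      node_grid[anchor] <- nid
      # walk the ring from the anchor
      nbs <- neighbor_indices26(anchor, dm)
      nbs <- nbs[!is.na(match(nbs, vox))]
      path <- anchor
      prev <- anchor
      cur <- nbs[1]
      visited[anchor] <- TRUE
      while (cur != anchor) {
        visited[cur] <- TRUE
        path <- c(path, cur)
        nxt <- setdiff(neighbor_indices26(cur, dm), c(prev, path[max(1, length(path) - 1)]))
        nxt <- nxt[!is.na(match(nxt, vox)) & !visited[nxt]]
        if (!length(nxt)) { cur <- anchor; break }
        prev <- cur
        cur <- nxt[1]
      }
      path <- c(path, anchor)
      co2 <- arrayInd(path, dm)
      loops[[length(loops) + 1L]] <-
        tibble::tibble(node = nid, chain_voxel_count = length(path) - 2L,
                       length_um = sum(step_lengths(co2, h)))
    }
  }

  if (length(edges)) {
    # collapse parallel chains into simple edges with multiplicity
    edges_tbl <- dplyr::bind_rows(edges) |>
      dplyr::group_by(.data$u, .data$v) |>
      dplyr::summarise(chain_voxel_count = min(.data$chain_voxel_count),
                       length_um = min(.data$length_um),
                       multiplicity = dplyr::n(), .groups = "drop") |>
      dplyr::arrange(.data$u, .data$v)
  } else {
    edges_tbl <- tibble::tibble(u = integer(), v = integer(),
                                chain_voxel_count = integer(),
                                length_um = numeric(),
                                multiplicity = integer())
  }
  loops_tbl <- if (length(loops)) dplyr::bind_rows(loops) else
    tibble::tibble(node = integer(), chain_voxel_count = integer(),
                   length_um = numeric())

  new_vascular_graph(node_tbl, edges_tbl, loops_tbl, h)
}

new_vascular_graph <- function(nodes, edges, self_loops, voxel_size_um) {
  g <- structure(list(nodes = nodes, edges = edges, self_loops = self_loops,
                      voxel_size_um = voxel_size_um),
                 class = "vascular_graph")
  g$nodes$degree <- graph_degrees(g)
  g$n_components <- graph_component_count(g)
  g
}

# simple-graph degree of every node (self-loops and multiplicity excluded)
graph_degrees <- function(graph) {
  tab <- table(factor(c(graph$edges$u, graph$edges$v),
                      levels = graph$nodes$id))
  as.integer(tab)
}

graph_component_count <- function(graph) {
  if (nrow(graph$nodes) == 0) return(0L)
  igraph::count_components(as_igraph(graph))
}

#' Convert a vascular graph to an igraph object (simple edge set)
#' @param graph a `vascular_graph`.
#' @return An undirected igraph graph with node/edge attributes.
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    d = graph$edges[, c("u", "v", "chain_voxel_count", "length_um",
                        "multiplicity")],
    directed = FALSE,
    vertices = data.frame(name = graph$nodes$id, kind = graph$nodes$kind,
                          x = graph$nodes$x, y = graph$nodes$y,
                          z = graph$nodes$z,
                          cluster_size = graph$nodes$cluster_size))
}

#' Build the vascular graph from a skeleton
#'
#' Wrapper chaining [classify_voxels()], [merge_junction_clusters()] and
#' [trace_edges()].
#'
#' @param skeleton a [skeleton_volume()].
#' @return A `vascular_graph`.
#' @export
build_graph <- function(skeleton) {
  labels <- classify_voxels(skeleton)
  nodes <- merge_junction_clusters(labels)
  trace_edges(labels, nodes)
}

#' Adjacency matrix of the simple edge set
#'
#' Symmetric 0/1 sparse matrix over node ids with zero diagonal.
#'
#' @param graph a `vascular_graph`.
#' @return A sparse symmetric [Matrix::Matrix()].
#' @export
to_adjacency <- function(graph) {
  n <- nrow(graph$nodes)
  ids <- graph$nodes$id
  A <- Matrix::sparseMatrix(
    i = match(graph$edges$u, ids), j = match(graph$edges$v, ids),
    x = 1, dims = c(n, n), symmetric = FALSE)
  A <- A + Matrix::t(A)
  A@x[] <- 1
  dimnames(A) <- list(ids, ids)
  A
}

#' Cycle rank of the reconstructed multigraph
#'
#' `edges - nodes + components` counted on the multigraph, i.e. including
#' recorded self-loops and parallel-chain multiplicities, so a skeletonized
#' ring has cycle rank 1 even though its simple edge set is empty.
#'
#' @param graph a `vascular_graph`.
#' @return integer cycle rank (>= 0).
#' @export
cycle_rank <- function(graph) {
  n_edges <- sum(graph$edges$multiplicity) + nrow(graph$self_loops)
  as.integer(n_edges - nrow(graph$nodes) + graph$n_components)
}

#' @exportS3Method base::print
print.vascular_graph <- function(x, ...) {
  cat(sprintf(
    "<vascular_graph> %d nodes (%d bifurcation, %d terminal), %d edges, %d self-loops, %d components\n",
    nrow(x$nodes), sum(x$nodes$kind == "bifurcation"),
    sum(x$nodes$kind == "terminal"), nrow(x$edges), nrow(x$self_loops),
    x$n_components))
  invisible(x)
}

#' Construct a vascular graph directly from node and edge tables
#'
#' Mainly for tests and for analysing externally supplied graphs: builds the
#' same `vascular_graph` structure the skeleton pipeline produces from a
#' simple edge list (undirected; duplicate rows collapse to multiplicity,
#' u == v rows become recorded self-loops).
#'
#' @param n_nodes number of nodes (ids 1..n_nodes).
#' @param edge_list two-column matrix/data frame of node id pairs.
#' @param voxel_size_um voxel size tag (default 1).
#' @return A `vascular_graph`.
#' @export
graph_from_edges <- function(n_nodes, edge_list, voxel_size_um = 1) {
  el <- matrix(as.integer(as.matrix(edge_list)), ncol = 2)
  stopifnot(all(el >= 1), all(el <= n_nodes))
  nodes <- tibble::tibble(id = seq_len(n_nodes), x = 0L, y = 0L,
                          z = seq_len(n_nodes) - 1L, kind = "terminal",
                          cluster_size = 1L)
  self <- el[, 1] == el[, 2]
  loops_tbl <- tibble::tibble(node = el[self, 1],
                              chain_voxel_count = 0L,
                              length_um = 0)
  el <- el[!self, , drop = FALSE]
  if (nrow(el)) {
    u <- pmin(el[, 1], el[, 2]); v <- pmax(el[, 1], el[, 2])
    edges_tbl <- tibble::tibble(u = u, v = v) |>
      dplyr::group_by(.data$u, .data$v) |>
      dplyr::summarise(multiplicity = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(chain_voxel_count = 0L, length_um = 1) |>
      dplyr::select("u", "v", "chain_voxel_count", "length_um",
                    "multiplicity") |>
      dplyr::arrange(.data$u, .data$v)
  } else {
    edges_tbl <- tibble::tibble(u = integer(), v = integer(),
                                chain_voxel_count = integer(),
                                length_um = numeric(),
                                multiplicity = integer())
  }
  new_vascular_graph(nodes, edges_tbl, loops_tbl, voxel_size_um)
}
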