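# Independent brute-force oracles for the topological metrics, plus small
# voxel fixtures. These deliberately share no code with the package
# implementation: dense adjacency, explicit loops, BFS by hand.

oracle_adjacency <- function(graph) {
  n <- nrow(graph$nodes)
  A <- matrix(0L, n, n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- match(graph$edges$u[k], graph$nodes$id)
    j <- match(graph$edges$v[k], graph$nodes$id)
    A[i, j] <- 1L
    A[j, i] <- 1L
  }
  A
}

# triangle enumeration per node
oracle_cc <- function(graph) {
  A <- oracle_adjacency(graph)
  n <- nrow(A)
  total <- 0
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1L)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a < b && A[nb[a], nb[b]] == 1L) e <- e + 1
      }
    }
    total <- total + 2 * e / (k * (k - 1))
  }
  total / n
}

# all-pairs hop distances by explicit BFS
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      for (nb in which(A[cur, ] == 1L)) {
        if (is.infinite(dist[nb])) {
          dist[nb] <- dist[cur] + 1
          queue <- c(queue, nb)
        }
      }
    }
    D[s, ] <- dist
  }
  D
}

oracle_apl <- function(graph, convention) {
  A <- oracle_adjacency(graph)
  D <- oracle_distances(A)
  n <- nrow(A)
  vals <- c()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) vals <- c(vals, D[i, j])
    }
  }
  reach <- vals[is.finite(vals)]
  if (convention == "connected_pairs") mean(reach)
  else sum(reach) / (n * (n - 1) / 2)
}

oracle_entropy <- function(graph) {
  A <- oracle_adjacency(graph)
  deg <- rowSums(A)
  deg <- deg[deg > 0]
  I <- deg / sum(deg)
  E <- 0
  for (p in I) E <- E - p * log(p)
  list(E = E, NSE = E / log(length(I)))
}

# random simple graph as a vascular_graph, seeded
random_vascular_graph <- function(n, p, seed) {
  set.seed(seed)
  el <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(el)) < p
  el <- el[keep, , drop = FALSE]
  if (nrow(el) == 0) el <- matrix(c(1L, 2L), 1) # ensure >= 1 edge
  graph_from_edges(n, el)
}

# ---------------------------------------------------------------------------
# voxel fixtures (logical arrays); h = voxel size tag

fix_skel <- function(coords, dm = NULL, h = 4.5) {
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 3, byrow = TRUE)
  storage.mode(coords) <- "integer"
  dimnames(coords) <- NULL
  if (is.null(dm)) dm <- apply(coords, 2, max) + 2L
  a <- array(FALSE, dm)
  a[coords] <- TRUE
  skeleton_volume(a, h)
}

# straight x-aligned line of n voxels starting at (2,2,2)
line_skeleton <- function(n, h = 4.5) {
  fix_skel(cbind(2:(n + 1), 2L, 2L), dm = c(n + 2L, 4L, 4L), h = h)
}

# Y: center with three straight arms (east, up-diagonals)
y_skeleton <- function(arm = 3L, h = 4.5) {
  c0 <- c(10L, 10L, 3L)
  coords <- c0
  for (i in seq_len(arm)) {
    coords <- rbind(coords,
                    c0 + c(i, 0L, 0L),      # +x
                    c0 + c(-i, i, 0L),      # diagonal
                    c0 + c(-i, -i, 0L))     # other diagonal
  }
  fix_skel(coords, dm = c(20L, 20L, 6L), h = h)
}

# plus sign: 4 straight arms crossing at one voxel
plus_skeleton <- function(arm = 4L, h = 4.5) {
  c0 <- c(10L, 10L, 3L)
  coords <- c0
  for (i in seq_len(arm)) {
    coords <- rbind(coords, c0 + c(i, 0L, 0L), c0 - c(i, 0L, 0L),
                    c0 + c(0L, i, 0L), c0 - c(0L, i, 0L))
  }
  fix_skel(coords, dm = c(20L, 20L, 6L), h = h)
}

# stadium-shaped voxel ring in the z=3 plane (diagonal corners so every ring
# voxel has exactly 2 neighbors), optionally with a chord -> theta shape
ring_skeleton <- function(chord = FALSE, h = 4.5) {
  coords <- rbind(
    cbind(5:11, 4L), cbind(5:11, 12L),               # top and bottom runs
    c(12L, 5L), c(13L, 6L), cbind(13L, 7:10), c(12L, 11L),   # right cap
    c(4L, 5L), c(3L, 6L), cbind(3L, 7:10), c(4L, 11L))       # left cap
  if (chord) coords <- rbind(coords, cbind(4:12, 8L))
  fix_skel(cbind(coords, 3L), dm = c(17L, 17L, 6L), h = h)
}

expect_no_2x2x2_block <- function(skel) {
  a <- array(as.logical(skel), dim(skel))
  d <- dim(a)
  blk <- a[1:(d[1] - 1), 1:(d[2] - 1), 1:(d[3] - 1)] &
    a[2:d[1], 1:(d[2] - 1), 1:(d[3] - 1)] &
    a[1:(d[1] - 1), 2:d[2], 1:(d[3] - 1)] &
    a[2:d[1], 2:d[2], 1:(d[3] - 1)] &
    a[1:(d[1] - 1), 1:(d[2] - 1), 2:d[3]] &
    a[2:d[1], 1:(d[2] - 1), 2:d[3]] &
    a[1:(d[1] - 1), 2:d[2], 2:d[3]] &
    a[2:d[1], 2:d[2], 2:d[3]]
  testthat::expect_false(any(blk))
}

# clean single-tree spec used by recovery tests (branch separation and
# lengths chosen so thinning recovers the exact topology)
clean_tree_spec <- function(n_levels = 3L, seed = 11L,
                            grid = c(128L, 128L, 128L)) {
  phantom_spec(grid_shape = grid, n_levels = n_levels, dropout_prob = 0,
               tortuosity_amplitude = 0.05, branch_length_mean = 110,
               branch_length_sd = 8, root_radius = 13.5, radius_taper = 0.8,
               seed = seed)
}
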