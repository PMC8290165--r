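#' Specification of a synthetic vascular phantom
#'
#' Parametric description of a contrast-filled hepatic vascular tree phantom:
#' bright tubular trees over dark parenchyma on an isotropic voxel grid.
#' Two documented phenotype presets emulate the qualitative contrast between
#' healthy liver vasculature (even, hierarchical, low tortuosity, arcaded)
#' and tumour vasculature (sparse, tortuous, dilated, fragmented).
#'
#' @details
#' Branching is strictly dichotomous: the trunk (level 0) bifurcates into two
#' children per level up to `n_levels`, so with `dropout_prob = 0` and no
#' boundary clipping the tree is a full binary tree with `2^(n_levels+1) - 1`
#' edges. Each non-trunk branch is independently deleted (with its whole
#' subtree) with probability `dropout_prob`, modelling necrotic/unperfused
#' regions. `tortuosity_amplitude` displaces branch centerlines by a half-sine
#' bow of that amplitude relative to the branch length, plus a smaller
#' second-harmonic wiggle. Branches are clipped (shortened) at the grid
#' boundary rather than rejected, mirroring excised-organ truncation.
#'
#' Fields beyond the minimal tree description:
#' \describe{
#'   \item{n_trees}{number of independent root trees in one volume
#'     (a perfused organ sample typically contains several disconnected
#'     subtrees; roots are spread along the x axis on the low-z face).}
#'   \item{arcade_frac}{fraction of eligible interior bifurcations that
#'     receive an arcade anastomosis (see [add_anastomoses()]); loops are
#'     added by that separate step, never by [generate_tree()] itself.}
#'   \item{radius_jitter_sd}{SD of a per-branch lognormal radius multiplier
#'     (models the abnormal dilation of tumour vessels).}
#'   \item{branch_length_taper}{multiplicative length decay per level.}
#' }
#'
#' @param grid_shape integer vector `(nx, ny, nz)`, all >= 16.
#' @param voxel_size_um isotropic voxel edge (micrometres).
#' @param root_position optional n_trees x 3 matrix of root positions (um);
#'   default places roots near the low-z face, spread along x.
#' @param n_trees number of independent trees.
#' @param n_levels branching depth (0 = unbranched trunk).
#' @param branch_length_mean,branch_length_sd trunk branch length (um).
#' @param branch_length_taper per-level length decay factor.
#' @param root_radius trunk radius (um), > 0.
#' @param radius_taper per-level radius factor in (0, 1].
#' @param radius_jitter_sd per-branch lognormal radius jitter SD.
#' @param bifurcation_angle_mean mean full angle between the two children
#'   (degrees).
#' @param angle_sd SD of the per-child half-angle (degrees).
#' @param tortuosity_amplitude centerline bow amplitude relative to branch
#'   length (>= 0).
#' @param dropout_prob probability in \[0, 1) of deleting each non-trunk
#'   subtree.
#' @param arcade_frac fraction of eligible bifurcations given an arcade loop.
#' @param phenotype_label "normal" or "tumor_like".
#' @param foreground_intensity vessel intensity in the rasterized volume.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return A `phantom_spec` object (validated list).
#' @seealso [phantom_preset()] for the documented phenotype defaults.
#' @export
phantom_spec <- function(grid_shape = c(128, 96, 64),
                         voxel_size_um = 4.5,
                         root_position = NULL,
                         n_trees = 1L,
                         n_levels = 4L,
                         branch_length_mean = 70,
                         branch_length_sd = 7,
                         branch_length_taper = 0.85,
                         root_radius = 13.5,
                         radius_taper = 0.8,
                         radius_jitter_sd = 0,
                         bifurcation_angle_mean = 65,
                         angle_sd = 6,
                         tortuosity_amplitude = 0.05,
                         dropout_prob = 0,
                         arcade_frac = 0,
                         phenotype_label = c("normal", "tumor_like"),
                         foreground_intensity = 100,
                         noise_sd = 0,
                         seed = 1L) {
  phenotype_label <- match.arg(phenotype_label)
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_size_um = voxel_size_um,
               root_position = root_position,
               n_trees = as.integer(n_trees),
               n_levels = as.integer(n_levels),
               branch_length_mean = branch_length_mean,
               branch_length_sd = branch_length_sd,
               branch_length_taper = branch_length_taper,
               root_radius = root_radius,
               radius_taper = radius_taper,
               radius_jitter_sd = radius_jitter_sd,
               bifurcation_angle_mean = bifurcation_angle_mean,
               angle_sd = angle_sd,
               tortuosity_amplitude = tortuosity_amplitude,
               dropout_prob = dropout_prob,
               arcade_frac = arcade_frac,
               phenotype_label = phenotype_label,
               foreground_intensity = foreground_intensity,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (length(s$grid_shape) != 3 || any(s$grid_shape < 16)) {
    stop("grid_shape must be three integers, all >= 16")
  }
  if (s$root_radius <= 0) stop("root_radius must be > 0")
  if (s$radius_taper <= 0 || s$radius_taper > 1) {
    stop("radius_taper must lie in (0, 1]")
  }
  if (s$dropout_prob < 0 || s$dropout_prob >= 1) {
    stop("dropout_prob must lie in [0, 1)")
  }
  if (s$arcade_frac < 0 || s$arcade_frac > 1) {
    stop("arcade_frac must lie in [0, 1]")
  }
  if (s$tortuosity_amplitude < 0) stop("tortuosity_amplitude must be >= 0")
  if (s$noise_sd < 0) stop("noise_sd must be >= 0")
  if (s$n_levels < 0) stop("n_levels must be >= 0")
  if (s$n_trees < 1) stop("n_trees must be >= 1")
  ext <- s$grid_shape * s$voxel_size_um
  margin <- s$root_radius + 2 * s$voxel_size_um
  if (any(ext <= 2 * margin)) {
    stop("grid too small to contain the root radius with a safety margin")
  }
  invisible(TRUE)
}

#' Documented phenotype presets
#'
#' Default phantom specifications for the two phenotypes. `normal`: three
#' hierarchical, low-tortuosity trees with regular arcade anastomoses
#' between sibling bifurcations (the organized, evenly distributed pattern of
#' healthy liver). `tumor_like`: a single sparse tree with subtree dropout,
#' high tortuosity, dilated and irregular radii, and almost no arcading
#' (irregular morphology with abnormal expansion and distortion, sparse
#' vessels from necrosis).
#'
#' @param phenotype "normal" or "tumor_like".
#' @param seed integer seed.
#' @param grid_shape grid dimensions `(nx, ny, nz)`.
#' @param noise_sd additive noise SD (default 10, i.e. 10% of the foreground
#'   intensity 100).
#' @return A `phantom_spec`.
#' @export
phantom_preset <- function(phenotype = c("normal", "tumor_like"),
                           seed = 1L,
                           grid_shape = c(128, 96, 64),
                           noise_sd = 10) {
  phenotype <- match.arg(phenotype)
  if (phenotype == "normal") {
    phantom_spec(grid_shape = grid_shape,
                 n_trees = 4L, n_levels = 4L,
                 branch_length_mean = 55, branch_length_sd = 5,
                 branch_length_taper = 0.8,
                 root_radius = 13.5, radius_taper = 0.85,
                 radius_jitter_sd = 0,
                 bifurcation_angle_mean = 60, angle_sd = 5,
                 tortuosity_amplitude = 0.05,
                 dropout_prob = 0, arcade_frac = 0.5,
                 phenotype_label = "normal",
                 noise_sd = noise_sd, seed = seed)
  } else {
    phantom_spec(grid_shape = grid_shape,
                 n_trees = 1L, n_levels = 5L,
                 branch_length_mean = 70, branch_length_sd = 14,
                 branch_length_taper = 0.85,
                 root_radius = 15, radius_taper = 0.85,
                 radius_jitter_sd = 0.15,
                 bifurcation_angle_mean = 65, angle_sd = 14,
                 tortuosity_amplitude = 0.35,
                 dropout_prob = 0.3, arcade_frac = 0.05,
                 phenotype_label = "tumor_like",
                 noise_sd = noise_sd, seed = seed)
  }
}

unit <- function(v) v / sqrt(sum(v^2))

# random unit vector perpendicular to d (consumes RNG)
random_perp <- function(d) {
  repeat {
    r <- stats::rnorm(3)
    p <- r - sum(r * d) * d
    n <- sqrt(sum(p^2))
    if (n > 1e-8) return(p / n)
  }
}

# polyline from p to q with half-sine bow + second harmonic, amplitude
# relative to segment length; endpoints fixed
make_polyline <- function(p, q, tort_amp, step_um) {
  len <- sqrt(sum((q - p)^2))
  m <- max(2L, as.integer(ceiling(len / step_um)) + 1L)
  t <- seq(0, 1, length.out = m)
  base <- outer(1 - t, p) + outer(t, q)
  if (tort_amp > 0 && len > 0) {
    d <- unit(q - p)
    p1 <- random_perp(d)
    p2 <- unit(pracma::cross(d, p1))
    phase <- stats::runif(1, 0, 2 * pi)
    a1 <- tort_amp * len
    a2 <- 0.4 * tort_amp * len
    base <- base +
      outer(a1 * sin(pi * t), p1) +
      outer(a2 * sin(2 * pi * t + phase) * sin(pi * t), p2)
  }
  colnames(base) <- c("x", "y", "z")
  base
}

polyline_length <- function(pl) {
  if (nrow(pl) < 2) return(0)
  sum(sqrt(rowSums(diff(pl)^2)))
}

# clip polyline to the axis-aligned box [lo, hi]; returns possibly truncated
# polyline (NULL if nothing inside from the start)
clip_polyline <- function(pl, lo, hi) {
  inside <- function(p) all(p >= lo) && all(p <= hi)
  if (!inside(pl[1, ])) return(NULL)
  for (i in 2:nrow(pl)) {
    if (!inside(pl[i, ])) {
      a <- pl[i - 1, ]; b <- pl[i, ]
      # binary search for the boundary crossing
      tlo <- 0; thi <- 1
      for (k in 1:25) {
        tm <- (tlo + thi) / 2
        if (inside(a + tm * (b - a))) tlo <- tm else thi <- tm
      }
      return(rbind(pl[seq_len(i - 1), , drop = FALSE], a + tlo * (b - a)))
    }
  }
  pl
}

#' Generate a ground-truth vascular tree (forest)
#'
#' Recursive dichotomous branching from each root per the phantom
#' specification. Branches are clipped at the grid boundary; each non-trunk
#' branch is deleted (with its subtree) with probability `dropout_prob`.
#' Pass-through nodes left by single-child survival are contracted so the
#' abstract graph contains only root/bifurcation/terminal nodes and is a
#' forest. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A `vascular_network`: list with tibbles `nodes`
#'   (id, x_um, y_um, z_um, radius_um, kind) and `edges`
#'   (u, v, radius_um, length_um, polyline list-column), plus the spec.
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  withr::with_seed(spec$seed, generate_tree_impl(spec))
}

generate_tree_impl <- function(spec) {
  h <- spec$voxel_size_um
  ext <- spec$grid_shape * h
  env <- new.env()
  env$nodes <- list()
  env$edges <- list()
  env$next_id <- 1L

  add_node <- function(pos, radius) {
    id <- env$next_id
    env$next_id <- id + 1L
    env$nodes[[id]] <- list(id = id, x_um = pos[1], y_um = pos[2],
                            z_um = pos[3], radius_um = radius)
    id
  }
  add_edge <- function(u, v, radius, pl) {
    env$edges[[length(env$edges) + 1L]] <-
      list(u = u, v = v, radius_um = radius,
           length_um = polyline_length(pl), polyline = list(pl))
  }

  roots <- spec$root_position
  if (is.null(roots)) {
    # spread roots on a near-square raster over the low-z face so separate
    # trees occupy separate perfusion territories
    zx <- spec$root_radius + 2 * h
    t <- spec$n_trees
    ncol_r <- ceiling(sqrt(t))
    nrow_r <- ceiling(t / ncol_r)
    ij <- expand.grid(i = seq_len(ncol_r), j = seq_len(nrow_r))[seq_len(t), ]
    roots <- cbind(ext[1] * (ij$i - 0.5) / ncol_r,
                   ext[2] * (ij$j - 0.5) / nrow_r,
                   rep(zx, t))
  } else {
    roots <- matrix(roots, ncol = 3)
  }
  if (nrow(roots) != spec$n_trees) {
    stop("root_position must supply one row per tree")
  }

  build <- function(pos, dir, radius, level, parent_id) {
    len <- spec$branch_length_mean * spec$branch_length_taper^level
    len <- len + stats::rnorm(1, 0, spec$branch_length_sd *
                                spec$branch_length_taper^level)
    len <- max(len, 0.3 * spec$branch_length_mean *
                 spec$branch_length_taper^level)
    q <- pos + len * dir
    pl <- make_polyline(pos, q, spec$tortuosity_amplitude, step_um = 2 * h)
    lo <- rep(radius + h, 3)
    hi <- ext - (radius + h)
    pl <- clip_polyline(pl, lo, hi)
    if (is.null(pl) || nrow(pl) < 2 || polyline_length(pl) < h) {
      return(invisible(NULL)) # branch entirely outside: dropped
    }
    clipped <- sqrt(sum((pl[nrow(pl), ] - q)^2)) > 1e-6
    end_pos <- pl[nrow(pl), ]
    vid <- add_node(end_pos, radius)
    add_edge(parent_id, vid, radius, pl)
    if (!clipped && level < spec$n_levels) {
      d <- unit(end_pos - pl[max(1, nrow(pl) - 2), ])
      p1 <- random_perp(d)
      for (sgn in c(1, -1)) {
        half <- (spec$bifurcation_angle_mean / 2 +
                   stats::rnorm(1, 0, spec$angle_sd)) * pi / 180
        half <- min(max(half, 0.1), pi / 2.2)
        cdir <- unit(cos(half) * d + sin(half) * sgn * p1)
        crad <- radius * spec$radius_taper
        if (spec$radius_jitter_sd > 0) {
          crad <- crad * exp(stats::rnorm(1, 0, spec$radius_jitter_sd))
        }
        crad <- max(crad, 0.8 * h)
        # dropout applies to every non-trunk branch
        if (stats::runif(1) >= spec$dropout_prob) {
          build(end_pos, cdir, crad, level + 1L, vid)
        }
      }
    }
    invisible(NULL)
  }

  centre <- ext / 2
  for (i in seq_len(spec$n_trees)) {
    rp <- roots[i, ]
    if (any(rp < spec$root_radius) || any(rp > ext - spec$root_radius)) {
      stop("grid too small to contain the root radius at the root position")
    }
    tilt <- c((centre[1] - rp[1]) / ext[3], (centre[2] - rp[2]) / ext[3], 1)
    dir <- unit(unit(tilt) * c(0.25, 0.25, 1) + stats::rnorm(3, 0, 0.03))
    rid <- add_node(rp, spec$root_radius)
    build(rp, dir, spec$root_radius, 0L, rid)
  }

  net <- finalize_network(env, spec)
  contract_passthrough(net)
}

finalize_network <- function(env, spec) {
  nodes <- dplyr::bind_rows(lapply(env$nodes, tibble::as_tibble))
  edges <- dplyr::bind_rows(lapply(env$edges, tibble::as_tibble))
  structure(list(nodes = nodes, edges = edges, spec = spec),
            class = "vascular_network")
}

# contract non-root degree-2 pass-through nodes (single-child survival after
# dropout or clipping) by splicing their two incident edges
contract_passthrough <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  roots <- root_ids(net)
  repeat {
    deg <- table(factor(c(edges$u, edges$v), levels = nodes$id))
    mid <- nodes$id[deg == 2 & !(nodes$id %in% roots)]
    # only contract nodes whose two incidences are distinct edges u->v, v->w
    if (length(mid) == 0) break
    m <- mid[1]
    idx <- which(edges$u == m | edges$v == m)
    if (length(idx) != 2) { roots <- c(roots, m); next } # self-loop guard
    e1 <- edges[idx[1], ]; e2 <- edges[idx[2], ]
    # orient e1 to end at m, e2 to start at m
    p1 <- e1$polyline[[1]]; p2 <- e2$polyline[[1]]
    if (e1$u == m) { p1 <- p1[rev(seq_len(nrow(p1))), , drop = FALSE]; a <- e1$v } else a <- e1$u
    if (e2$v == m) { p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]; b <- e2$u } else b <- e2$v
    pl <- rbind(p1, p2[-1, , drop = FALSE])
    newe <- tibble::tibble(u = a, v = b,
                           radius_um = min(e1$radius_um, e2$radius_um),
                           length_um = polyline_length(pl),
                           polyline = list(pl))
    edges <- dplyr::bind_rows(edges[-idx, ], newe)
    nodes <- nodes[nodes$id != m, ]
  }
  nodes$kind <- node_kinds(nodes, edges, roots)
  structure(list(nodes = nodes, edges = edges, spec = net$spec),
            class = "vascular_network")
}

root_ids <- function(net) {
  # roots are nodes that never appear as an edge target (v)
  setdiff(net$nodes$id, net$edges$v)
}

node_kinds <- function(nodes, edges, roots) {
  deg <- table(factor(c(edges$u, edges$v), levels = nodes$id))
  kind <- ifelse(deg >= 3, "bifurcation",
                 ifelse(deg == 1, "terminal", "terminal"))
  kind[deg == 0] <- "terminal"
  kind[nodes$id %in% roots] <- "root"
  as.character(kind)
}

#' @exportS3Method base::print
print.vascular_network <- function(x, ...) {
  cat(sprintf("<vascular_network> %d nodes, %d edges, total length %.0f um\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length_um)))
  invisible(x)
}

#' Number of abstract connected components of a ground-truth network
#' @param network a `vascular_network`.
#' @return integer component count.
#' @export
network_components <- function(network) {
  if (nrow(network$edges) == 0) return(nrow(network$nodes))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("u", "v")], directed = FALSE,
    vertices = data.frame(name = network$nodes$id))
  igraph::count_components(g)
}

#' Mean centerline tortuosity of a network
#'
#' Arc length over chord length, averaged over edges (chord computed between
#' polyline endpoints; edges with zero chord are skipped).
#' @param network a `vascular_network`.
#' @return mean tortuosity >= 1.
#' @export
network_tortuosity <- function(network) {
  vals <- vapply(network$edges$polyline, function(pl) {
    chord <- sqrt(sum((pl[nrow(pl), ] - pl[1, ])^2))
    if (chord < 1e-9) return(NA_real_)
    polyline_length(pl) / chord
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Add arcade anastomoses between sibling bifurcations
#'
#' For each eligible bifurcation (an interior node both of whose children are
#' themselves bifurcations), with probability `arcade_frac` an arc is added
#' between the two children, emulating the dense regular arcading of healthy
#' capillary beds. The arc bulges away from the parent node. This is the only
#' loop-creating step; [generate_tree()] always returns a forest.
#'
#' @param network a `vascular_network` from [generate_tree()].
#' @param arcade_frac probability per eligible bifurcation.
#' @param seed integer seed (deterministic arc selection and shape).
#' @return The network with arcade edges appended.
#' @export
add_anastomoses <- function(network, arcade_frac, seed) {
  stopifnot(arcade_frac >= 0, arcade_frac <= 1)
  if (arcade_frac == 0 || nrow(network$edges) == 0) return(network)
  withr::with_seed(as.integer(seed), {
    nodes <- network$nodes
    edges <- network$edges
    deg <- table(factor(c(edges$u, edges$v), levels = nodes$id))
    is_bif <- stats::setNames(as.integer(deg) >= 3, names(deg))
    kids <- split(edges$v, edges$u)
    new_edges <- list()
    for (p in names(kids)) {
      ch <- kids[[p]]
      if (length(ch) != 2) next
      if (!all(is_bif[as.character(ch)])) next
      if (stats::runif(1) >= arcade_frac) next
      n1 <- nodes[nodes$id == ch[1], ]
      n2 <- nodes[nodes$id == ch[2], ]
      np <- nodes[nodes$id == as.integer(p), ]
      a <- c(n1$x_um, n1$y_um, n1$z_um)
      b <- c(n2$x_um, n2$y_um, n2$z_um)
      pp <- c(np$x_um, np$y_um, np$z_um)
      mid <- (a + b) / 2
      away <- mid - pp
      nrm <- sqrt(sum(away^2))
      away <- if (nrm > 1e-9) away / nrm else c(0, 0, 1)
      bulge <- mid + 0.35 * sqrt(sum((b - a)^2)) * away
      t <- seq(0, 1, length.out = 15)
      pl <- outer((1 - t)^2, a) + outer(2 * t * (1 - t), bulge) +
        outer(t^2, b)
      colnames(pl) <- c("x", "y", "z")
      r <- 0.7 * min(n1$radius_um, n2$radius_um)
      new_edges[[length(new_edges) + 1L]] <-
        tibble::tibble(u = ch[1], v = ch[2], radius_um = r,
                       length_um = polyline_length(pl), polyline = list(pl))
    }
    if (length(new_edges)) {
      network$edges <- dplyr::bind_rows(edges, dplyr::bind_rows(new_edges))
    }
    network
  })
}

#' Rasterize a ground-truth network to a volume and exact tube mask
#'
#' Each edge is drawn as a tube of its radius: a voxel belongs to the mask
#' iff its centre lies within the edge radius of the centerline polyline
#' (no antialiasing), so the mask is an exact oracle for segmentation tests.
#' Voxel centres sit at `(i + 0.5) * voxel_size` for 0-based index i.
#'
#' @param network a `vascular_network`.
#' @param spec the [phantom_spec()] providing grid and intensities.
#' @return list with `volume` (a [volume_image()]: foreground intensity on
#'   background 0, before noise) and `mask` (a [binary_mask()]).
#' @export
rasterize <- function(network, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$voxel_size_um
  dm <- spec$grid_shape
  mask <- array(FALSE, dim = dm)
  for (k in seq_len(nrow(network$edges))) {
    pl <- network$edges$polyline[[k]]
    r <- network$edges$radius_um[k]
    for (i in seq_len(nrow(pl) - 1)) {
      mask <- stamp_segment(mask, pl[i, ], pl[i + 1, ], r, h)
    }
  }
  vol <- array(0, dim = dm)
  vol[mask] <- spec$foreground_intensity
  list(volume = volume_image(vol, h),
       mask = binary_mask(mask, h))
}

# mark voxels whose centre is within radius r of segment p-q (um coords)
stamp_segment <- function(mask, p, q, r, h) {
  dm <- dim(mask)
  lo <- pmax(floor((pmin(p, q) - r) / h - 0.5) + 1, 0)
  hi <- pmin(ceiling((pmax(p, q) + r) / h - 0.5) + 1, dm - 1)
  if (any(hi < lo)) return(mask)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  cx <- (xs + 0.5) * h; cy <- (ys + 0.5) * h; cz <- (zs + 0.5) * h
  gx <- array(rep(cx, times = length(ys) * length(zs)),
              dim = c(length(xs), length(ys), length(zs)))
  gy <- array(rep(rep(cy, each = length(xs)), times = length(zs)),
              dim = dim(gx))
  gz <- array(rep(cz, each = length(xs) * length(ys)), dim = dim(gx))
  d <- q - p
  L2 <- sum(d^2)
  if (L2 < 1e-12) {
    dist2 <- (gx - p[1])^2 + (gy - p[2])^2 + (gz - p[3])^2
  } else {
    t <- ((gx - p[1]) * d[1] + (gy - p[2]) * d[2] + (gz - p[3]) * d[3]) / L2
    t <- pmin(pmax(t, 0), 1)
    dist2 <- (gx - (p[1] + t * d[1]))^2 + (gy - (p[2] + t * d[2]))^2 +
      (gz - (p[3] + t * d[3]))^2
  }
  sel <- dist2 <= r^2
  if (any(sel)) {
    sub <- mask[xs + 1, ys + 1, zs + 1, drop = FALSE]
    sub[sel] <- TRUE
    mask[xs + 1, ys + 1, zs + 1] <- sub
  }
  mask
}

#' Add Gaussian noise to a volume
#'
#' Additive i.i.d. Gaussian noise, deterministic given `seed`. Volumes are
#' stored as floating point, so no clipping is applied by default; an
#' explicit `clip_range` clips the result (useful before integer export).
#'
#' @param volume a [volume_image()].
#' @param noise_sd noise standard deviation (>= 0, intensity units).
#' @param seed integer seed.
#' @param clip_range optional length-2 numeric range to clip to.
#' @return A [volume_image()] of the same shape and voxel size.
#' @export
add_noise <- function(volume, noise_sd, seed, clip_range = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd == 0) return(volume)
  out <- withr::with_seed(as.integer(seed), {
    as_bare_array(volume) + array(stats::rnorm(length(volume), 0, noise_sd),
                                  dim = dim(volume))
  })
  if (!is.null(clip_range)) {
    out <- pmin(pmax(out, clip_range[1]), clip_range[2])
  }
  volume_image(out, voxel_size(volume))
}

#' Simulate a complete phantom
#'
#' Convenience wrapper: [generate_tree()], [add_anastomoses()] (when
#' `arcade_frac > 0`), [rasterize()] and [add_noise()] (when `noise_sd > 0`),
#' with sub-seeds derived from `spec$seed` so the whole phantom is a pure
#' function of the spec.
#'
#' @param spec a [phantom_spec()].
#' @return list with `network`, `volume` (noisy), `clean_volume`, `mask`,
#'   and `spec`.
#' @export
simulate_phantom <- function(spec) {
  net <- generate_tree(spec)
  if (spec$arcade_frac > 0) {
    net <- add_anastomoses(net, spec$arcade_frac, seed = spec$seed + 1L)
  }
  ras <- rasterize(net, spec)
  vol <- ras$volume
  if (spec$noise_sd > 0) {
    vol <- add_noise(vol, spec$noise_sd, seed = spec$seed + 2L)
  }
  list(network = net, volume = vol, clean_volume = ras$volume,
       mask = ras$mask, spec = spec)
}

#' Hand-built single-tube network (test/benchmark helper)
#'
#' @param from,to segment endpoints in micrometres.
#' @param radius_um tube radius.
#' @return A minimal `vascular_network` with one straight edge.
#' @export
tube_network <- function(from, to, radius_um) {
  pl <- rbind(from, to)
  colnames(pl) <- c("x", "y", "z")
  nodes <- tibble::tibble(id = c(1L, 2L),
                          x_um = c(from[1], to[1]),
                          y_um = c(from[2], to[2]),
                          z_um = c(from[3], to[3]),
                          radius_um = radius_um,
                          kind = c("root", "terminal"))
  edges <- tibble::tibble(u = 1L, v = 2L, radius_um = radius_um,
                          length_um = sqrt(sum((to - from)^2)),
                          polyline = list(pl))
  structure(list(nodes = nodes, edges = edges, spec = NULL),
            class = "vascular_network")
}

#' Hand-built torus network (single closed loop; test helper)
#'
#' A circular centerline of ring radius `ring_radius_um` in the plane
#' `z = centre[3]`, drawn as a tube. The abstract graph is one node with a
#' closed self-polyline, so this fixture is deliberately NOT a forest.
#'
#' @param centre torus centre (um).
#' @param ring_radius_um radius of the centerline circle.
#' @param tube_radius_um tube radius.
#' @param n_points polyline resolution.
#' @return A `vascular_network` whose single edge closes on its single node.
#' @export
torus_network <- function(centre, ring_radius_um, tube_radius_um,
                          n_points = 72) {
  th <- seq(0, 2 * pi, length.out = n_points + 1)
  pl <- cbind(x = centre[1] + ring_radius_um * cos(th),
              y = centre[2] + ring_radius_um * sin(th),
              z = rep(centre[3], length(th)))
  nodes <- tibble::tibble(id = 1L, x_um = pl[1, 1], y_um = pl[1, 2],
                          z_um = pl[1, 3], radius_um = tube_radius_um,
                          kind = "terminal")
  edges <- tibble::tibble(u = 1L, v = 1L, radius_um = tube_radius_um,
                          length_um = polyline_length(pl),
                          polyline = list(pl))
  structure(list(nodes = nodes, edges = edges, spec = NULL),
            class = "vascular_network")
}
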