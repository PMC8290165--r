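#' Topology-preserving 3D skeletonization
#'
#' Extracts a unit-width centerline set from a binary vessel mask by
#' sequential topology-preserving thinning in (26, 6) digital topology:
#' border voxels that are simple points (their deletion changes neither
#' foreground 26-components nor background 6-components locally) and are not
#' curve endpoints are removed over six directional subiterations until a
#' fixed point. Component count and cycle structure of the mask are
#' preserved; the skeleton is a voxelwise subset of the mask.
#'
#' @param mask a [binary_mask()].
#' @return A [skeleton_volume()]. An empty mask yields an empty skeleton
#'   with a warning.
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "binary_mask") || is.array(mask))
  m <- array(as.logical(mask), dim(mask))
  if (!any(m)) {
    warning("empty mask: returning empty skeleton")
    return(skeleton_volume(m, voxel_size(mask)))
  }
  thin <- cpp_thin3d(m, as.integer(dim(m)))
  skeleton_volume(array(thin, dim(m)), voxel_size(mask))
}

# physical length of a voxel step chain: 1, sqrt(2), sqrt(3) x voxel size
step_lengths <- function(coords, h) {
  if (nrow(coords) < 2) return(0)
  sqrt(rowSums(diff(coords)^2)) * h
}

#' Prune short terminal spurs from a skeleton
#'
#' Iteratively removes terminal branches (endpoint up to, but excluding, the
#' nearest junction voxel) whose physical length is below `min_length_um`.
#' Components that contain no junction (bare paths, rings) are never removed
#' wholesale. The operation is idempotent at a fixed threshold: it iterates
#' internally until no spur below the threshold remains.
#'
#' @param skeleton a [skeleton_volume()].
#' @param min_length_um minimum branch length to keep (>= 0); 0 is the
#'   identity. Default pruning in the pipeline is 3 voxel edges.
#' @return A pruned [skeleton_volume()].
#' @export
prune_spurs <- function(skeleton, min_length_um) {
  stopifnot(min_length_um >= 0)
  if (min_length_um == 0) return(skeleton)
  h <- voxel_size(skeleton)
  m <- array(as.logical(skeleton), dim(skeleton))
  dm <- dim(m)
  repeat {
    cnt <- cpp_count_neighbors26(m, as.integer(dm))
    endpoints <- which(m & cnt == 1)
    if (length(endpoints) == 0) break
    removed_any <- FALSE
    for (e in endpoints) {
      if (!m[e]) next
      # walk from the endpoint along the chain until a junction or far end
      path <- integer(0)
      cur <- e
      prev <- -1L
      hit_junction <- FALSE
      repeat {
        path <- c(path, cur)
        nb <- neighbor_indices26(cur, dm)
        nb <- nb[m[nb]]
        nb <- setdiff(nb, prev)
        if (length(nb) == 0) { hit_junction <- FALSE; break }
        if (length(nb) > 1) { hit_junction <- TRUE; break } # reached junction
        nxt <- nb[1]
        if (cnt[nxt] > 2) { hit_junction <- TRUE; break }
        prev <- cur
        cur <- nxt
        if (length(path) * h > min_length_um + h) break
      }
      if (!hit_junction) next # whole component is a bare path: keep
      coords <- arrayInd(path, dm)
      plen <- sum(step_lengths(coords, h))
      if (plen < min_length_um) {
        m[path] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  skeleton_volume(m, h)
}

# 26-neighborhood linear indices of a linear index (in-grid only)
neighbor_indices26 <- function(idx, dm) {
  co <- arrayInd(idx, dm)
  xs <- co[1] + (-1:1); ys <- co[2] + (-1:1); zs <- co[3] + (-1:1)
  xs <- xs[xs >= 1 & xs <= dm[1]]
  ys <- ys[ys >= 1 & ys <= dm[2]]
  zs <- zs[zs >= 1 & zs <= dm[3]]
  g <- expand.grid(x = xs, y = ys, z = zs)
  out <- g$x + dm[1] * ((g$y - 1) + dm[2] * (g$z - 1))
  setdiff(out, idx)
}
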