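#' Write a volume as NIfTI
#'
#' Voxel size is recorded in the header in millimetres (um x 1e-3).
#'
#' @param x a [volume_image()], [binary_mask()] or [skeleton_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path) {
  vs_mm <- voxel_size(x) * 1e-3
  img <- RNifti::asNifti(array(as.numeric(x), dim(x)))
  RNifti::pixdim(img) <- rep(vs_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path `.nii` / `.nii.gz` file.
#' @param as "volume" (default), "mask" or "skeleton".
#' @return the corresponding object; voxel size is taken from the header
#'   (mm x 1e3 = um). Anisotropic voxels are rejected: resample first.
#' @export
read_volume_nifti <- function(path, as = c("volume", "mask", "skeleton")) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)[1:3]
  if (max(pd) - min(pd) > 1e-6 * max(pd)) {
    stop("anisotropic voxels: resample to an isotropic grid first")
  }
  vs_um <- pd[1] * 1e3
  a <- array(as.numeric(img), dim(img)[1:3])
  switch(as,
         volume = volume_image(a, vs_um),
         mask = binary_mask(a > 0.5, vs_um),
         skeleton = skeleton_volume(a > 0.5, vs_um))
}

#' Write a volume as a multi-page TIFF stack
#'
#' Intensities are rescaled to \[0, 1\] (16-bit storage); one page per z
#' slice. TIFF carries no voxel-size metadata, so the voxel size is written
#' to a JSON sidecar `<path>.meta.json`.
#'
#' @param x a volume or mask.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(x, path) {
  a <- array(as.numeric(x), dim(x))
  rng <- range(a)
  if (diff(rng) > 0) a <- (a - rng[1]) / diff(rng)
  pages <- lapply(seq_len(dim(a)[3]), function(z) a[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(list(voxel_size_um = voxel_size(x),
                            intensity_range = rng),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_volume_tiff()]
#' @param path `.tif` file (with its `.meta.json` sidecar if present).
#' @return A [volume_image()].
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  a <- simplify2array(pages)
  meta_path <- paste0(path, ".meta.json")
  vs <- 4.5
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    vs <- meta$voxel_size_um
    rng <- unlist(meta$intensity_range)
    if (length(rng) == 2 && diff(rng) > 0) a <- a * diff(rng) + rng[1]
  }
  volume_image(a, vs)
}

#' Export a vascular graph
#'
#' Writes GraphML (node attributes x, y, z, kind, cluster_size; edge
#' attributes chain_voxel_count, length_um, multiplicity), node and edge
#' CSV tables, and the adjacency matrix as MatrixMarket. Coordinates are
#' 0-based (z, y, x) voxel indices; physical positions are index x voxel
#' size.
#'
#' @param graph a `vascular_graph`.
#' @param dir output directory (created if needed).
#' @param stem file stem, default "graph".
#' @return named vector of the written paths, invisibly.
#' @export
write_graph_files <- function(graph, dir, stem = "graph") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(graphml = file.path(dir, paste0(stem, ".graphml")),
             nodes = file.path(dir, paste0(stem, "_nodes.csv")),
             edges = file.path(dir, paste0(stem, "_edges.csv")),
             mtx = file.path(dir, paste0(stem, "_adjacency.mtx")))
  igraph::write_graph(as_igraph(graph), paths["graphml"], format = "graphml")
  readr::write_csv(graph$nodes, paths["nodes"])
  readr::write_csv(graph$edges, paths["edges"])
  Matrix::writeMM(methods::as(to_adjacency(graph), "generalMatrix"),
                  paths["mtx"])
  invisible(paths)
}

#' Write a metrics report as JSON (and read it back)
#'
#' @param report a `metrics_report` row (or several stacked rows).
#' @param path output `.json`.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, auto_unbox = FALSE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_metrics_json
#' @export
read_metrics_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  out <- tibble::as_tibble(df)
  class(out) <- c("metrics_report", class(out))
  out
}
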