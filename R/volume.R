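#' 3D scalar volume with voxel size metadata
#'
#' A `volume_image` is a plain 3D numeric array carrying the isotropic voxel
#' edge length in micrometres as an attribute. All image-processing steps in
#' the package preserve this metadata. Dimension order is `(x, y, z)` with x
#' fastest (R's native column-major layout); exported coordinates are 0-based
#' voxel indices reported as `(z, y, x)` alongside `(x, y, z)` columns.
#'
#' @param values 3D numeric array of finite intensities.
#' @param voxel_size_um isotropic voxel edge length in micrometres (> 0).
#' @return A `volume_image` object (numeric array with attributes).
#' @export
volume_image <- function(values, voxel_size_um = 4.5) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (!all(is.finite(values))) stop("volume values must be finite")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1 ||
      voxel_size_um <= 0) {
    stop("voxel_size_um must be a single positive number")
  }
  structure(values * 1.0,
            dim = dim(values),
            voxel_size_um = as.numeric(voxel_size_um),
            class = c("volume_image", "array"))
}

#' 3D binary mask with voxel size metadata
#'
#' @param values 3D logical array (or 0/1 numeric, coerced).
#' @param voxel_size_um isotropic voxel edge length in micrometres.
#' @return A `binary_mask` object (logical array with attributes).
#' @export
binary_mask <- function(values, voxel_size_um = 4.5) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  v <- array(as.logical(values), dim = dim(values))
  if (anyNA(v)) stop("mask values must not be NA")
  structure(v,
            voxel_size_um = as.numeric(voxel_size_um),
            class = c("binary_mask", "array"))
}

#' Unit-width skeleton volume
#'
#' Same storage as [binary_mask()] but tagged as a centerline set; produced by
#' [skeletonize()].
#'
#' @param values 3D logical array.
#' @param voxel_size_um isotropic voxel edge length in micrometres.
#' @return A `skeleton_volume` object.
#' @export
skeleton_volume <- function(values, voxel_size_um = 4.5) {
  m <- binary_mask(values, voxel_size_um)
  class(m) <- c("skeleton_volume", class(m))
  m
}

#' Voxel edge length of a volume, mask or skeleton
#' @param x a `volume_image`, `binary_mask` or `skeleton_volume`.
#' @return voxel edge length in micrometres.
#' @export
voxel_size <- function(x) {
  vs <- attr(x, "voxel_size_um")
  if (is.null(vs)) stop("object carries no voxel_size_um attribute")
  vs
}

# strip classes/attrs down to a bare array (internal)
as_bare_array <- function(x) {
  array(as.vector(x), dim = dim(x))
}

#' @exportS3Method base::print
print.volume_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume_image> %d x %d x %d voxels @ %.3g um, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], voxel_size(x), min(x), max(x)))
  invisible(x)
}

#' @exportS3Method base::print
print.binary_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<%s> %d x %d x %d voxels @ %.3g um, %d foreground\n",
              class(x)[1], d[1], d[2], d[3], voxel_size(x), sum(x)))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("grid shapes differ: (%s) vs (%s)",
                 paste(dim(a), collapse = ","),
                 paste(dim(b), collapse = ",")))
  }
  if (!isTRUE(all.equal(voxel_size(a), voxel_size(b)))) {
    stop("voxel sizes differ between inputs")
  }
  invisible(TRUE)
}

#' Label 26- or 6-connected components of a mask
#'
#' Thin wrapper over the package's flood-fill labeller; 26-connectivity is the
#' package-wide default, matching the neighbor rule used for skeleton graphs.
#'
#' @param mask a `binary_mask` or logical array.
#' @param connectivity 26 (default) or 6.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  m <- array(as.logical(mask), dim = dim(mask))
  cpp_label3d(m, as.integer(dim(m)), as.integer(connectivity))
}

#' Dice overlap coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 for identical non-empty masks.
#'
#' @param a,b binary masks on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
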