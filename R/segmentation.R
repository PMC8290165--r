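#' Restrict a volume to a region of interest
#'
#' Voxels outside the ROI are set to the background value 0; voxels inside
#' are unchanged. First preprocessing step of the vessel segmentation chain.
#'
#' @param volume a [volume_image()].
#' @param roi a [binary_mask()] on the same grid.
#' @return A [volume_image()].
#' @export
extract_region <- function(volume, roi) {
  check_same_grid(volume, roi)
  out <- as_bare_array(volume)
  out[!as.logical(roi)] <- 0
  volume_image(out, voxel_size(volume))
}

#' Percentile-clipped linear gray-map transformation
#'
#' Linearly rescales intensities so the `low_pct` / `high_pct` percentiles
#' map to 0 / 1, clipping outside. A constant (degenerate) volume yields an
#' all-zero output with a warning.
#'
#' @param volume a [volume_image()].
#' @param low_pct,high_pct percentile window, `0 <= low < high <= 100`.
#' @return A [volume_image()] with values in \[0, 1\].
#' @export
transform_gray <- function(volume, low_pct = 1, high_pct = 99) {
  stopifnot(low_pct >= 0, high_pct <= 100, low_pct < high_pct)
  v <- as_bare_array(volume)
  qs <- stats::quantile(v, c(low_pct, high_pct) / 100, names = FALSE)
  if (diff(qs) < .Machine$double.eps) {
    warning("degenerate (constant) volume; returning all zeros")
    return(volume_image(array(0, dim(v)), voxel_size(volume)))
  }
  out <- (v - qs[1]) / (qs[2] - qs[1])
  out <- pmin(pmax(out, 0), 1)
  volume_image(out, voxel_size(volume))
}

# second derivatives of a blurred array by central differences (unit spacing)
hessian_components <- function(g) {
  d <- dim(g)
  shift <- function(a, dx, dy, dz) {
    idx <- function(n, s) pmin(pmax(seq_len(n) + s, 1), n)
    a[idx(d[1], dx), idx(d[2], dy), idx(d[3], dz)]
  }
  list(
    xx = shift(g, 1, 0, 0) - 2 * g + shift(g, -1, 0, 0),
    yy = shift(g, 0, 1, 0) - 2 * g + shift(g, 0, -1, 0),
    zz = shift(g, 0, 0, 1) - 2 * g + shift(g, 0, 0, -1),
    xy = (shift(g, 1, 1, 0) - shift(g, 1, -1, 0) -
            shift(g, -1, 1, 0) + shift(g, -1, -1, 0)) / 4,
    xz = (shift(g, 1, 0, 1) - shift(g, 1, 0, -1) -
            shift(g, -1, 0, 1) + shift(g, -1, 0, -1)) / 4,
    yz = (shift(g, 0, 1, 1) - shift(g, 0, 1, -1) -
            shift(g, 0, -1, 1) + shift(g, 0, -1, -1)) / 4
  )
}

#' Multiscale Hessian tubularity (vesselness) filter
#'
#' Bright-tube polarity Hessian-eigenvalue vesselness: at each scale the
#' volume is Gaussian-smoothed, scale-normalized second derivatives are
#' taken, and the tubularity response is computed from the sorted
#' eigenvalues `|l1| <= |l2| <= |l3|` (tubes: `l2, l3 << 0`, `l1 ~ 0`) as
#' `(1 - exp(-Ra^2/2a^2)) * exp(-Rb^2/2b^2) * (1 - exp(-S^2/2c^2))` with
#' `Ra = |l2|/|l3|`, `Rb = |l1|/sqrt(|l2 l3|)` and `S` the Frobenius norm.
#' The per-voxel maximum over scales is rescaled to \[0, 1\].
#'
#' @param volume a [volume_image()].
#' @param scales_um positive tube-radius scales in micrometres; defaults to
#'   1-3 voxels, bracketing the phantom vessel calibers.
#' @param alpha,beta plate/blob sensitivity parameters.
#' @param c_frac structureness cutoff as a fraction of the maximum Frobenius
#'   norm at each scale.
#' @return A [volume_image()] response in \[0, 1\].
#' @export
enhance_vessels <- function(volume, scales_um = NULL, alpha = 0.5,
                            beta = 0.5, c_frac = 0.3) {
  h <- voxel_size(volume)
  if (is.null(scales_um)) scales_um <- h * c(1, 2, 3)
  stopifnot(length(scales_um) >= 1, all(scales_um > 0))
  if (max(scales_um) / h > min(dim(volume)) / 4) {
    warning("largest scale exceeds a quarter of the smallest grid dimension")
  }
  v <- as_bare_array(volume)
  dm <- dim(v)
  best <- array(0, dm)
  for (s in scales_um) {
    sig <- s / h # voxels
    g <- cpp_gaussian_blur3d(v, as.integer(dm), sig)
    hc <- hessian_components(array(g, dm))
    norm <- sig^2 # gamma = 2 scale normalization
    ev <- cpp_hessian_eigen(norm * hc$xx, norm * hc$yy, norm * hc$zz,
                            norm * hc$xy, norm * hc$xz, norm * hc$yz)
    l1 <- ev$l1; l2 <- ev$l2; l3 <- ev$l3
    S2 <- l1^2 + l2^2 + l3^2
    c2 <- (c_frac^2) * max(S2)
    if (c2 <= 0) next
    l2l3 <- abs(l2 * l3)
    l2l3[l2l3 < 1e-300] <- 1e-300
    l3a <- abs(l3)
    l3a[l3a < 1e-300] <- 1e-300
    Ra2 <- (l2 / l3a)^2
    Rb2 <- l1^2 / l2l3
    resp <- (1 - exp(-Ra2 / (2 * alpha^2))) *
      exp(-Rb2 / (2 * beta^2)) *
      (1 - exp(-S2 / (2 * c2)))
    resp[l2 >= 0 | l3 >= 0] <- 0 # bright-tube polarity
    best <- pmax(best, array(resp, dm))
  }
  mx <- max(best)
  if (mx > 0) best <- best / mx
  out <- volume_image(best, h)
  attr(out, "provenance") <- list(op = "enhance_vessels",
                                  scales_um = scales_um, alpha = alpha,
                                  beta = beta, c_frac = c_frac)
  out
}

# Otsu threshold from a 256-bin histogram (between-class variance maximum)
otsu_threshold <- function(v, n_bins = 256) {
  rng <- range(v)
  if (diff(rng) < .Machine$double.eps) {
    stop("degenerate histogram: constant volume has no Otsu threshold")
  }
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  hst <- tabulate(findInterval(v, br, all.inside = TRUE), nbins = n_bins)
  p <- hst / sum(hst)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  (br[k] + br[k + 1]) / 2
}

#' Threshold segmentation
#'
#' Initial vessel segmentation by global thresholding; the mask contains
#' voxels strictly above the threshold (ties go to background). The chosen
#' threshold is recorded in the output's provenance attribute.
#'
#' @param volume a [volume_image()].
#' @param method "otsu" (between-class variance maximum on a 256-bin
#'   histogram) or "fixed".
#' @param value threshold for `method = "fixed"`; must lie within the
#'   intensity range.
#' @return A [binary_mask()] with a `provenance` attribute.
#' @export
threshold_segment <- function(volume, method = c("otsu", "fixed"),
                              value = NULL) {
  method <- match.arg(method)
  v <- as_bare_array(volume)
  if (method == "otsu") {
    thr <- otsu_threshold(v)
  } else {
    if (is.null(value)) stop("fixed thresholding needs a value")
    if (value < min(v) - abs(min(v)) * 1e-9 || value > max(v)) {
      # allow value == max (empty mask) but reject far outside the range
      if (value > max(v)) thr <- value
      else stop("fixed threshold outside the intensity range")
    }
    thr <- value
  }
  m <- binary_mask(v > thr, voxel_size(volume))
  attr(m, "provenance") <- list(op = "threshold_segment", method = method,
                                threshold = thr, rule = "strictly_greater")
  m
}

#' Seeded region growing with running-mean homogeneity
#'
#' Grows 26-connected regions from the seed voxels, accepting a voxel when
#' its intensity lies within `tol` of the running mean of the region grown
#' so far, restricted to a dilated neighborhood of the initial mask (so
#' growth refines the threshold result without leaking across the volume).
#' The output always contains the seed voxels; with seeds inside the mask it
#' is a superset of the seed-connected mask voxels whenever `tol` covers
#' their intensities.
#'
#' @param mask initial [binary_mask()] (from [threshold_segment()]).
#' @param volume the intensity [volume_image()] driving the homogeneity
#'   criterion.
#' @param seeds integer matrix of 1-based voxel indices (n x 3, columns
#'   x, y, z), or `NULL` to use all mask voxels as seeds.
#' @param tol intensity tolerance (>= 0).
#' @param dilate growth halo around the mask, in voxels.
#' @return A [binary_mask()]: the grown region united with the mask
#'   components containing seeds.
#' @export
region_grow <- function(mask, volume, seeds = NULL, tol, dilate = 2) {
  check_same_grid(mask, volume)
  dm <- dim(mask)
  if (is.null(seeds)) {
    seeds <- which(as.logical(mask))
    if (length(seeds) == 0) {
      warning("no seeds: returning the mask unchanged")
      return(mask)
    }
    seeds0 <- seeds - 1L
  } else {
    if (NROW(seeds) == 0) {
      warning("no seeds: returning the mask unchanged")
      return(mask)
    }
    seeds <- matrix(as.integer(seeds), ncol = 3)
    if (any(seeds < 1) || any(seeds[, 1] > dm[1]) || any(seeds[, 2] > dm[2]) ||
        any(seeds[, 3] > dm[3])) {
      stop("seed voxels outside the grid")
    }
    seeds0 <- (seeds[, 1] - 1L) + dm[1] * ((seeds[, 2] - 1L) +
                                             dm[2] * (seeds[, 3] - 1L))
  }
  stopifnot(tol >= 0)
  m <- array(as.logical(mask), dm)
  allowed <- cpp_dilate3d(m, as.integer(dm), as.integer(dilate))
  grown <- cpp_region_grow(as_bare_array(volume), allowed, as.integer(dm),
                           as.integer(seeds0), tol)
  # union with mask components containing seeds
  lab <- cpp_label3d(m, as.integer(dm), 26L)
  seed_labs <- setdiff(unique(lab[seeds0 + 1L]), 0L)
  out <- array(as.logical(grown), dm)
  if (length(seed_labs)) out <- out | array(lab %in% seed_labs, dm)
  res <- binary_mask(out, voxel_size(mask))
  attr(res, "provenance") <- list(op = "region_grow", tol = tol,
                                  dilate = dilate,
                                  n_seeds = length(seeds0))
  res
}

#' Full segmentation chain on a grayscale volume
#'
#' The preprocessing and segmentation sequence used by the pipeline:
#' optional ROI extraction, percentile gray-map transformation, multiscale
#' tubularity enhancement, Otsu thresholding of the response, and
#' region-growing refinement on the gray-transformed volume (recovering tube
#' voxels the enhancement under-segments near boundaries).
#'
#' @param volume a [volume_image()].
#' @param roi optional [binary_mask()].
#' @param scales_um vesselness scales (um); default 1-3 voxels.
#' @param low_pct,high_pct gray-map percentile window.
#' @param grow_tol region-growing tolerance on the \[0, 1\] gray scale;
#'   `NULL` disables the growing step.
#' @param dilate growth halo (voxels).
#' @return A [binary_mask()] with provenance recording every parameter.
#' @export
segment_vessels <- function(volume, roi = NULL, scales_um = NULL,
                            low_pct = 0, high_pct = 100,
                            grow_tol = 0.25, dilate = 2) {
  if (!is.null(roi)) volume <- extract_region(volume, roi)
  gray <- transform_gray(volume, low_pct, high_pct)
  resp <- enhance_vessels(gray, scales_um = scales_um)
  mask <- threshold_segment(resp, method = "otsu")
  prov <- list(gray = list(low_pct = low_pct, high_pct = high_pct),
               enhance = attr(resp, "provenance"),
               threshold = attr(mask, "provenance"))
  if (!is.null(grow_tol)) {
    mask <- region_grow(mask, gray, seeds = NULL, tol = grow_tol,
                        dilate = dilate)
    prov$grow <- attr(mask, "provenance")
  }
  attr(mask, "provenance") <- prov
  mask
}
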