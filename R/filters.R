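#' Otsu threshold of a scalar image
#'
#' Computes the threshold that maximizes the between-class variance of the
#' image histogram (Otsu's method) and returns it together with the
#' above-threshold mask. The histogram spans `[min, max]` of the considered
#' voxels with `n_bins` equal bins; candidate thresholds are the bin
#' boundaries, so the result depends (mildly) on `n_bins`.
#'
#' @param image a [scalar_image()].
#' @param mask optional [mask_image()]; only voxels inside are considered and
#'   the output mask is restricted to it.
#' @param n_bins number of histogram bins (default 128).
#' @return A list with `threshold` (numeric) and `mask` (a `mask_image` of
#'   voxels with value strictly above the threshold).
#' @export
otsu_threshold <- function(image, mask = NULL, n_bins = 128L) {
  stopifnot(inherits(image, "scalar_image"))
  v <- as.vector(image$values)
  sel <- if (is.null(mask)) rep(TRUE, length(v)) else as.vector(mask$values)
  x <- v[sel]
  rng <- range(x)
  if (diff(rng) == 0) stop("otsu_threshold: image is constant within the mask")
  h <- tabulate(pmin(pmax(floor((x - rng[1]) / diff(rng) * n_bins) + 1L, 1L),
                     n_bins), nbins = n_bins)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * diff(rng) / n_bins
  w0 <- cumsum(h)
  m0 <- cumsum(h * mids)
  n <- w0[n_bins]
  mtot <- m0[n_bins]
  # between-class variance at each cut (class 0 = bins 1..t)
  w0k <- w0[-n_bins]
  m0k <- m0[-n_bins]
  valid <- w0k > 0 & w0k < n
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mtot * w0k[valid] / n - m0k[valid])^2 /
    (w0k[valid] / n * (1 - w0k[valid] / n))
  t_bin <- which.max(bcv)
  thr <- rng[1] + t_bin * diff(rng) / n_bins
  out <- v > thr & sel
  list(threshold = thr,
       mask = mask_image(out, image$grid))
}

#' Otsu threshold sensitivity to histogram binning
#'
#' The Otsu threshold depends on the histogram bin count; this helper reports
#' the computed threshold over a range of bin counts so the binning
#' sensitivity can be quantified.
#'
#' @inheritParams otsu_threshold
#' @param bin_counts integer vector of bin counts to evaluate.
#' @return data.frame with columns `n_bins` and `threshold`.
#' @export
otsu_sensitivity <- function(image, mask = NULL,
                             bin_counts = c(32L, 64L, 128L, 256L, 512L, 1024L)) {
  data.frame(
    n_bins = bin_counts,
    threshold = vapply(bin_counts,
                       function(nb) otsu_threshold(image, mask, nb)$threshold,
                       numeric(1)))
}

#' Connected components of a binary mask
#'
#' Labels maximal connected voxel sets 1..K. The labelling is deterministic:
#' components are numbered by the raster order of their first voxel.
#'
#' @param mask a [mask_image()].
#' @param connectivity 6, 18 or 26.
#' @return A [label_image()].
#' @export
connected_components <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "mask_image"), connectivity %in% c(6L, 18L, 26L))
  lab <- cpp_label_components(as.vector(mask$values), mask$grid$dims,
                              as.integer(connectivity))
  label_image(lab, mask$grid)
}

#' Dilate a mask by a world-space distance
#'
#' Adds every voxel whose centre lies within `distance_mm` (Euclidean, in
#' world millimetres, so anisotropic spacing is respected) of a voxel of the
#' input mask. Extensive (`input` is a subset of the output) and monotone in
#' distance.
#'
#' @param mask a [mask_image()].
#' @param distance_mm nonnegative distance in mm.
#' @return A [mask_image()].
#' @export
dilate_mask <- function(mask, distance_mm) {
  stopifnot(inherits(mask, "mask_image"), distance_mm >= 0)
  if (distance_mm == 0) return(mask)
  sp <- mask$grid$spacing
  r <- floor(distance_mm / sp)
  off <- as.matrix(expand.grid(-r[1]:r[1], -r[2]:r[2], -r[3]:r[3]))
  d2 <- (off[, 1] * sp[1])^2 + (off[, 2] * sp[2])^2 + (off[, 3] * sp[3])^2
  off <- off[d2 <= distance_mm^2, , drop = FALSE]
  out <- cpp_dilate_offsets(as.vector(mask$values), mask$grid$dims,
                            matrix(as.integer(off), ncol = 3))
  mask_image(out, mask$grid)
}

#' Trilinear resampling at arbitrary world points
#'
#' Samples a scalar or vector image at world-coordinate points by trilinear
#' interpolation in index space. Points outside the voxel-centre lattice
#' return `background`.
#'
#' @param image a [scalar_image()] or [vector_image()].
#' @param points_world n x 3 matrix of world coordinates (mm).
#' @param background value returned outside the domain.
#' @return numeric vector (scalar image) or n x 3 matrix (vector image).
#' @export
resample_trilinear <- function(image, points_world, background = 0) {
  stopifnot(inherits(image, c("scalar_image", "vector_image", "label_image")))
  idx <- world_to_index(image$grid, points_world)
  nchan <- if (inherits(image, "vector_image")) 3L else 1L
  out <- cpp_trilinear(as.numeric(image$values), image$grid$dims, nchan, idx,
                       as.numeric(background))
  if (nchan == 1L) as.vector(out) else out
}

# component-wise trilinear resampling of a tensor image (6 channels)
resample_tensor <- function(image, points_world, background = 0) {
  stopifnot(inherits(image, "tensor_image"))
  idx <- world_to_index(image$grid, points_world)
  cpp_trilinear(as.numeric(image$values), image$grid$dims, 6L, idx,
                as.numeric(background))
}
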