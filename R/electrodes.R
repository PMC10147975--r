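#' Paired original / projected electrode sets
#'
#' Post-implantation electrode centroids (from CT) paired by label with
#' their projections on the preoperative brain surface.
#'
#' @param orig,proj [point_set()]s with identical label sets.
#' @return An `electrode_set` object.
#' @export
electrode_set <- function(orig, proj) {
  stopifnot(inherits(orig, "point_set"), inherits(proj, "point_set"))
  if (!setequal(orig$label, proj$label) || nrow(orig) != nrow(proj))
    stop("electrode_set: orig and proj must carry the same labels")
  structure(list(orig = orig, proj = proj), class = "electrode_set")
}

#' Segment electrodes from a CT-like image
#'
#' Otsu-thresholds the image to a bright-structure mask (optionally after
#' removing an exclusion region such as the skull), splits it into connected
#' components and discards components smaller than `min_voxels`.
#'
#' @param ct a [scalar_image()] with high-intensity electrodes.
#' @param exclusion_mask optional [mask_image()] of voxels to ignore.
#' @param min_voxels minimum component size kept (default 2).
#' @param connectivity component connectivity (default 26).
#' @return A [label_image()] with one label per electrode.
#' @export
segment_electrodes <- function(ct, exclusion_mask = NULL, min_voxels = 2L,
                               connectivity = 26L) {
  stopifnot(inherits(ct, "scalar_image"))
  keep <- if (is.null(exclusion_mask)) NULL else
    mask_image(!exclusion_mask$values, ct$grid)
  ot <- otsu_threshold(ct, mask = keep)
  m <- ot$mask$values
  labs <- connected_components(mask_image(m, ct$grid), connectivity)
  sizes <- tabulate(labs$values[labs$values > 0])
  keep <- which(sizes >= min_voxels)
  if (length(keep) == 0)
    stop("segment_electrodes: no components of at least ", min_voxels, " voxels")
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  v <- labs$values
  v[v > 0] <- remap[v[v > 0]]
  label_image(v, ct$grid)
}

#' Centroids of labelled components
#'
#' World-coordinate centre of mass (mean of member voxel centres) for each
#' label 1..K.
#'
#' @param labels a [label_image()].
#' @return A [point_set()] with labels `E1..EK`.
#' @export
centroids <- function(labels) {
  stopifnot(inherits(labels, "label_image"))
  v <- as.vector(labels$values)
  K <- max(v)
  if (K < 1) stop("centroids: no labelled components")
  ctr <- voxel_centers(labels$grid)
  sel <- v > 0
  cc <- rowsum(ctr[sel, , drop = FALSE], v[sel]) /
    as.vector(table(factor(v[sel], levels = seq_len(K))))
  point_set(cc, sprintf("E%d", seq_len(K)))
}

#' Electrode displacement vectors
#'
#' The prescribed-displacement seed data for the biomechanical model: at each
#' projected electrode position, the vector from the projected to the
#' original (post-implantation) position, paired by label.
#'
#' @param es an [electrode_set()].
#' @return list with `points` (the projected [point_set()]) and `vectors`
#'   (n x 3 mm displacement matrix, rows aligned with `points`).
#' @export
electrode_displacements <- function(es) {
  stopifnot(inherits(es, "electrode_set"))
  m <- match(es$proj$label, es$orig$label)
  if (anyNA(m)) stop("electrode_displacements: label mismatch between orig and proj")
  vec <- ps_coords(es$orig)[m, , drop = FALSE] - ps_coords(es$proj)
  dimnames(vec) <- NULL
  list(points = es$proj, vectors = vec)
}

#' Moving least squares interpolation of scattered vector data
#'
#' Fits the MLS approximation (the same shape-function machinery as the
#' meshless solver) to values at source points and evaluates it at
#' destination points. Constant and linear fields are reproduced exactly.
#'
#' @param src_points n x 3 source positions (mm).
#' @param src_values n x k source values.
#' @param dst_points m x 3 evaluation positions.
#' @param params an [mls_params()]; by default interpolating (singular) at
#'   all source points.
#' @param support_radius support radius in mm; default covers the source
#'   spacing robustly (2.5 x median nearest-neighbour distance).
#' @return m x k matrix of interpolated values.
#' @export
mls_interpolate <- function(src_points, src_values, dst_points,
                            params = NULL, support_radius = NULL) {
  src_points <- matrix(as.numeric(src_points), ncol = 3)
  src_values <- as.matrix(src_values)
  dst_points <- matrix(as.numeric(dst_points), ncol = 3)
  if (is.null(support_radius)) {
    d <- as.matrix(stats::dist(src_points))
    diag(d) <- Inf
    support_radius <- 2.5 * stats::median(apply(d, 1, min))
    # every destination point needs at least the linear-basis support size;
    # widen the radius to cover the 6th-nearest source of the worst point
    cross <- outer(rowSums(dst_points^2), rep(1, nrow(src_points))) -
      2 * dst_points %*% t(src_points) +
      outer(rep(1, nrow(dst_points)), rowSums(src_points^2))
    cross[cross < 0] <- 0
    cross <- sqrt(cross)
    k6 <- apply(cross, 1, function(r) sort(r)[min(6, length(r))])
    support_radius <- max(support_radius, 1.15 * max(k6))
  }
  # electrode-style source clouds are quasi-planar, which makes the 3D
  # linear-basis moment matrix nearly singular and the fit oscillatory;
  # thicken such clouds along the best-fit plane normal with duplicated
  # values (enforcing a zero out-of-plane gradient)
  ctr <- colMeans(src_points)
  sv <- svd(sweep(src_points, 2, ctr))
  if (sv$d[3] < 0.1 * sv$d[2]) {
    nrml <- sv$v[, 3]
    off <- 0.25 * support_radius
    src_points <- rbind(src_points + matrix(nrml * off, nrow(src_points), 3, byrow = TRUE),
                        src_points - matrix(nrml * off, nrow(src_points), 3, byrow = TRUE))
    src_values <- rbind(src_values, src_values)
  }
  if (is.null(params))
    params <- mls_params(singular_nodes = seq_len(nrow(src_points)))
  shp <- mls_shape(src_points, dst_points, params,
                   radii = rep(support_radius, nrow(src_points)))
  eval_mls_field(shp, src_values, nrow(dst_points))
}

#' Build the prescribed-displacement load table
#'
#' Interpolates the electrode displacement vectors from the projected
#' centroids onto the selected brain-surface nodes by MLS, producing the
#' load table for [solve_static()].
#'
#' @param node_ids indices of the selected surface nodes.
#' @param node_coords full node coordinate matrix (mm) the ids refer to.
#' @param es an [electrode_set()].
#' @param support_radius MLS support radius (mm), see [mls_interpolate()].
#' @return A `load_table` data.frame with columns `node, ux, uy, uz`.
#' @export
build_load_table <- function(node_ids, node_coords, es, support_radius = NULL) {
  stopifnot(length(node_ids) > 0)
  ed <- electrode_displacements(es)
  u <- mls_interpolate(ps_coords(ed$points), ed$vectors,
                       node_coords[node_ids, , drop = FALSE],
                       support_radius = support_radius)
  out <- data.frame(node = as.integer(node_ids), ux = u[, 1], uy = u[, 2],
                    uz = u[, 3])
  class(out) <- c("load_table", "data.frame")
  out
}

#' Simulate a CT-like image of an electrode grid
#'
#' Renders Gaussian blobs (default 2 mm FWHM) of unit peak intensity at the
#' electrode positions on a dark background, for testing the electrode
#' segmentation chain.
#'
#' @param points a [point_set()] of electrode positions.
#' @param grid an [image_grid()].
#' @param fwhm_mm blob full width at half maximum (mm).
#' @param background background intensity.
#' @return A [scalar_image()].
#' @export
simulate_electrode_ct <- function(points, grid, fwhm_mm = 2, background = 0) {
  stopifnot(inherits(points, "point_set"), inherits(grid, "image_grid"))
  sd <- fwhm_mm / (2 * sqrt(2 * log(2)))
  ctr <- voxel_centers(grid)
  v <- rep(background, nrow(ctr))
  xyz <- ps_coords(points)
  # only evaluate within 4 sd of each blob
  r2max <- (4 * sd)^2
  for (e in seq_len(nrow(xyz))) {
    d2 <- (ctr[, 1] - xyz[e, 1])^2 + (ctr[, 2] - xyz[e, 2])^2 +
          (ctr[, 3] - xyz[e, 3])^2
    idx <- d2 < r2max
    v[idx] <- v[idx] + exp(-d2[idx] / (2 * sd^2))
  }
  scalar_image(v, grid)
}
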