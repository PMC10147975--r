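#' Concentric-sphere head phantom specification
#'
#' Describes a nested-sphere head model (e.g. scalp, skull, CSF, GM, WM core)
#' used to generate synthetic label images with the structure of a real head
#' label map. Radii are listed outer to inner and must be strictly
#' decreasing.
#'
#' @param layer_radii numeric, sphere radii in mm, outer to inner.
#' @param layer_labels integer label codes, one per layer (distinct).
#' @param grid_dims voxels per axis.
#' @param spacing mm per axis.
#' @param origin world position of voxel (0,0,0); by default the grid is
#'   centred on the sphere centre at (0,0,0).
#' @param center sphere centre in world mm.
#' @return A `sphere_phantom_spec` object.
#' @export
sphere_phantom_spec <- function(layer_radii, layer_labels = seq_along(layer_radii),
                                grid_dims = c(64L, 64L, 64L),
                                spacing = c(1, 1, 1), origin = NULL,
                                center = c(0, 0, 0)) {
  layer_radii <- as.numeric(layer_radii)
  if (length(layer_radii) == 0) stop("sphere_phantom_spec: need at least one layer")
  if (any(diff(layer_radii) >= 0))
    stop("sphere_phantom_spec: layer radii must be strictly decreasing (outer to inner)")
  if (anyDuplicated(layer_labels)) stop("sphere_phantom_spec: labels must be distinct")
  if (length(layer_labels) != length(layer_radii))
    stop("sphere_phantom_spec: one label per layer required")
  grid_dims <- as.integer(grid_dims)
  spacing <- as.numeric(spacing)
  if (is.null(origin))
    origin <- center - (grid_dims - 1) / 2 * spacing
  ext <- (grid_dims - 1) * spacing / 2
  if (any(layer_radii[1] > ext))
    stop("sphere_phantom_spec: outer radius ", layer_radii[1],
         " mm exceeds the grid half-extent (", paste(signif(ext, 4), collapse = ", "), ") mm")
  structure(list(layer_radii = layer_radii, layer_labels = as.integer(layer_labels),
                 grid_dims = grid_dims, spacing = spacing, origin = origin,
                 center = center), class = "sphere_phantom_spec")
}

#' Generate a concentric-sphere label image
#'
#' Each voxel is labelled by the innermost layer whose radius contains the
#' voxel centre (no partial-volume handling, matching the one-element-per-
#' voxel meshing downstream); background is 0.
#'
#' @param spec a [sphere_phantom_spec()].
#' @return A [label_image()].
#' @export
make_sphere_phantom <- function(spec) {
  stopifnot(inherits(spec, "sphere_phantom_spec"))
  grid <- image_grid(spec$grid_dims, spec$spacing, spec$origin)
  ctr <- voxel_centers(grid)
  r <- sqrt(rowSums(sweep(ctr, 2, spec$center)^2))
  lab <- integer(nrow(ctr))
  # outer to inner: inner assignments overwrite outer ones
  for (l in seq_along(spec$layer_radii))
    lab[r <= spec$layer_radii[l]] <- spec$layer_labels[l]
  label_image(lab, grid)
}

#' Synthetic diffusion-tensor image specification
#'
#' Per-label eigenvalue triples (mm^2/s) and a fibre direction field used to
#' emulate a diffusion tensor image on a label phantom. Direction fields:
#' `"constant"` (along `direction`), `"radial"` and `"tangential"` (with
#' respect to `center`; degenerate voxels at the centre fall back to the x
#' axis).
#'
#' @param eigenvalues named list: label code (as character) -> length-3
#'   eigenvalue triple, descending, mm^2/s.
#' @param field `"constant"`, `"radial"` or `"tangential"`.
#' @param direction unit vector for the constant field.
#' @param center centre for radial/tangential fields (world mm).
#' @param noise_sd standard deviation of i.i.d. Gaussian noise added to each
#'   tensor component (mm^2/s).
#' @param seed integer seed for the noise.
#' @return A `synthetic_dti_spec` object.
#' @export
synthetic_dti_spec <- function(eigenvalues, field = "constant",
                               direction = c(1, 0, 0), center = c(0, 0, 0),
                               noise_sd = 0, seed = 1L) {
  stopifnot(is.list(eigenvalues), length(eigenvalues) > 0)
  for (ev in eigenvalues) {
    if (length(ev) != 3 || any(ev < 0))
      stop("synthetic_dti_spec: eigenvalue triples must be length 3 and nonnegative")
  }
  field <- match.arg(field, c("constant", "radial", "tangential"))
  direction <- direction / sqrt(sum(direction^2))
  structure(list(eigenvalues = eigenvalues, field = field, direction = direction,
                 center = center, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_dti_spec")
}

#' Generate a synthetic DTI from a label image
#'
#' Builds `D = R diag(lambda) R^T` per voxel, with the rotation taking the x
#' axis to the local fibre direction and per-label eigenvalues from the spec;
#' optional seeded Gaussian component noise is added afterwards. Background
#' (label 0) voxels get zero tensors unless an eigenvalue triple for label
#' `"0"` is supplied.
#'
#' @param labels a [label_image()].
#' @param spec a [synthetic_dti_spec()].
#' @return A [tensor_image()].
#' @export
make_synthetic_dti <- function(labels, spec) {
  stopifnot(inherits(labels, "label_image"), inherits(spec, "synthetic_dti_spec"))
  lab <- as.vector(labels$values)
  present <- setdiff(sort(unique(lab)), 0L)
  missing <- setdiff(as.character(present), names(spec$eigenvalues))
  if (length(missing))
    stop("make_synthetic_dti: no eigenvalue triple for label(s) ",
         paste(missing, collapse = ", "))
  n <- length(lab)
  ctr <- voxel_centers(labels$grid)
  # fibre direction per voxel
  e1 <- switch(spec$field,
    constant = matrix(spec$direction, n, 3, byrow = TRUE),
    radial = {
      d <- sweep(ctr, 2, spec$center)
      bad <- sqrt(rowSums(d^2)) < 1e-9
      if (any(bad)) d[bad, ] <- rep(c(1, 0, 0), each = sum(bad))
      d / pmax(sqrt(rowSums(d^2)), 1e-300)
    },
    tangential = {
      d <- sweep(ctr, 2, spec$center)
      tg <- cbind(-d[, 2], d[, 1], 0)
      bad <- sqrt(rowSums(tg^2)) < 1e-9
      if (any(bad)) tg[bad, ] <- rep(c(1, 0, 0), each = sum(bad))
      tg / pmax(sqrt(rowSums(tg^2)), 1e-300)
    })
  # complete e1 to an orthonormal frame (e2 orthogonal to e1, e3 = e1 x e2)
  ref <- matrix(c(0, 0, 1), n, 3, byrow = TRUE)
  near_z <- abs(e1[, 3]) > 0.9
  if (any(near_z)) ref[near_z, ] <- rep(c(0, 1, 0), each = sum(near_z))
  e2 <- cbind(ref[, 2] * e1[, 3] - ref[, 3] * e1[, 2],
              ref[, 3] * e1[, 1] - ref[, 1] * e1[, 3],
              ref[, 1] * e1[, 2] - ref[, 2] * e1[, 1])
  e2 <- e2 / sqrt(rowSums(e2^2))
  e3 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  l1 <- l2 <- l3 <- numeric(n)
  for (nm in names(spec$eigenvalues)) {
    idx <- lab == as.integer(nm)
    ev <- spec$eigenvalues[[nm]]
    l1[idx] <- ev[1]; l2[idx] <- ev[2]; l3[idx] <- ev[3]
  }
  # D = l1 e1 e1' + l2 e2 e2' + l3 e3 e3', packed (xx,xy,xz,yy,yz,zz)
  t6 <- rbind(l1 * e1[, 1]^2 + l2 * e2[, 1]^2 + l3 * e3[, 1]^2,
              l1 * e1[, 1] * e1[, 2] + l2 * e2[, 1] * e2[, 2] + l3 * e3[, 1] * e3[, 2],
              l1 * e1[, 1] * e1[, 3] + l2 * e2[, 1] * e2[, 3] + l3 * e3[, 1] * e3[, 3],
              l1 * e1[, 2]^2 + l2 * e2[, 2]^2 + l3 * e3[, 2]^2,
              l1 * e1[, 2] * e1[, 3] + l2 * e2[, 2] * e2[, 3] + l3 * e3[, 2] * e3[, 3],
              l1 * e1[, 3]^2 + l2 * e2[, 3]^2 + l3 * e3[, 3]^2)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    t6 <- t6 + matrix(stats::rnorm(6 * n, sd = spec$noise_sd), 6, n)
  }
  tensor_image(t6, labels$grid)
}

#' Synthetic subdural electrode grid on a surface
#'
#' Places a `rows x cols` rectangular electrode grid with the given pitch on
#' a (closed) surface: lattice points in the tangent plane of a seed vertex
#' are projected to their closest surface points (`proj`), and the
#' post-implantation positions (`orig`) are obtained by displacing each
#' projected point inward (opposite to the local outward normal) by
#' `inward_shift`, emulating the brain shift caused by implantation.
#'
#' @param surface a [tri_surface()].
#' @param rows,cols grid dimensions.
#' @param pitch electrode spacing in mm.
#' @param inward_shift inward displacement in mm.
#' @param seed integer; selects the seed vertex reproducibly.
#' @return list with `orig` and `proj` [point_set()]s (labels `E1..`,
#'   row-major).
#' @export
make_electrode_grid <- function(surface, rows = 8L, cols = 8L, pitch = 10,
                                inward_shift = 5, seed = 1L) {
  stopifnot(inherits(surface, "tri_surface"), pitch > 0, inward_shift >= 0)
  ext <- apply(surface$vertices, 2, range)
  if (max(rows, cols) * pitch > 1.2 * max(ext[2, ] - ext[1, ]))
    stop("make_electrode_grid: a ", rows, "x", cols, " grid at pitch ", pitch,
         " mm does not fit on the surface")
  set.seed(seed)
  # seed vertex: the topmost vertex after a seeded random rotation of the
  # preference axis, so different seeds give different patches
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  iv <- which.max(surface$vertices %*% axis)
  p0 <- surface$vertices[iv, ]
  nrm <- vertex_normals(surface)[iv, ]
  # tangent frame
  t1 <- c(-nrm[2], nrm[1], 0)
  if (sqrt(sum(t1^2)) < 1e-6) t1 <- c(1, 0, 0)
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(nrm[2] * t1[3] - nrm[3] * t1[2],
          nrm[3] * t1[1] - nrm[1] * t1[3],
          nrm[1] * t1[2] - nrm[2] * t1[1])
  ui <- (seq_len(rows) - (rows + 1) / 2) * pitch
  vj <- (seq_len(cols) - (cols + 1) / 2) * pitch
  lattice <- as.matrix(expand.grid(ui, vj))
  # gnomonic pre-warp: stretch planar offsets so that closest-point
  # projection onto the (locally spherical) surface preserves the arc pitch
  c0 <- colMeans(surface$vertices)
  R_est <- mean(sqrt(rowSums(sweep(surface$vertices, 2, c0)^2)))
  rho <- sqrt(rowSums(lattice^2))
  if (max(rho) / R_est > 0.45 * pi)
    stop("make_electrode_grid: electrode patch does not fit on the surface")
  stretch <- ifelse(rho > 1e-12, R_est * tan(rho / R_est) / rho, 1)
  lattice <- lattice * stretch
  pts <- sweep(lattice[, 1, drop = FALSE] %*% rbind(t1) +
               lattice[, 2, drop = FALSE] %*% rbind(t2), 2, p0, `+`)
  cp <- cpp_closest_point(pts, surface$vertices, surface$triangles)
  proj <- cp$point
  if (any(cp$distance > max(rows, cols) * pitch))
    stop("make_electrode_grid: electrode patch does not fit on the surface")
  # outward normal at each projected point (from the hit triangle)
  fn <- face_normals(surface)
  nrm_p <- fn[cp$triangle, , drop = FALSE]
  orig <- proj - inward_shift * nrm_p
  labels <- sprintf("E%d", seq_len(rows * cols))
  list(orig = point_set(orig, labels), proj = point_set(proj, labels))
}
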