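#' Voxel lattice with world-coordinate placement
#'
#' An `image_grid` describes a regular 3D voxel lattice: the number of voxels
#' per axis, the voxel spacing in millimetres, the world position of the first
#' voxel centre, and a direction matrix whose orthonormal columns give the
#' world orientation of the voxel axes. All world coordinates in this package
#' are in the LPS (left-posterior-superior) frame, matching the NRRD
#' convention used by the supported file formats.
#'
#' Voxel indices are 0-based; the centre of voxel `(i,j,k)` is
#' `origin + direction %*% (spacing * c(i,j,k))`.
#'
#' @param dims integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric length 3, voxel spacing in mm (all > 0).
#' @param origin numeric length 3, world position (mm) of voxel (0,0,0).
#' @param direction 3x3 matrix with orthonormal columns.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(dims, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       direction = diag(3)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- as.matrix(direction)
  stopifnot(length(dims) == 3, length(spacing) == 3, length(origin) == 3,
            all(dim(direction) == c(3, 3)))
  if (any(dims < 1L)) stop("image_grid: dims must all be >= 1")
  if (any(spacing <= 0)) stop("image_grid: spacing must be positive")
  cn <- sqrt(colSums(direction^2))
  if (any(abs(cn - 1) > 1e-8)) stop("image_grid: direction columns must be unit norm")
  structure(list(dims = dims, spacing = spacing, origin = origin,
                 direction = direction), class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Test two grids for geometric compatibility
#' @param a,b `image_grid` objects.
#' @param tol numeric tolerance on spacing/origin/direction.
#' @return logical
#' @export
grids_equal <- function(a, b, tol = 1e-8) {
  all(a$dims == b$dims) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

# index (0-based, possibly fractional) -> world mm; idx is n x 3
index_to_world <- function(grid, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(idx %*% t(grid$direction %*% diag(grid$spacing)), 2, grid$origin, `+`)
}

# world mm -> continuous 0-based index; pts is n x 3
world_to_index <- function(grid, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  A <- grid$direction %*% diag(grid$spacing)
  t(solve(A, t(sweep(pts, 2, grid$origin, `-`))))
}

#' World coordinates of all voxel centres
#'
#' @param grid an `image_grid`.
#' @return An `prod(dims) x 3` matrix of voxel-centre positions (mm), in
#'   raster (column-major, first axis fastest) order.
#' @export
voxel_centers <- function(grid) {
  d <- grid$dims
  ijk <- cbind(rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
               rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
               rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
  index_to_world(grid, ijk)
}

#' Voxel volume in cubic millimetres
#' @param grid an `image_grid`.
#' @return numeric scalar, mm^3.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

new_image <- function(values, grid, kind, nchan = NULL) {
  stopifnot(inherits(grid, "image_grid"))
  d <- grid$dims
  if (is.null(nchan)) {
    values <- array(values, dim = d)
  } else {
    values <- array(values, dim = c(nchan, d))
  }
  structure(list(values = values, grid = grid),
            class = c(kind, "ecog_image"))
}

#' Image containers
#'
#' Scalar, label, mask, vector (3-channel) and symmetric-tensor (6-channel)
#' images on an [image_grid()]. Channel-bearing images store channels on the
#' first array axis. Tensor components are stored in NRRD
#' `3D-symmetric-matrix` order: `(xx, xy, xz, yy, yz, zz)`.
#'
#' @param values numeric array (recycled to the grid shape).
#' @param grid an [image_grid()].
#' @return An object of class `ecog_image` with subclass
#'   `scalar_image`, `label_image`, `mask_image`, `vector_image` or
#'   `tensor_image`.
#' @export
scalar_image <- function(values, grid) new_image(as.numeric(values), grid, "scalar_image")

#' @rdname scalar_image
#' @export
label_image <- function(values, grid) {
  v <- as.integer(round(values))
  if (any(v < 0L, na.rm = TRUE)) stop("label_image: labels must be nonnegative")
  new_image(v, grid, "label_image")
}

#' @rdname scalar_image
#' @export
mask_image <- function(values, grid) new_image(as.logical(values), grid, "mask_image")

#' @rdname scalar_image
#' @export
vector_image <- function(values, grid) new_image(as.numeric(values), grid, "vector_image", nchan = 3L)

#' @rdname scalar_image
#' @param frame 3x3 measurement frame (orthonormal); tensors are stored in
#'   this frame on disk and rotated into world axes on load by [read_nrrd()].
#' @export
tensor_image <- function(values, grid, frame = diag(3)) {
  img <- new_image(as.numeric(values), grid, "tensor_image", nchan = 6L)
  img$frame <- as.matrix(frame)
  img
}

#' @export
print.ecog_image <- function(x, ...) {
  cat(sprintf("%s: ", class(x)[1]))
  print(x$grid)
  v <- x$values
  if (is.logical(v)) {
    cat(sprintf("  %d voxels on\n", sum(v)))
  } else {
    cat(sprintf("  range [%.4g, %.4g]\n", min(v), max(v)))
  }
  invisible(x)
}

# ---- symmetric tensor packing helpers (component order xx,xy,xz,yy,yz,zz) ----

#' Pack / unpack symmetric 3x3 tensors
#'
#' `sym6_to_mat` expands a 6-vector in `(xx,xy,xz,yy,yz,zz)` order to a
#' symmetric 3x3 matrix; `mat_to_sym6` is its inverse.
#' @param v numeric length 6.
#' @return 3x3 matrix, or length-6 vector.
#' @export
sym6_to_mat <- function(v) {
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3, 3)
}

#' @rdname sym6_to_mat
#' @param m symmetric 3x3 matrix.
#' @export
mat_to_sym6 <- function(m) c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])

# apply a rotation R to every tensor of a 6 x n matrix of packed tensors: R D R^T
rotate_sym6 <- function(v6, R) {
  # v6: 6 x n
  xx <- v6[1, ]; xy <- v6[2, ]; xz <- v6[3, ]
  yy <- v6[4, ]; yz <- v6[5, ]; zz <- v6[6, ]
  # columns of D R^T: (D r1, D r2, D r3) with r_i rows of R
  out <- matrix(0, 6, ncol(v6))
  # compute M = R D, then M R^T
  for (i in 1:3) for (j in i:3) {
    mij <- (R[i, 1] * xx + R[i, 2] * xy + R[i, 3] * xz) * R[j, 1] +
           (R[i, 1] * xy + R[i, 2] * yy + R[i, 3] * yz) * R[j, 2] +
           (R[i, 1] * xz + R[i, 2] * yz + R[i, 3] * zz) * R[j, 3]
    k <- c("11" = 1, "12" = 2, "13" = 3, "22" = 4, "23" = 5, "33" = 6)[paste0(i, j)]
    out[k, ] <- mij
  }
  out
}
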