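#' Hexahedral mesh from masked voxels
#'
#' One trilinear hexahedron per masked voxel, vertices at voxel corners in
#' world coordinates, shared vertices merged. Node and element ordering is
#' deterministic (corner-lattice raster order).
#'
#' @param x a [mask_image()] or [label_image()] (any nonzero voxel is meshed).
#' @return A `hex_mesh`: `nodes` (n x 3 mm world), `nodes_ijk` (corner
#'   lattice indices), `elems` (m x 8), `voxel` (owning voxel linear index),
#'   `labels` (per-element source label), `grid`, `node_map`.
#' @export
voxels_to_hexmesh <- function(x) {
  stopifnot(inherits(x, c("mask_image", "label_image")))
  grid <- x$grid
  m <- if (inherits(x, "mask_image")) as.vector(x$values) else as.vector(x$values) > 0
  if (!any(m)) stop("voxels_to_hexmesh: empty mask")
  res <- cpp_hexmesh_from_mask(m, grid$dims)
  # corner (i,j,k) lattice -> world: voxel centres at integer indices, so
  # corners sit at index - 0.5
  nodes <- index_to_world(grid, sweep(res$nodes_ijk, 2, 0.5))
  labels <- if (inherits(x, "label_image")) as.vector(x$values)[res$voxel] else
    rep(1L, nrow(res$elems))
  structure(list(nodes = nodes, nodes_ijk = res$nodes_ijk, elems = res$elems,
                 voxel = res$voxel, labels = labels, grid = grid,
                 node_map = res$node_map, mask = m),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("hex_mesh: %d nodes, %d hexahedral elements (voxel size %.3g x %.3g x %.3g mm)\n",
              nrow(x$nodes), nrow(x$elems), x$grid$spacing[1], x$grid$spacing[2],
              x$grid$spacing[3]))
  invisible(x)
}

#' Per-element conductivity tensors from a tensor image
#'
#' Extracts the conductivity tensor of each element's source voxel and
#' rotates it into the voxel-index frame used for assembly (relevant when
#' the grid direction matrix is not the identity).
#'
#' @param mesh a [voxels_to_hexmesh()] mesh.
#' @param cond a [tensor_image()] of conductivities (S/m) on the same grid.
#' @return 6 x m matrix of packed per-element tensors (index frame).
#' @export
element_tensors <- function(mesh, cond) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(cond, "tensor_image"),
            grids_equal(mesh$grid, cond$grid))
  t6 <- matrix(cond$values, nrow = 6)[, mesh$voxel, drop = FALSE]
  D <- mesh$grid$direction
  if (max(abs(D - diag(3))) > 1e-12) t6 <- rotate_sym6(t6, t(D))
  ev <- cpp_sym3_eig(t6)
  if (min(ev$values[3, ]) <= 0) {
    bad <- which.min(ev$values[3, ])
    stop("element_tensors: non-SPD conductivity tensor at element ", bad,
         " (min eigenvalue ", signif(ev$values[3, bad], 3), ")")
  }
  t6
}

#' Dipole source for the forward problem
#'
#' @param position dipole position (mm world), strictly inside the mesh.
#' @param moment dipole moment (A mm).
#' @param sigma0 3x3 source-region conductivity (S/m, world frame); by
#'   default taken from the element containing the dipole.
#' @param homogeneity_radius radius (voxels) within which the conductivity
#'   must equal `sigma0` for the full-subtraction splitting to be valid.
#' @return A `dipole_source` object.
#' @export
dipole_source <- function(position, moment, sigma0 = NULL,
                          homogeneity_radius = 3) {
  structure(list(position = as.numeric(position), moment = as.numeric(moment),
                 sigma0 = sigma0, homogeneity_radius = homogeneity_radius),
            class = "dipole_source")
}

#' Assemble the electrostatic stiffness operator
#'
#' \eqn{K_{ab} = \sum_e \int_e \nabla N_a \cdot \sigma_e \nabla N_b}, with
#' 2x2x2 Gauss quadrature per hexahedron, assembled directly into compressed
#' sparse rows. K is symmetric with zero row sums (the pure-Neumann operator
#' has the constants as null space).
#'
#' @param mesh a [voxels_to_hexmesh()] mesh.
#' @param sig6 6 x m packed per-element tensors (see [element_tensors()]).
#' @return An `ecog_spd_operator` (list with `row_ptr`, `col`, `val`, `n`).
#' @export
assemble_system <- function(mesh, sig6) {
  stopifnot(inherits(mesh, "hex_mesh"))
  d <- mesh$grid$dims
  lat <- c(d[1] + 1L, d[2] + 1L, d[3] + 1L)
  K <- cpp_hex_assemble(mesh$nodes_ijk, mesh$elems, sig6, mesh$grid$spacing,
                        lat, mesh$node_map)
  structure(K, class = "ecog_spd_operator")
}

#' Convert the assembled operator to a Matrix::dgCMatrix
#'
#' Mainly for verification on small meshes.
#' @param K an `ecog_spd_operator`.
#' @return A `Matrix::dgCMatrix`.
#' @export
as_sparse_matrix <- function(K) {
  i <- rep(seq_len(K$n), diff(K$row_ptr))
  Matrix::sparseMatrix(i = i, j = K$col + 1L, x = K$val, dims = c(K$n, K$n))
}

# dipole/source geometry in the index-aligned frame used by the C++ kernels
to_index_frame <- function(grid, dipole) {
  D <- grid$direction
  pos_idx <- world_to_index(grid, matrix(dipole$position, 1))
  # index-frame coordinates: origin at voxel (0,0,0) centre, axes = voxel axes
  pos <- as.numeric(pos_idx) * grid$spacing
  mom <- as.numeric(t(D) %*% dipole$moment)
  list(pos = pos, mom = mom, origin0 = -0.5 * grid$spacing)
}

#' Full-subtraction right-hand side
#'
#' Builds the load vector of the full-subtraction formulation,
#' \deqn{b_a = -\int_\Omega \nabla N_a\cdot(\sigma-\sigma_0)\nabla\phi_\infty
#'       - \oint_{\partial\Omega} N_a\,(\sigma_0\nabla\phi_\infty\cdot n),}
#' where \eqn{\phi_\infty} is the analytic dipole potential of the
#' homogeneous medium \eqn{\sigma_0} (see [analytic_dipole_infinite()]).
#' The conductivity within `homogeneity_radius` voxels of the dipole must
#' equal \eqn{\sigma_0}; otherwise an error advises repositioning.
#'
#' @param mesh a [voxels_to_hexmesh()] mesh.
#' @param sig6 per-element tensors (index frame).
#' @param dipole a [dipole_source()].
#' @return list with `b` (load vector, zero-sum), `sigma0` (3x3, index
#'   frame) and `phi_inf` at the mesh nodes.
#' @export
full_subtraction_rhs <- function(mesh, sig6, dipole) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(dipole, "dipole_source"))
  grid <- mesh$grid
  fr <- to_index_frame(grid, dipole)
  # element containing the dipole and homogeneity check
  idx <- world_to_index(grid, matrix(dipole$position, 1))
  vox <- round(as.numeric(idx))
  d <- grid$dims
  if (any(vox < 0) || any(vox >= d))
    stop("full_subtraction_rhs: dipole outside the image grid")
  # source tensor: default = tensor of the containing element
  lin <- 1 + vox[1] + d[1] * vox[2] + d[1] * d[2] * vox[3]
  e0 <- match(lin, mesh$voxel)
  if (is.na(e0))
    stop("full_subtraction_rhs: dipole must lie inside a meshed voxel")
  if (is.null(dipole$sigma0)) {
    s0 <- sym6_to_mat(sig6[, e0])
  } else {
    s0 <- as.matrix(dipole$sigma0)
    D <- grid$direction
    if (max(abs(D - diag(3))) > 1e-12) s0 <- t(D) %*% s0 %*% D
  }
  # homogeneity within the configured radius (in voxels)
  r <- dipole$homogeneity_radius
  vox_ijk <- cbind((mesh$voxel - 1) %% d[1],
                   ((mesh$voxel - 1) %/% d[1]) %% d[2],
                   (mesh$voxel - 1) %/% (d[1] * d[2]))
  dist_vox <- sqrt(rowSums(sweep(vox_ijk, 2, vox)^2))
  nearby <- which(dist_vox <= r)
  dev <- max(abs(sig6[, nearby, drop = FALSE] - mat_to_sym6(s0)))
  if (dev > 1e-10 * max(abs(s0)))
    stop("full_subtraction_rhs: conductivity is inhomogeneous within ", r,
         " voxels of the dipole (max deviation ", signif(dev, 3),
         " S/m); reposition the dipole or supply sigma0 explicitly")
  b <- cpp_hex_rhs(mesh$nodes_ijk, mesh$elems, sig6, mesh$mask, d,
                   mesh$voxel, grid$spacing, fr$origin0, s0, fr$pos, fr$mom,
                   nrow(mesh$nodes), 1e-14)
  # singularity potential at the nodes (index frame = world up to rotation)
  node_pos_idx <- sweep(mesh$nodes_ijk, 2, 0.5) * matrix(grid$spacing,
                                                         nrow(mesh$nodes), 3,
                                                         byrow = TRUE)
  phi_inf <- analytic_dipole_infinite(s0, fr$pos, fr$mom, node_pos_idx)
  list(b = b, sigma0 = s0, phi_inf = phi_inf)
}

#' Solve the gauge-fixed system by preconditioned conjugate gradients
#'
#' Jacobi-preconditioned CG with the constant null space projected out of
#' the right-hand side and preconditioned residuals. Returns the correction
#' potential, the total potential (`correction + phi_inf`, mean-zero over
#' the nodes) and the solver report.
#'
#' @param K an `ecog_spd_operator`.
#' @param rhs result of [full_subtraction_rhs()].
#' @param tol relative residual tolerance.
#' @param max_iter iteration budget.
#' @return A `forward_solution`.
#' @export
solve_potential <- function(K, rhs, tol = 1e-8, max_iter = 2000L) {
  res <- cpp_cg(K$row_ptr, K$col, K$val, rhs$b, tol, as.integer(max_iter))
  if (res$relres > tol)
    stop("solve_potential: CG did not reach tol ", tol, " in ", max_iter,
         " iterations (relative residual ", signif(res$relres, 3), ")")
  total <- res$x + rhs$phi_inf
  total <- total - mean(total)
  structure(list(correction = res$x, potential = total,
                 phi_inf = rhs$phi_inf, iterations = res$iterations,
                 relres = res$relres), class = "forward_solution")
}

#' @export
print.forward_solution <- function(x, ...) {
  cat(sprintf("forward_solution: %d nodes, CG %d iterations (relres %.2e)\n",
              length(x$potential), x$iterations, x$relres))
  invisible(x)
}

#' Solve the ECoG forward problem on a conductivity image
#'
#' Convenience driver: meshes the nonzero-conductivity voxels, assembles the
#' stiffness operator, builds the full-subtraction load and solves.
#'
#' @param labels head [label_image()] or [mask_image()] defining the domain.
#' @param cond conductivity [tensor_image()] (S/m).
#' @param dipole a [dipole_source()].
#' @param tol,max_iter CG controls.
#' @return list with `mesh`, `solution`.
#' @export
forward_solve <- function(labels, cond, dipole, tol = 1e-8, max_iter = 2000L) {
  mesh <- voxels_to_hexmesh(labels)
  sig6 <- element_tensors(mesh, cond)
  K <- assemble_system(mesh, sig6)
  rhs <- full_subtraction_rhs(mesh, sig6, dipole)
  sol <- solve_potential(K, rhs, tol = tol, max_iter = max_iter)
  list(mesh = mesh, solution = sol)
}

#' Sample nodal potentials at arbitrary points
#'
#' Trilinear evaluation within the containing element; points up to half a
#' voxel outside the mesh are snapped to the nearest element.
#'
#' @param solution a `forward_solution`.
#' @param mesh the matching `hex_mesh`.
#' @param points n x 3 world coordinates (mm) or a [point_set()].
#' @param what `"total"` or `"correction"`.
#' @return numeric vector of potentials.
#' @export
sample_potentials <- function(solution, mesh, points, what = "total") {
  stopifnot(inherits(solution, "forward_solution"), inherits(mesh, "hex_mesh"))
  if (inherits(points, "point_set")) points <- ps_coords(points)
  idx <- world_to_index(mesh$grid, matrix(points, ncol = 3))
  vals <- switch(what, total = solution$potential,
                 correction = solution$correction,
                 stop("sample_potentials: unknown field '", what, "'"))
  cpp_hex_sample(mesh$node_map, mesh$mask, mesh$grid$dims, vals, idx, 0.5)
}
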