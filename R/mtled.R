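#' Tetrahedral background integration grid
#'
#' Node cloud plus tetrahedral connectivity used for background integration
#' in the meshless solver. Tetrahedra with negative volume are reoriented.
#'
#' @param nodes n x 3 node positions (mm).
#' @param tets m x 4 1-based connectivity.
#' @return A `tet_grid` object.
#' @export
tet_grid <- function(nodes, tets) {
  nodes <- matrix(as.numeric(nodes), ncol = 3)
  tets <- matrix(as.integer(tets), ncol = 4)
  if (nrow(tets) && (min(tets) < 1 || max(tets) > nrow(nodes)))
    stop("tet_grid: tet indices out of range")
  # fix orientation so all volumes are positive
  v <- tet_volumes(nodes, tets)
  flip <- v < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  if (any(tet_volumes(nodes, tets) <= 0))
    stop("tet_grid: degenerate (zero-volume) tetrahedra present")
  structure(list(nodes = nodes, tets = tets), class = "tet_grid")
}

tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - a
  e2 <- nodes[tets[, 3], , drop = FALSE] - a
  e3 <- nodes[tets[, 4], , drop = FALSE] - a
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
   e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
   e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
}

#' @export
print.tet_grid <- function(x, ...) {
  cat(sprintf("tet_grid: %d nodes, %d tetrahedra, volume %.4g mm^3\n",
              nrow(x$nodes), nrow(x$tets), sum(tet_volumes(x$nodes, x$tets))))
  invisible(x)
}

#' Structured tetrahedral grid of a box or masked voxel region
#'
#' Builds a regular node lattice and splits each cell into six tetrahedra
#' (Kuhn decomposition). `structured_tet_grid` fills a box; `mask_tet_grid`
#' keeps only cells whose corresponding (coarsened) voxel block is inside a
#' mask, giving a phantom-friendly background grid for the meshless model.
#'
#' @param lower,upper box corners (mm).
#' @param divisions cells per axis (length 3).
#' @return A [tet_grid()].
#' @export
structured_tet_grid <- function(lower, upper, divisions) {
  divisions <- as.integer(divisions)
  stopifnot(all(divisions >= 1), all(upper > lower))
  nx <- divisions[1] + 1L; ny <- divisions[2] + 1L; nz <- divisions[3] + 1L
  xs <- seq(lower[1], upper[1], length.out = nx)
  ys <- seq(lower[2], upper[2], length.out = ny)
  zs <- seq(lower[3], upper[3], length.out = nz)
  nodes <- as.matrix(expand.grid(xs, ys, zs))
  nid <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  cells <- as.matrix(expand.grid(seq_len(divisions[1]), seq_len(divisions[2]),
                                 seq_len(divisions[3])))
  tets <- structured_cells_to_tets(cells, nid)
  tet_grid(nodes, tets)
}

# Kuhn 6-tet decomposition of cells given by their lower corner (i,j,k)
structured_cells_to_tets <- function(cells, nid) {
  co <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
              c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  kt <- rbind(c(1,2,3,7), c(1,3,4,7), c(1,4,8,7),
              c(1,8,5,7), c(1,5,6,7), c(1,6,2,7))
  vid <- matrix(0L, nrow(cells), 8)
  for (c in 1:8)
    vid[, c] <- nid(cells[, 1] + co[c, 1], cells[, 2] + co[c, 2],
                    cells[, 3] + co[c, 3])
  do.call(rbind, lapply(1:6, function(t) vid[, kt[t, ], drop = FALSE]))
}

#' @rdname structured_tet_grid
#' @param mask a [mask_image()]; one cell per block of `coarsen`^3 voxels
#'   whose centre voxel block intersects the mask.
#' @param coarsen integer block size in voxels per cell.
#' @export
mask_tet_grid <- function(mask, coarsen = 4L) {
  stopifnot(inherits(mask, "mask_image"))
  g <- mask$grid
  d <- g$dims %/% coarsen
  keep <- array(FALSE, d)
  mv <- mask$values
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    blk <- mv[((i - 1) * coarsen + 1):min(i * coarsen, g$dims[1]),
              ((j - 1) * coarsen + 1):min(j * coarsen, g$dims[2]),
              ((k - 1) * coarsen + 1):min(k * coarsen, g$dims[3])]
    keep[i, j, k] <- mean(blk) > 0.5
  }
  cells <- which(keep, arr.ind = TRUE)
  if (nrow(cells) == 0) stop("mask_tet_grid: mask too small for the chosen coarsening")
  # lattice nodes at block corners
  nx <- d[1] + 1L; ny <- d[2] + 1L
  nid_full <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  tets_full <- structured_cells_to_tets(cells, nid_full)
  used <- sort(unique(as.vector(tets_full)))
  remap <- integer(nx * ny * (d[3] + 1L))
  remap[used] <- seq_along(used)
  ijk <- cbind((used - 1L) %% nx,
               ((used - 1L) %/% nx) %% ny,
               (used - 1L) %/% (nx * ny))
  nodes <- index_to_world(g, sweep(ijk * coarsen, 2, c(0.5, 0.5, 0.5)))
  tet_grid(nodes, matrix(remap[tets_full], ncol = 4))
}

#' Integration points of a tetrahedral background grid
#'
#' The 4-point degree-2 Gauss rule per tetrahedron: barycentric permutations
#' of (0.58541020, 0.13819660, 0.13819660, 0.13819660), each with weight
#' V/4. Weights per tetrahedron sum to its volume.
#'
#' @param grid a [tet_grid()].
#' @return list with `points` (4m x 3 mm), `weights` (mm^3) and `element`
#'   (owning tetrahedron, 1-based).
#' @export
build_integration_points <- function(grid) {
  stopifnot(inherits(grid, "tet_grid"))
  cpp_tet_ips(grid$nodes, grid$tets)
}

#' Moving least squares parameters
#'
#' @param support_scale support radius as a multiple of the local average
#'   edge length (default 1.8).
#' @param singular_nodes integer indices of nodes given (near-)interpolating
#'   singular weights, used to impose essential boundary conditions directly.
#' @param sing_eps regularization of the singular weight (dimensionless,
#'   relative to the support radius).
#' @return An `mls_params` object.
#' @export
mls_params <- function(support_scale = 1.8, singular_nodes = integer(),
                       sing_eps = 1e-4) {
  stopifnot(support_scale > 0, sing_eps > 0)
  structure(list(support_scale = support_scale,
                 singular_nodes = as.integer(singular_nodes),
                 sing_eps = sing_eps), class = "mls_params")
}

# per-node support radii: support_scale x mean incident edge length
node_support_radii <- function(grid, support_scale) {
  tets <- grid$tets
  ed <- rbind(tets[, c(1, 2)], tets[, c(1, 3)], tets[, c(1, 4)],
              tets[, c(2, 3)], tets[, c(2, 4)], tets[, c(3, 4)])
  len <- sqrt(rowSums((grid$nodes[ed[, 1], , drop = FALSE] -
                       grid$nodes[ed[, 2], , drop = FALSE])^2))
  num <- rowsum(c(len, len), c(ed[, 1], ed[, 2]))
  cnt <- rowsum(rep(1, 2 * nrow(ed)), c(ed[, 1], ed[, 2]))
  r <- numeric(nrow(grid$nodes))
  r[as.integer(rownames(num))] <- num / cnt
  if (any(r == 0)) r[r == 0] <- mean(r[r > 0])
  support_scale * r
}

#' Evaluate MLS shape functions
#'
#' Linear-basis moving least squares shape functions with quartic-spline
#' weights over a node cloud, evaluated with analytic gradients at arbitrary
#' points. Shape functions form a partition of unity and reproduce affine
#' fields exactly.
#'
#' @param nodes n x 3 node cloud (mm).
#' @param points m x 3 evaluation points (mm).
#' @param params an [mls_params()].
#' @param radii optional per-node support radii (mm); when omitted they are
#'   estimated from the node cloud's nearest-neighbour spacing.
#' @return list with CSR-style fields `offsets` (0-based, length m+1), `ids`
#'   (1-based node indices), `phi`, `dphi` (gradients, 1/mm).
#' @export
mls_shape <- function(nodes, points, params = mls_params(), radii = NULL) {
  nodes <- matrix(as.numeric(nodes), ncol = 3)
  points <- matrix(as.numeric(points), ncol = 3)
  if (is.null(radii)) {
    # nearest-neighbour spacing estimate
    ns <- nrow(nodes)
    take <- if (ns > 500) sample.int(ns, 500) else seq_len(ns)
    d <- as.matrix(stats::dist(nodes[take, , drop = FALSE]))
    diag(d) <- Inf
    h <- stats::median(apply(d, 1, min))
    radii <- rep(params$support_scale * h, ns)
  }
  sing <- rep(FALSE, nrow(nodes))
  sing[params$singular_nodes] <- TRUE
  cpp_mls_shape(nodes, radii, sing, points, params$sing_eps)
}

#' Neo-Hookean second Piola-Kirchhoff stress
#'
#' Compressible neo-Hookean model with decoupled volumetric response:
#' \deqn{S = \mu J^{-2/3}\left(I - \tfrac{\mathrm{tr}C}{3}C^{-1}\right)
#'   + K J (J-1) C^{-1}}
#' with \eqn{\mu = E/2(1+\nu)}, \eqn{K = E/3(1-2\nu)}, \eqn{C = F^\top F},
#' \eqn{J = \det F}.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param E Young's modulus (Pa).
#' @param nu Poisson's ratio.
#' @return list with `S` (second Piola-Kirchhoff, Pa), `P` (first
#'   Piola-Kirchhoff) and `energy_density` (Pa).
#' @export
neo_hookean_pk2 <- function(F, E, nu) {
  F <- matrix(as.numeric(F), 3, 3)
  if (det(F) <= 0) stop("neo_hookean_pk2: det(F) must be positive")
  cpp_pk2_stress(as.numeric(F), E, nu)
}

#' MTLED solver configuration
#'
#' The explicit solver runs in scaled pseudo-time: nodal masses are scaled so
#' a unit time step is stable (mass scaling is the standard choice for
#' dynamic relaxation, where only the converged static state matters), and
#' mass-proportional damping is adapted from a Rayleigh-quotient estimate of
#' the lowest mode. Loads ramp smoothly (3-4-5 polynomial) over
#' `ramp_steps`.
#'
#' @param ramp_steps loading ramp length in steps.
#' @param max_steps step budget.
#' @param tol displacement-increment convergence tolerance (mm).
#' @param patience consecutive steps below `tol` required to declare
#'   convergence.
#' @param mass_scale safety factor on the scaled nodal masses.
#' @param damp_max_frac cap on the damping coefficient as a fraction of the
#'   critical value 2/dt.
#' @return An `mtled_config` object.
#' @export
mtled_config <- function(ramp_steps = 500L, max_steps = 20000L, tol = 1e-5,
                         patience = 100L, mass_scale = 2, damp_max_frac = 0.9) {
  stopifnot(max_steps > ramp_steps, tol > 0, mass_scale >= 0.3)
  structure(list(ramp_steps = as.integer(ramp_steps),
                 max_steps = as.integer(max_steps), tol = tol,
                 patience = as.integer(patience), mass_scale = mass_scale,
                 damp_max_frac = damp_max_frac), class = "mtled_config")
}

#' Build a meshless model (shape data at integration points)
#'
#' Precomputes the background integration points and the MLS shape values
#' and reference gradients at them. Prescribed nodes get singular
#' (interpolating) weights so essential boundary conditions are imposed
#' directly. With `consistency_correction` (the default) a first-order
#' variational-consistency correction of the test-function gradients is
#' precomputed: the Gauss-integrated gradient of every free node's test
#' function is constrained to zero (as for a test function vanishing on the
#' essential boundary) and that of every prescribed node to its boundary
#' integral \eqn{\oint \phi_a n\,d\Gamma}, which restores the exact affine
#' patch test and surface-consistent reactions under quadrature.
#'
#' @param grid a [tet_grid()] (nodes double as the meshless cloud).
#' @param prescribed_nodes node indices that will carry essential BCs.
#' @param params an [mls_params()].
#' @param E,nu material constants, recycled over integration points;
#'   override per point via [assign_materials()].
#' @param consistency_correction logical; precompute corrected test
#'   gradients used by [solve_static()].
#' @return A `meshless_model` object.
#' @export
meshless_model <- function(grid, prescribed_nodes = integer(),
                           params = mls_params(), E = 3000, nu = 0.49,
                           consistency_correction = TRUE) {
  stopifnot(inherits(grid, "tet_grid"))
  params$singular_nodes <- as.integer(prescribed_nodes)
  radii <- node_support_radii(grid, params$support_scale)
  ips <- build_integration_points(grid)
  shp <- mls_shape(grid$nodes, ips$points, params, radii)
  nip <- length(ips$weights)
  model <- structure(list(grid = grid, params = params, radii = radii,
                 ip_points = ips$points, ip_weights = ips$weights,
                 ip_element = ips$element, shape = shp,
                 prescribed = as.integer(prescribed_nodes),
                 E = rep_len(E, nip), nu = rep_len(nu, nip)),
            class = "meshless_model")
  if (consistency_correction)
    model$dphi_test <- vc_corrected_gradients(model)
  model
}

# boundary faces of the tet grid with outward normals and a 3-point
# (edge-midpoint, degree-2) quadrature
grid_boundary_quadrature <- function(grid) {
  tets <- grid$tets
  fc <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
              tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
  opp <- c(tets[, 1], tets[, 2], tets[, 3], tets[, 4])
  key <- apply(cbind(pmin(fc[, 1], pmin(fc[, 2], fc[, 3])),
                     fc[, 1] + fc[, 2] + fc[, 3],
                     pmax(fc[, 1], pmax(fc[, 2], fc[, 3]))), 1,
               paste, collapse = ",")
  once <- names(which(table(key) == 1))
  sel <- key %in% once
  fc <- fc[sel, , drop = FALSE]
  opp <- opp[sel]
  v1 <- grid$nodes[fc[, 2], , drop = FALSE] - grid$nodes[fc[, 1], , drop = FALSE]
  v2 <- grid$nodes[fc[, 3], , drop = FALSE] - grid$nodes[fc[, 1], , drop = FALSE]
  nrm <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
               v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
               v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  # outward: away from the opposite vertex of the owning tet
  cen <- (grid$nodes[fc[, 1], ] + grid$nodes[fc[, 2], ] + grid$nodes[fc[, 3], ]) / 3
  flip <- rowSums(nrm * (cen - grid$nodes[opp, , drop = FALSE])) < 0
  nrm[flip, ] <- -nrm[flip, ]
  area <- sqrt(rowSums(nrm^2)) / 2
  un <- nrm / (2 * area)
  pts <- rbind((grid$nodes[fc[, 1], ] + grid$nodes[fc[, 2], ]) / 2,
               (grid$nodes[fc[, 2], ] + grid$nodes[fc[, 3], ]) / 2,
               (grid$nodes[fc[, 1], ] + grid$nodes[fc[, 3], ]) / 2)
  list(points = pts, weights = rep(area / 3, 3), normals = rbind(un, un, un))
}

# first-order variationally consistent test gradients (see meshless_model)
vc_corrected_gradients <- function(model) {
  shp <- model$shape
  grp <- shp$ids
  went <- model$ip_weights[rep(seq_along(model$ip_weights), diff(shp$offsets))]
  r <- rowsum(went * shp$dphi, grp)          # integrated gradients per node
  s <- rowsum(went * shp$phi, grp)           # integrated shape values
  target <- matrix(0, nrow(model$grid$nodes), 3)
  if (length(model$prescribed)) {
    bq <- grid_boundary_quadrature(model$grid)
    sb <- mls_shape(model$grid$nodes, bq$points, model$params, model$radii)
    ent <- rep(seq_len(nrow(bq$points)), diff(sb$offsets))
    bint <- rowsum(sb$phi * bq$weights[ent] * bq$normals[ent, , drop = FALSE],
                   sb$ids)
    keep <- intersect(as.integer(rownames(bint)), model$prescribed)
    target[keep, ] <- bint[match(keep, as.integer(rownames(bint))), ]
  }
  nodes_present <- as.integer(rownames(r))
  resid <- r - target[nodes_present, , drop = FALSE]
  rfull <- matrix(0, nrow(model$grid$nodes), 3)
  rfull[nodes_present, ] <- resid
  sfull <- rep(1, nrow(model$grid$nodes))
  sfull[nodes_present] <- s
  delta <- -rfull[grp, , drop = FALSE] * (shp$phi / sfull[grp])
  # cap outsized corrections (possible at fringe nodes of irregular grids)
  # to keep the explicit stepping stable; regular benchmark grids are
  # untouched by the cap
  gscale <- stats::median(sqrt(rowSums(shp$dphi^2)))
  dmag <- sqrt(rowSums(delta^2))
  worst <- vapply(split(dmag, grp), max, numeric(1))
  scl <- rep(1, nrow(model$grid$nodes))
  scl[as.integer(names(worst))] <- pmin(1, 3 * gscale / pmax(worst, 1e-300))
  shp$dphi + delta * scl[grp]
}

#' @export
print.meshless_model <- function(x, ...) {
  cat(sprintf("meshless_model: %d nodes, %d integration points, %d prescribed nodes\n",
              nrow(x$grid$nodes), length(x$ip_weights), length(x$prescribed)))
  invisible(x)
}

model_moduli <- function(model) {
  list(mu = model$E / (2 * (1 + model$nu)),
       kappa = model$E / (3 * (1 - 2 * model$nu)))
}

#' Internal nodal forces of a meshless model
#'
#' Total-Lagrangian internal force vector
#' \eqn{f_a = \sum_{ip} w\, P \nabla\phi_a} for a given nodal parameter
#' field, plus the total strain energy.
#'
#' @param model a [meshless_model()].
#' @param U n x 3 nodal parameters (mm).
#' @param corrected use the variationally corrected test gradients (as the
#'   solver does); the default `FALSE` gives the plain Galerkin operator,
#'   which is the exact gradient of the total strain energy.
#' @return list with `forces` (n x 3, N assuming Pa and mm), `energy` and
#'   `min_J`.
#' @export
internal_forces <- function(model, U, corrected = FALSE) {
  m <- model_moduli(model)
  dpt <- if (corrected && !is.null(model$dphi_test)) model$dphi_test else
    model$shape$dphi
  cpp_internal_forces(model$shape$offsets, model$shape$ids, model$shape$dphi,
                      dpt, model$ip_weights, m$mu, m$kappa,
                      matrix(U, ncol = 3), FALSE)
}

#' Solve the static deformation under prescribed displacements
#'
#' Explicit central-difference iteration with adaptive dynamic relaxation:
#' prescribed nodes track the smoothly ramped target displacements exactly
#' (singular MLS weights), free nodes relax until the maximum displacement
#' increment stays below tolerance.
#'
#' @param model a [meshless_model()] whose `prescribed` set matches `loads`.
#' @param loads a `load_table` data.frame (columns `node`, `ux`, `uy`, `uz`)
#'   giving target displacements (mm) of the prescribed nodes.
#' @param config an [mtled_config()].
#' @return A `deformation_state`: nodal parameters `U`, evaluated nodal
#'   displacements `displacements`, residual forces, energy history,
#'   convergence info.
#' @export
solve_static <- function(model, loads, config = mtled_config()) {
  stopifnot(inherits(model, "meshless_model"))
  N <- nrow(model$grid$nodes)
  if (!all(loads$node %in% seq_len(N)))
    stop("solve_static: load table references unknown nodes")
  if (!setequal(loads$node, model$prescribed))
    stop("solve_static: loaded nodes must equal the model's prescribed node set")
  target <- matrix(0, N, 3)
  target[loads$node, ] <- as.matrix(loads[, c("ux", "uy", "uz")])
  fixed <- rep(FALSE, N)
  fixed[loads$node] <- TRUE
  m <- model_moduli(model)
  dpt <- if (!is.null(model$dphi_test)) model$dphi_test else model$shape$dphi
  res <- cpp_adr_solve(model$shape$offsets, model$shape$ids, model$shape$dphi,
                       dpt, model$ip_weights, m$mu, m$kappa, N, fixed, target,
                       config$ramp_steps, config$max_steps, config$tol,
                       config$patience, config$mass_scale, config$damp_max_frac)
  if (!res$converged)
    warning("solve_static: not converged in ", res$steps,
            " steps (last max increment ", signif(utils::tail(res$max_increment, 1), 3),
            " mm)")
  # evaluated displacements at the nodes (parameters != displacements for
  # non-interpolating free nodes)
  shp_n <- mls_shape(model$grid$nodes, model$grid$nodes, model$params, model$radii)
  disp <- eval_mls_field(shp_n, res$U, nrow(model$grid$nodes))
  structure(list(U = res$U, displacements = disp, forces = res$forces,
                 energy = res$energy, max_increment = res$max_increment,
                 steps = res$steps, converged = res$converged,
                 strain_energy = res$strain_energy, min_J = res$min_J,
                 model = model, fixed = fixed),
            class = "deformation_state")
}

# evaluate a nodal parameter field through CSR shape data; `values` has one
# row per node of the cloud the shape data was built on
eval_mls_field <- function(shape, values, npts) {
  values <- as.matrix(values)
  out <- matrix(0, npts, ncol(values))
  grp <- rep(seq_len(npts), diff(shape$offsets))
  for (c in seq_len(ncol(values))) {
    contrib <- shape$phi * values[shape$ids, c]
    out[, c] <- rowsum(contrib, grp)[, 1]
  }
  out
}

#' @export
print.deformation_state <- function(x, ...) {
  cat(sprintf("deformation_state: %d steps, converged=%s, max |u| = %.3g mm\n",
              x$steps, x$converged, max(abs(x$displacements))))
  invisible(x)
}

#' Assign material properties from fuzzy intensity classes
#'
#' Classifies image intensities inside a mask into fuzzy classes (FCM on the
#' scalar intensity) and assigns each integration point the
#' membership-weighted Young's modulus \eqn{E = \sum_c u_c E_c}; Poisson's
#' ratio is constant. Integration points outside the image fall back to the
#' nearest voxel with a warning.
#'
#' @param model a [meshless_model()].
#' @param intensity a [scalar_image()].
#' @param mask a [mask_image()].
#' @param class_E numeric vector of per-class Young's moduli (Pa), ordered by
#'   ascending class centre intensity.
#' @param nu Poisson's ratio (constant).
#' @param fcm_config an [fcm_config()].
#' @return The model with per-integration-point `E` and `nu` set.
#' @export
assign_materials <- function(model, intensity, mask, class_E, nu = 0.49,
                             fcm_config = NULL) {
  stopifnot(inherits(model, "meshless_model"), inherits(intensity, "scalar_image"))
  nc <- length(class_E)
  if (is.null(fcm_config)) fcm_config <- fcm_config(n_clusters = nc)
  if (fcm_config$n_clusters != nc)
    stop("assign_materials: class_E length must match n_clusters")
  sel <- as.vector(mask$values)
  x <- matrix(as.vector(intensity$values)[sel], ncol = 1)
  fit <- fcm(x, fcm_config)
  ord <- order(fit$centers[, 1])
  # membership image per class
  grid <- intensity$grid
  Eimg <- numeric(length(sel))
  memb <- matrix(0, length(sel), nc)
  memb[sel, ] <- fit$memberships[, ord]
  Evox <- as.vector(memb %*% class_E)
  Evox[!sel] <- NA
  idx <- world_to_index(grid, model$ip_points)
  # trilinear where possible; nearest voxel fallback outside mask/image
  d <- grid$dims
  ni <- pmin(pmax(round(idx[, 1]), 0), d[1] - 1)
  nj <- pmin(pmax(round(idx[, 2]), 0), d[2] - 1)
  nk <- pmin(pmax(round(idx[, 3]), 0), d[3] - 1)
  lin <- 1 + ni + d[1] * nj + d[1] * d[2] * nk
  Eip <- Evox[lin]
  nbad <- sum(is.na(Eip))
  if (nbad > 0) {
    warning("assign_materials: ", nbad,
            " integration points outside the mask; using nearest in-mask voxel")
    sel_idx <- which(sel)
    ctr <- voxel_centers(grid)[sel_idx, , drop = FALSE]
    for (i in which(is.na(Eip))) {
      j <- which.min(colSums((t(ctr) - model$ip_points[i, ])^2))
      Eip[i] <- Evox[sel_idx[j]]
    }
  }
  model$E <- Eip
  model$nu <- rep_len(nu, length(Eip))
  model
}
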