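#' Displacement field on an image grid
#'
#' A [vector_image()] of world-space displacements (mm) tagged with its
#' direction: `"forward"` maps reference to deformed positions
#' (`x -> x + u(x)`), `"backward"` maps deformed to reference.
#'
#' @param values 3 x dims displacement array (mm).
#' @param grid an [image_grid()].
#' @param direction `"forward"` or `"backward"`.
#' @return A `displacement_field` (also a `vector_image`).
#' @export
displacement_field <- function(values, grid, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  img <- vector_image(values, grid)
  img$direction_kind <- direction
  class(img) <- c("displacement_field", class(img))
  img
}

#' Project a meshless solution onto an image grid
#'
#' Evaluates the solved displacement field at voxel centres inside a mask
#' using the same MLS shape functions as the solver, producing the forward
#' displacement field transform. Voxels without sufficient MLS support are
#' zero-filled and counted in a warning.
#'
#' @param state a `deformation_state` from [solve_static()].
#' @param grid target [image_grid()].
#' @param mask optional [mask_image()]; outside voxels get zero.
#' @return A [displacement_field()] (forward).
#' @export
field_from_solution <- function(state, grid, mask = NULL) {
  stopifnot(inherits(state, "deformation_state"))
  model <- state$model
  ctr <- voxel_centers(grid)
  sel <- if (is.null(mask)) rep(TRUE, nrow(ctr)) else as.vector(mask$values)
  vals <- matrix(0, nrow(ctr), 3)
  pts <- ctr[sel, , drop = FALSE]
  ok <- rep(TRUE, nrow(pts))
  res <- tryCatch(
    eval_mls_field(mls_shape(model$grid$nodes, pts, model$params, model$radii),
                   state$U, nrow(pts)),
    error = function(e) NULL)
  if (is.null(res)) {
    # some voxels lack support: evaluate point-wise, zero where unsupported
    res <- matrix(0, nrow(pts), 3)
    nbad <- 0L
    for (i in seq_len(nrow(pts))) {
      r <- tryCatch(
        eval_mls_field(mls_shape(model$grid$nodes, pts[i, , drop = FALSE],
                                 model$params, model$radii), state$U, 1L),
        error = function(e) NULL)
      if (is.null(r)) nbad <- nbad + 1L else res[i, ] <- r
    }
    if (nbad > 0)
      warning("field_from_solution: ", nbad,
              " voxels without MLS support set to zero")
  }
  vals[sel, ] <- res
  displacement_field(t(vals), grid, "forward")
}

#' Invert a forward displacement field
#'
#' Fixed-point iteration `v_{k+1}(x) = -u(x + v_k(x))` for the backward
#' field `v` of a forward field `u`, iterated until the composition residual
#' `|v(x) + u(x + v(x))|` falls below `tol` everywhere (or `max_iter`).
#'
#' @param fwd a forward [displacement_field()].
#' @param tol residual tolerance in mm (default 0.05).
#' @param max_iter iteration budget (default 50).
#' @param relax under-relaxation factor of the fixed-point update (1 = plain
#'   iteration; smaller values help near the contraction limit).
#' @param max_fail_frac fraction of voxels allowed to miss `tol` (default 0:
#'   any failure is an error). Fields with sliding interfaces (e.g. brain
#'   shift under a static skull) are discontinuous there and cannot be
#'   inverted pointwise; a small allowance turns those voxels into a warning
#'   instead.
#' @return A backward [displacement_field()].
#' @export
invert_field <- function(fwd, tol = 0.05, max_iter = 50L, relax = 1,
                         max_fail_frac = 0) {
  stopifnot(inherits(fwd, "displacement_field"),
            fwd$direction_kind == "forward")
  grid <- fwd$grid
  ctr <- voxel_centers(grid)
  d <- grid$dims
  # clamped sampler: border voxels whose preimage leaves the grid by a
  # fraction of a voxel would otherwise oscillate against the background
  sample_clamped <- function(pts) {
    idx <- world_to_index(grid, pts)
    for (ax in 1:3) idx[, ax] <- pmin(pmax(idx[, ax], 0), d[ax] - 1)
    cpp_trilinear(as.numeric(fwd$values), d, 3L, idx, 0)
  }
  v <- matrix(0, nrow(ctr), 3)
  res_inf <- Inf
  for (it in seq_len(max_iter)) {
    vnew <- -sample_clamped(ctr + v)
    res_inf <- max(abs(vnew - v))
    v <- v + relax * (vnew - v)
    if (res_inf < tol / 2) break
  }
  # composition residual |v(x) + u(x + v(x))|, judged where the pulled-back
  # sample stays inside the field's domain (border voxels whose preimage
  # leaves the grid cannot be inverted from gridded data)
  idx <- world_to_index(grid, ctr + v)
  inside <- idx[, 1] >= 0 & idx[, 2] >= 0 & idx[, 3] >= 0 &
    idx[, 1] <= grid$dims[1] - 1 & idx[, 2] <= grid$dims[2] - 1 &
    idx[, 3] <= grid$dims[3] - 1
  comp <- sqrt(rowSums((v + resample_trilinear(fwd, ctr + v))^2))
  comp[!inside] <- 0
  nfail <- sum(comp > tol)
  if (nfail > max_fail_frac * sum(inside)) {
    worst <- which.max(comp)
    stop(sprintf(paste0("invert_field: not converged (residual %.3g mm at voxel ",
                        "%d, world (%.1f, %.1f, %.1f); %d voxels above tol); ",
                        "displacements may be too large for fixed-point inversion"),
                 max(comp), worst, ctr[worst, 1], ctr[worst, 2], ctr[worst, 3],
                 nfail))
  }
  if (nfail > 0)
    warning("invert_field: ", nfail, " voxels exceed the composition tolerance ",
            "(max residual ", signif(max(comp), 3), " mm), likely at a sliding ",
            "interface of the field")
  displacement_field(t(v), grid, "backward")
}

#' Warp a scalar image with a backward displacement field
#'
#' `out(x) = in(x + v(x))` by trilinear sampling, the pull-back resampling
#' used to predict the postoperative image from the preoperative one.
#'
#' @param img a [scalar_image()].
#' @param backward a backward [displacement_field()] on a compatible grid.
#' @param background value for samples outside the input image.
#' @return A [scalar_image()] on the field's grid.
#' @export
warp_scalar <- function(img, backward, background = 0) {
  stopifnot(inherits(img, "scalar_image"),
            inherits(backward, "displacement_field"),
            backward$direction_kind == "backward")
  ctr <- voxel_centers(backward$grid)
  v <- matrix(backward$values, nrow = 3)
  out <- resample_trilinear(img, ctr + t(v), background = background)
  scalar_image(out, backward$grid)
}

# central-difference Jacobian of a displacement field: returns 9 x n column-
# major d(x + v)/dx per voxel (one-sided at borders)
field_jacobian <- function(field) {
  g <- field$grid
  d <- g$dims
  v <- array(field$values, c(3, d))
  J <- matrix(0, 9, prod(d))
  A <- g$direction %*% diag(g$spacing)  # d world / d index
  Ainv <- solve(A)
  for (comp in 1:3) {
    vi <- array(v[comp, , , ], d)
    for (ax in 1:3) {
      hi <- vi
      lo <- vi
      idx_p <- pmin(seq_len(d[ax]) + 1, d[ax])
      idx_m <- pmax(seq_len(d[ax]) - 1, 1)
      if (ax == 1) { hi <- vi[idx_p, , , drop = FALSE]; lo <- vi[idx_m, , , drop = FALSE] }
      if (ax == 2) { hi <- vi[, idx_p, , drop = FALSE]; lo <- vi[, idx_m, , drop = FALSE] }
      if (ax == 3) { hi <- vi[, , idx_p, drop = FALSE]; lo <- vi[, , idx_m, drop = FALSE] }
      den <- rep(2, d[ax])
      den[1] <- 1
      den[d[ax]] <- 1
      den_arr <- switch(ax,
                        array(rep(den, times = d[2] * d[3]), d),
                        aperm(array(rep(den, times = d[1] * d[3]), d[c(2, 1, 3)]), c(2, 1, 3)),
                        aperm(array(rep(den, times = d[1] * d[2]), d[c(3, 1, 2)]), c(2, 3, 1)))
      # dv_comp / d index_ax
      didx <- (hi - lo) / den_arr
      # chain rule to world derivatives: dv/dworld = dv/didx * Ainv[ax, ]
      for (wx in 1:3)
        J[comp + 3 * (wx - 1), ] <- J[comp + 3 * (wx - 1), ] +
          as.vector(didx) * Ainv[ax, wx]
    }
  }
  J
}

#' Warp a diffusion tensor image (PPD reorientation)
#'
#' Resamples tensor components linearly at the pulled-back positions, then
#' reorients each tensor with the preservation-of-principal-direction (PPD)
#' method: the local forward-map Jacobian rotates the principal eigenvector
#' to `F e1 / |F e1|` and the second eigenvector to the Gram-Schmidt
#' projection of `F e2`; eigenvalues are preserved exactly. The forward
#' Jacobian is obtained from the backward field as
#' `F = (I + grad v)^{-1}` by central differences (identity is used at
#' voxels with singular Jacobian, with a warning).
#'
#' @param dti a [tensor_image()].
#' @param backward a backward [displacement_field()].
#' @return A [tensor_image()] on the field's grid.
#' @export
warp_dti <- function(dti, backward) {
  stopifnot(inherits(dti, "tensor_image"),
            inherits(backward, "displacement_field"),
            backward$direction_kind == "backward")
  grid <- backward$grid
  ctr <- voxel_centers(grid)
  v <- t(matrix(backward$values, nrow = 3))
  t6 <- t(resample_tensor(dti, ctr + v))
  # backward-map Jacobian d(x + v)/dx, inverted to the forward Jacobian
  Jb <- field_jacobian(backward)
  Jb[c(1, 5, 9), ] <- Jb[c(1, 5, 9), ] + 1
  # vectorized 3x3 inversion by adjugate (column-major packing)
  b11 <- Jb[1, ]; b21 <- Jb[2, ]; b31 <- Jb[3, ]
  b12 <- Jb[4, ]; b22 <- Jb[5, ]; b32 <- Jb[6, ]
  b13 <- Jb[7, ]; b23 <- Jb[8, ]; b33 <- Jb[9, ]
  det <- b11 * (b22 * b33 - b23 * b32) - b12 * (b21 * b33 - b23 * b31) +
         b13 * (b21 * b32 - b22 * b31)
  sing <- !is.finite(det) | abs(det) < 1e-12
  dets <- ifelse(sing, 1, det)
  Ff <- rbind((b22 * b33 - b23 * b32) / dets,
              -(b21 * b33 - b23 * b31) / dets,
              (b21 * b32 - b22 * b31) / dets,
              -(b12 * b33 - b13 * b32) / dets,
              (b11 * b33 - b13 * b31) / dets,
              -(b11 * b32 - b12 * b31) / dets,
              (b12 * b23 - b13 * b22) / dets,
              -(b11 * b23 - b13 * b21) / dets,
              (b11 * b22 - b12 * b21) / dets)
  nsing <- sum(sing)
  if (nsing > 0) Ff[, sing] <- c(1, 0, 0, 0, 1, 0, 0, 0, 1)
  if (nsing > 0)
    warning("warp_dti: ", nsing, " voxels with singular Jacobian; identity reorientation")
  out <- cpp_ppd(t6, Ff)
  tensor_image(out, grid)
}
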