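test_that("solution fields reproduce rigid and affine nodal displacements", {
  g <- structured_tet_grid(c(0, 0, 0), c(20, 20, 20), c(4, 4, 4))
  model <- meshless_model(g, consistency_correction = FALSE)
  grid <- image_grid(c(11, 11, 11), spacing = c(1.6, 1.6, 1.6),
                     origin = c(2, 2, 2))
  N <- nrow(g$nodes)
  # zero deformation -> zero field
  st0 <- structure(list(U = matrix(0, N, 3), model = model),
                   class = "deformation_state")
  f0 <- field_from_solution(st0, grid)
  expect_equal(max(abs(f0$values)), 0)
  # rigid translation
  tr <- matrix(rep(c(1, -2, 0.5), each = N), N, 3)
  ft <- field_from_solution(structure(list(U = tr, model = model),
                                      class = "deformation_state"), grid)
  v <- matrix(ft$values, 3)
  expect_lt(max(abs(v - c(1, -2, 0.5))), 1e-9)
  # affine nodal displacement -> affine field at voxel centres
  A <- matrix(c(0.03, 0.01, 0, -0.01, 0.02, 0.005, 0, 0.01, -0.02), 3, 3)
  ua <- t(A %*% t(g$nodes))
  fa <- field_from_solution(structure(list(U = ua, model = model),
                                      class = "deformation_state"), grid)
  ctr <- voxel_centers(grid)
  expect_lt(max(abs(t(matrix(fa$values, 3)) - t(A %*% t(ctr)))), 1e-8)
})

test_that("field inversion: zero, constant, and smooth sinusoidal fields", {
  g <- image_grid(c(24, 24, 24), spacing = c(2, 2, 2), origin = c(-23, -23, -23))
  ctr <- voxel_centers(g)
  z <- displacement_field(matrix(0, 3, 24^3), g, "forward")
  expect_equal(max(abs(invert_field(z)$values)), 0)
  cst <- displacement_field(matrix(c(1.5, -1, 2), 3, 24^3), g, "forward")
  vi <- matrix(invert_field(cst, tol = 0.01)$values, 3)
  # constant translation inverts to -t (judged away from the border where
  # the pulled-back samples stay inside)
  interior <- apply(abs(ctr), 1, max) < 18
  expect_lt(max(abs(t(vi)[interior, ] - rep(c(-1.5, 1, -2), each = sum(interior)))),
            0.01)
  # smooth sinusoidal field, 3 mm amplitude: composition residual < 0.1 voxel
  u <- 3 * cbind(sin(pi * ctr[, 1] / 24) * cos(pi * ctr[, 2] / 24),
                 sin(pi * ctr[, 2] / 24) * cos(pi * ctr[, 3] / 24),
                 sin(pi * ctr[, 3] / 24))
  fwd <- displacement_field(t(u), g, "forward")
  bwd <- invert_field(fwd, tol = 0.2)
  v <- t(matrix(bwd$values, 3))
  comp <- sqrt(rowSums((v + resample_trilinear(fwd, ctr + v))^2))
  expect_lt(max(comp[interior]) / 2, 0.1)
})

test_that("scalar warping pulls back images and round-trips through the inverse", {
  g <- image_grid(c(24, 24, 24), spacing = c(2, 2, 2), origin = c(-23, -23, -23))
  ctr <- voxel_centers(g)
  img <- scalar_image(sin(ctr[, 1] / 9) * cos(ctr[, 2] / 7) +
                        0.5 * sin(ctr[, 3] / 11), g)
  # zero field: identical image
  z <- displacement_field(matrix(0, 3, 24^3), g, "backward")
  expect_equal(warp_scalar(img, z)$values, img$values)
  # exact one-voxel translation: interior voxels bit-equal to the shift
  tr <- displacement_field(matrix(c(2, 0, 0), 3, 24^3), g, "backward")
  w <- warp_scalar(img, tr)
  expect_equal(w$values[1:22, , ], img$values[2:23, , ], tolerance = 1e-14)
  # warp then inverse-warp of a smooth image stays within 2% of range
  u <- 3 * cbind(sin(pi * ctr[, 1] / 24) * cos(pi * ctr[, 2] / 24),
                 sin(pi * ctr[, 2] / 24) * cos(pi * ctr[, 3] / 24),
                 sin(pi * ctr[, 3] / 24))
  fwd <- displacement_field(t(u), g, "forward")
  bwd <- invert_field(fwd, tol = 0.2)
  wimg <- warp_scalar(img, bwd)
  # inverse-warp: the forward field itself acts as the backward transform of
  # the inverse mapping
  back <- warp_scalar(wimg, displacement_field(fwd$values, g, "backward"))
  rng <- diff(range(img$values))
  err <- abs(back$values - img$values)[6:19, 6:19, 6:19]
  expect_lt(max(err) / rng, 0.02)
})

test_that("PPD reorientation rotates eigenframes and preserves eigenvalues", {
  g <- image_grid(c(20, 20, 20), spacing = c(2, 2, 2), origin = c(-19, -19, -19))
  ctr <- voxel_centers(g)
  lam <- c(1.7e-3, 0.3e-3, 0.2e-3)
  t6 <- matrix(mat_to_sym6(diag(lam)), 6, nrow(ctr))
  dti <- tensor_image(t6, g)
  # zero field: identical tensors
  z <- displacement_field(matrix(0, 3, 20^3), g, "backward")
  expect_equal(warp_dti(dti, z)$values, dti$values, tolerance = 1e-12)
  # global rigid rotation
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  v <- t(R) %*% t(ctr) - t(ctr)
  wd <- warp_dti(dti, displacement_field(matrix(v, 3), g, "backward"))
  eg <- ecogfwd:::cpp_sym3_eig(matrix(wd$values, 6))
  interior <- which(apply(abs(ctr), 1, max) < 15)
  target <- as.numeric(R %*% c(1, 0, 0))
  ang <- acos(pmin(1, abs(colSums(eg$vectors[1:3, interior] * target))))
  expect_lt(max(ang), 1e-6)
  expect_lt(max(abs(eg$values[, interior] - lam)), 1e-12)
  # pure shear on isotropic tensors: unchanged
  iso <- tensor_image(matrix(mat_to_sym6(diag(3) * 1e-3), 6, nrow(ctr)), g)
  shear <- displacement_field(rbind(0.1 * ctr[, 2], 0 * ctr[, 1], 0 * ctr[, 1]),
                              g, "backward")
  wiso <- warp_dti(iso, shear)
  # compare away from the border, where pulled-back samples leave the domain
  din <- array(abs(wiso$values - iso$values), c(6, 20, 20, 20))
  expect_lt(max(din[, 5:16, 5:16, 5:16]), 1e-12)
})
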