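test_that("voxel hex meshing merges shared corners and conserves volume", {
  g <- image_grid(c(2, 2, 2), spacing = c(1.5, 1, 2))
  mesh <- voxels_to_hexmesh(mask_image(array(TRUE, c(2, 2, 2)), g))
  expect_equal(nrow(mesh$elems), 8)
  expect_equal(nrow(mesh$nodes), 27)
  set.seed(14)
  m <- array(runif(6^3) < 0.4, c(6, 6, 6))
  m[1, 1, 1] <- TRUE
  g6 <- image_grid(c(6, 6, 6), spacing = c(1.5, 1, 2))
  mesh <- voxels_to_hexmesh(mask_image(m, g6))
  expect_equal(nrow(mesh$elems), sum(m))
  # element volumes sum to the voxel volume total
  expect_equal(nrow(mesh$elems) * voxel_volume(g6), sum(m) * 3, tolerance = 1e-9)
  expect_error(voxels_to_hexmesh(mask_image(array(FALSE, c(6, 6, 6)), g6)),
               "empty")
})

test_that("assembled stiffness matches an independent dense assembly on one element", {
  g <- image_grid(c(1, 1, 1), spacing = c(1, 1, 1))
  mesh <- voxels_to_hexmesh(mask_image(array(TRUE, c(1, 1, 1)), g))
  sig6 <- matrix(c(1, 0, 0, 1, 0, 1), 6, 1)
  K <- as.matrix(as_sparse_matrix(assemble_system(mesh, sig6)))
  # oracle: independent Gauss integration of grad(Na) . grad(Nb) on [0,1]^3
  # in the VTK hexahedron corner order used by the mesh
  hexoff <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  gl <- list(x = c(-1, 1) / sqrt(3) / 2 + 0.5, w = c(0.5, 0.5))
  Ko <- matrix(0, 8, 8)
  for (ix in 1:2) for (iy in 1:2) for (iz in 1:2) {
    p <- c(gl$x[ix], gl$x[iy], gl$x[iz])
    w <- gl$w[ix] * gl$w[iy] * gl$w[iz]
    dN <- t(vapply(1:8, function(a) {
      o <- hexoff[a, ]
      f <- ifelse(o == 1, p, 1 - p)
      df <- ifelse(o == 1, 1, -1)
      c(df[1] * f[2] * f[3], f[1] * df[2] * f[3], f[1] * f[2] * df[3])
    }, numeric(3)))
    Ko <- Ko + w * dN %*% t(dN)
  }
  # map local corner order to global node ids
  perm <- mesh$elems[1, ]
  Kd <- matrix(0, 8, 8)
  Kd[perm, perm] <- Ko
  expect_equal(K, unname(Kd), tolerance = 1e-12)
  # null space and linearity
  expect_lt(max(abs(K %*% rep(1, 8))), 1e-12)
  K2 <- as.matrix(as_sparse_matrix(assemble_system(mesh, 2 * sig6)))
  expect_equal(K2, 2 * K, tolerance = 1e-14)
  expect_lt(max(abs(K - t(K))), 1e-14)
})

test_that("stiffness is SPD on the gauge-fixed subspace of a small mesh", {
  g <- image_grid(c(3, 3, 3), spacing = c(1.3, 1, 0.8))
  set.seed(2)
  mesh <- voxels_to_hexmesh(mask_image(array(TRUE, c(3, 3, 3)), g))
  sv <- runif(nrow(mesh$elems), 0.1, 2)
  sig6 <- rbind(sv, 0, 0, sv, 0, sv)
  K <- as.matrix(as_sparse_matrix(assemble_system(mesh, sig6)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(abs(ev[length(ev)]), 1e-10)       # constants in the null space
  expect_gt(ev[length(ev) - 1], 1e-8)         # rest strictly positive
})

test_that("full-subtraction load: compatibility, linearity, homogeneity", {
  d <- 11
  g <- image_grid(rep(d, 3), spacing = c(2, 2, 2),
                  origin = rep(-(d - 1), 3))
  lab <- make_sphere_phantom(sphere_phantom_spec(9, 1L, grid_dims = rep(d, 3),
                                                 spacing = c(2, 2, 2)))
  mesh <- voxels_to_hexmesh(lab)
  sig6 <- matrix(c(0.33, 0, 0, 0.33, 0, 0.33), 6, nrow(mesh$elems))
  dip <- dipole_source(c(0.4, 0.3, 4), c(1e-3, 0, 0), sigma0 = diag(3) * 0.33)
  rhs <- full_subtraction_rhs(mesh, sig6, dip)
  # compatibility: the load sums to zero up to the face-quadrature error of
  # the steep singularity gradient on this deliberately coarse phantom
  expect_lt(abs(sum(rhs$b)), 1e-4 * sum(abs(rhs$b)))
  # moment flip negates the load
  dip2 <- dipole_source(c(0.4, 0.3, 4), c(-1e-3, 0, 0), sigma0 = diag(3) * 0.33)
  expect_equal(full_subtraction_rhs(mesh, sig6, dip2)$b, -rhs$b,
               tolerance = 1e-12)
  # homogeneous conductivity: the volume term vanishes, so doubling the
  # deviation tolerance changes nothing
  sig_in <- sig6
  sig_in[1, 10] <- 0.66  # off-centre heterogeneity far from the dipole
  sig_in[4, 10] <- 0.66
  sig_in[6, 10] <- 0.66
  rhs_h <- full_subtraction_rhs(mesh, sig_in, dip)
  expect_gt(max(abs(rhs_h$b - rhs$b)), 0)
  # inhomogeneity in the element next to the dipole is rejected
  vox_dip <- round(ecogfwd:::world_to_index(g, matrix(c(0.4, 0.3, 4), 1)))
  lin_dip <- 1 + vox_dip[1] + d * vox_dip[2] + d^2 * vox_dip[3]
  e_near <- match(lin_dip, mesh$voxel)
  sig_bad <- sig6
  sig_bad[c(1, 4, 6), e_near] <- 1.79
  expect_error(full_subtraction_rhs(mesh, sig_bad, dip), "inhomogeneous")
})

test_that("conjugate gradients solves the gauge-fixed system to tolerance", {
  g <- image_grid(c(4, 4, 4))
  mesh <- voxels_to_hexmesh(mask_image(array(TRUE, c(4, 4, 4)), g))
  sig6 <- matrix(c(1, 0, 0, 1, 0, 1), 6, nrow(mesh$elems))
  K <- assemble_system(mesh, sig6)
  set.seed(4)
  b <- rnorm(nrow(mesh$nodes))
  b <- b - mean(b)
  sol <- ecogfwd:::cpp_cg(K$row_ptr, K$col, K$val, b, 1e-10, 2000L)
  Km <- as_sparse_matrix(K)
  expect_lt(sqrt(sum((as.vector(Km %*% sol$x) - b)^2)) / sqrt(sum(b^2)), 1e-9)
  expect_lt(abs(mean(sol$x)), 1e-12)
  # zero load gives the zero solution
  s0 <- ecogfwd:::cpp_cg(K$row_ptr, K$col, K$val, rep(0, nrow(mesh$nodes)),
                         1e-10, 100L)
  expect_equal(max(abs(s0$x)), 0)
})

test_that("potential sampling is exact for nodal and linear fields", {
  g <- image_grid(c(5, 5, 5), spacing = c(2, 2, 2))
  mesh <- voxels_to_hexmesh(mask_image(array(TRUE, c(5, 5, 5)), g))
  lin <- 2 + 0.3 * mesh$nodes[, 1] - 0.1 * mesh$nodes[, 2] + 0.05 * mesh$nodes[, 3]
  sol <- structure(list(potential = lin, correction = lin * 0,
                        phi_inf = lin * 0, iterations = 0, relres = 0),
                   class = "forward_solution")
  # at a node
  expect_equal(sample_potentials(sol, mesh, mesh$nodes[17, , drop = FALSE]),
               lin[17], tolerance = 1e-12)
  set.seed(6)
  pts <- matrix(runif(30, 0, 8), ncol = 3)
  expect_equal(sample_potentials(sol, mesh, pts),
               2 + 0.3 * pts[, 1] - 0.1 * pts[, 2] + 0.05 * pts[, 3],
               tolerance = 1e-12)
  expect_error(sample_potentials(sol, mesh, matrix(c(50, 50, 50), 1)),
               "outside")
})

test_that("the solution is invariant to the labelling of equivalent inputs", {
  # solving from a label image or its mask gives identical potentials
  lab <- make_sphere_phantom(sphere_phantom_spec(9, 1L, grid_dims = rep(11, 3),
                                                 spacing = c(2, 2, 2)))
  msk <- mask_image(lab$values > 0, lab$grid)
  t6 <- matrix(0, 6, prod(lab$grid$dims))
  t6[c(1, 4, 6), as.vector(lab$values) > 0] <- 0.33
  cond <- tensor_image(t6, lab$grid)
  dip <- dipole_source(c(0, 0, 4), c(1e-3, 0, 0), sigma0 = diag(3) * 0.33)
  s1 <- forward_solve(lab, cond, dip, tol = 1e-9)
  s2 <- forward_solve(msk, cond, dip, tol = 1e-9)
  expect_equal(s1$solution$potential, s2$solution$potential, tolerance = 1e-10)
})
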