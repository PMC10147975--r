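test_that("sphere phantom volume matches a supersampled oracle", {
  spec <- sphere_phantom_spec(10, 1L, grid_dims = c(32, 32, 32))
  lab <- make_sphere_phantom(spec)
  n_in <- sum(lab$values > 0)
  # oracle: 5x supersampled voxel counting of the same ball
  ss <- 5
  off <- (seq_len(ss) - (ss + 1) / 2) / ss
  sub <- as.matrix(expand.grid(off, off, off))
  ctr <- voxel_centers(lab$grid)
  frac <- vapply(seq_len(nrow(ctr)), function(i) {
    mean(rowSums(sweep(sub, 2, ctr[i, ], `+`)^2) <= 100)
  }, numeric(1))
  v_oracle <- sum(frac)
  expect_lt(abs(n_in - v_oracle) / v_oracle, 0.02)
  expect_lt(abs(n_in - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
})

test_that("sphere phantom validates its spec and nests layers", {
  expect_error(sphere_phantom_spec(numeric(0)), "at least one")
  expect_error(sphere_phantom_spec(c(10, 12)), "decreasing")
  expect_error(sphere_phantom_spec(c(10, 5), layer_labels = c(1, 1)), "distinct")
  expect_error(sphere_phantom_spec(100, grid_dims = c(32, 32, 32)), "exceeds")
  spec <- sphere_phantom_spec(c(10, 6), c(1L, 2L), grid_dims = c(32, 32, 32))
  lab <- make_sphere_phantom(spec)
  inner <- lab$values == 2
  expect_true(all(lab$values[inner] > 0))
  ctr <- voxel_centers(lab$grid)
  r <- sqrt(rowSums(ctr^2))
  expect_true(all(r[as.vector(inner)] <= 6))
  expect_true(all((lab$values > 0) [inner]))  # inner labels subset of the union
})

test_that("synthetic DTI builds the requested eigensystem deterministically", {
  spec <- sphere_phantom_spec(6, 1L, grid_dims = c(16, 16, 16))
  lab <- make_sphere_phantom(spec)
  # isotropic: every voxel tensor equals d I
  iso <- make_synthetic_dti(lab, synthetic_dti_spec(list(`1` = rep(2e-3, 3))))
  t6 <- matrix(iso$values, 6)
  sel <- as.vector(lab$values) == 1
  expect_equal(max(abs(t6[c(1, 4, 6), sel] - 2e-3)), 0)
  expect_equal(max(abs(t6[c(2, 3, 5), sel])), 0)
  # constant x fibre: principal eigenvector = x everywhere
  ani <- make_synthetic_dti(lab, synthetic_dti_spec(
    list(`1` = c(3e-3, 0.3e-3, 0.3e-3)), field = "constant",
    direction = c(1, 0, 0)))
  a6 <- matrix(ani$values, 6)[, sel, drop = FALSE]
  eg <- ecogfwd:::cpp_sym3_eig(a6)
  expect_lt(max(1 - abs(eg$vectors[1, ])), 1e-12)
  # determinism under a fixed seed
  sp <- synthetic_dti_spec(list(`1` = c(1e-3, 1e-3, 1e-3)), noise_sd = 1e-4,
                           seed = 9L)
  expect_identical(make_synthetic_dti(lab, sp)$values,
                   make_synthetic_dti(lab, sp)$values)
  expect_error(make_synthetic_dti(lab, synthetic_dti_spec(list(`7` = rep(1e-3, 3)))),
               "label")
})

test_that("infinite-medium dipole potential matches closed forms and a transform oracle", {
  set.seed(4)
  pts <- matrix(rnorm(60, sd = 30), ncol = 3)
  m <- c(1.2, -0.5, 2)
  r0 <- c(1, 2, 3)
  # isotropic reduction
  phi <- analytic_dipole_infinite(0.33, r0, m, pts)
  s <- sweep(pts, 2, r0)
  expect_equal(phi, as.vector(s %*% m) / (4 * pi * 0.33 * rowSums(s^2)^1.5),
               tolerance = 1e-14)
  # on-axis value and antipodal sign flip
  phi_ax <- analytic_dipole_infinite(0.33, c(0, 0, 0), c(0, 0, 2),
                                     rbind(c(0, 0, 5), c(0, 0, -5)))
  expect_equal(phi_ax[1], 2 / (4 * pi * 0.33 * 25), tolerance = 1e-14)
  expect_equal(phi_ax[1], -phi_ax[2], tolerance = 1e-14)
  # anisotropic vs change-of-variables oracle r' = S^{-1/2} r
  S <- diag(c(0.66, 0.33, 0.33))
  phi_a <- analytic_dipole_infinite(S, r0, m, pts)
  W <- diag(1 / sqrt(diag(S)))
  # phi(r) = (det S)^{-1/2} phi_iso(W r; sigma = 1, moment W m) evaluated at W r0
  phi_o <- analytic_dipole_infinite(1, as.numeric(W %*% r0), as.numeric(W %*% m),
                                    t(W %*% t(pts))) / sqrt(det(S))
  expect_equal(phi_a, phi_o, tolerance = 1e-12)
  expect_error(analytic_dipole_infinite(diag(c(1, 1, 0)), r0, m, pts), "positive")
  expect_error(analytic_dipole_infinite(0.33, r0, m, rbind(r0)), "coincides")
})

test_that("multilayer sphere series matches the central-dipole closed form", {
  pts <- 80 * fib_dirs(64)
  for (mom in list(c(0, 0, 2), c(2, 0, 0), c(1, -1, 0.5))) {
    m <- analytic_sphere_model(80, 0.33, c(0, 0, 0), mom)
    phi <- analytic_dipole_sphere(m, pts)$potential
    ref <- 3 * (pts %*% mom) / 80 / (4 * pi * 0.33 * 80^2)
    expect_equal(phi, as.vector(ref), tolerance = 1e-12)
  }
})

test_that("multilayer series self-converges and degenerates to the homogeneous case", {
  pts <- 80 * fib_dirs(100)
  m60 <- analytic_sphere_model(80, 0.33, c(0, 0, 40), c(1, 1, 1), n_terms = 60)
  m120 <- analytic_sphere_model(80, 0.33, c(0, 0, 40), c(1, 1, 1), n_terms = 120)
  p60 <- analytic_dipole_sphere(m60, pts, tol = 0)$potential
  p120 <- analytic_dipole_sphere(m120, pts, tol = 0)$potential
  expect_lt(max(abs(p60 - p120)) / max(abs(p120)), 1e-8)
  # all-layers-equal 3-layer model equals the homogeneous solution
  m3 <- analytic_sphere_model(c(40, 60, 80), rep(0.33, 3), c(0, 0, 20), c(1, 2, 3),
                              n_terms = 150)
  m1 <- analytic_sphere_model(80, 0.33, c(0, 0, 20), c(1, 2, 3), n_terms = 150)
  p3 <- analytic_dipole_sphere(m3, pts)$potential
  p1 <- analytic_dipole_sphere(m1, pts)$potential
  expect_lt(max(abs(p3 - p1)), 1e-10 * max(abs(p1)))
  expect_error(analytic_sphere_model(80, 0.33, c(0, 0, 90), c(1, 0, 0)), "inside")
})

test_that("synthetic electrode grids sit on the surface with the exact inward shift", {
  surf <- brain_sphere_surface()
  eg <- make_electrode_grid(surf, 8, 8, 10, inward_shift = 0, seed = 1)
  expect_equal(ps_coords(eg$orig), ps_coords(eg$proj))      # zero shift
  eg <- make_electrode_grid(surf, 8, 8, 10, inward_shift = 5, seed = 1)
  expect_equal(nrow(eg$proj), 64)
  d <- sqrt(rowSums((ps_coords(eg$orig) - ps_coords(eg$proj))^2))
  expect_lt(max(abs(d - 5)), 1e-9)
  # projected points lie on the surface
  cp <- project_points_to_surface(eg$proj, surf)
  expect_lt(max(attr(cp, "distance")), 1e-8)
  # reproducible given the seed
  eg2 <- make_electrode_grid(surf, 8, 8, 10, inward_shift = 5, seed = 1)
  expect_identical(ps_coords(eg$proj), ps_coords(eg2$proj))
  expect_error(make_electrode_grid(surf, 30, 30, 20, 1, 1), "fit")
})

test_that("shape and magnitude error metrics behave as defined", {
  v <- c(1, -2, 3, 0.5)
  expect_equal(rdm_mag(v, v), list(rdm = 0, mag = 1))
  expect_equal(rdm_mag(2 * v, v), list(rdm = 0, mag = 2))
  r <- rdm_mag(c(1, 0), c(0, 1))
  expect_equal(r$rdm, sqrt(2))
  expect_error(rdm_mag(v, rep(0, 4)), "zero")
})
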