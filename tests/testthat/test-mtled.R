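test_that("tet background integration uses the exact 4-point rule", {
  g <- structured_tet_grid(c(0, 0, 0), c(2, 3, 4), c(2, 2, 2))
  ips <- build_integration_points(g)
  vols <- ecogfwd:::tet_volumes(g$nodes, g$tets)
  expect_equal(length(ips$weights), 4 * nrow(g$tets))
  # per-tet weights are V/4 and sum to the total volume
  expect_equal(as.vector(rowsum(ips$weights, ips$element)), vols,
               tolerance = 1e-12)
  expect_equal(sum(ips$weights), 2 * 3 * 4, tolerance = 1e-10)
  # the rule integrates quadratics exactly: f = x^2 over one tet
  t1 <- g$tets[1, ]
  X <- g$nodes[t1, ]
  ip1 <- ips$points[1:4, ]
  quad <- sum(ips$weights[1:4] * ip1[, 1]^2)
  # oracle: exact integral of x^2 over the tet by barycentric expansion
  # int x^2 dV = V/10 * (sum_i sum_j>=i xi xj) for barycentric-linear x
  xs <- X[, 1]
  exact <- vols[1] / 10 * (sum(xs^2) + sum(outer(xs, xs)[upper.tri(diag(4))]))
  expect_equal(quad, exact, tolerance = 1e-12)
  # inverted tets are repaired by the constructor, degenerate ones rejected
  expect_error(tet_grid(X, matrix(c(1, 1, 2, 3), 1)), "degenerate")
})

test_that("MLS shape functions: partition of unity, linear reproduction, gradients", {
  cm <- cube_model()
  g <- cm$grid
  rad <- ecogfwd:::node_support_radii(g, 1.8)
  set.seed(1)
  pts <- matrix(runif(3000, 1, 39), ncol = 3)
  shp <- mls_shape(g$nodes, pts, mls_params(), radii = rad)
  pu <- rowsum(shp$phi, rep(seq_len(nrow(pts)), diff(shp$offsets)))
  expect_lt(max(abs(pu - 1)), 1e-12)
  lin <- ecogfwd:::eval_mls_field(
    shp, cbind(1 + 2 * g$nodes[, 1] - g$nodes[, 2] + 0.5 * g$nodes[, 3]),
    nrow(pts))
  expect_lt(max(abs(lin - (1 + 2 * pts[, 1] - pts[, 2] + 0.5 * pts[, 3]))), 1e-10)
  # analytic gradients vs central differences on a smooth nodal field
  vals <- cbind(sin(g$nodes[, 1] / 7) * g$nodes[, 2] / 11)
  h <- 1e-6
  p0 <- pts[1:5, , drop = FALSE]
  shp0 <- mls_shape(g$nodes, p0, mls_params(), radii = rad)
  for (d in 1:3) {
    gx <- vapply(1:5, function(i) {
      rng <- (shp0$offsets[i] + 1):shp0$offsets[i + 1]
      sum(shp0$dphi[rng, d] * vals[shp0$ids[rng]])
    }, numeric(1))
    fd <- vapply(1:5, function(i) {
      e <- matrix(0, 1, 3); e[d] <- h
      up <- ecogfwd:::eval_mls_field(
        mls_shape(g$nodes, p0[i, , drop = FALSE] + e, mls_params(), radii = rad),
        vals, 1L)
      dn <- ecogfwd:::eval_mls_field(
        mls_shape(g$nodes, p0[i, , drop = FALSE] - e, mls_params(), radii = rad),
        vals, 1L)
      (up - dn) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(gx - fd)), 1e-6)
  }
  # singular moment matrix reported with the offending point
  expect_error(mls_shape(matrix(rnorm(12), 4), matrix(c(100, 100, 100), 1),
                         mls_params(), radii = rep(1, 4)), "support")
})

test_that("neo-Hookean stress is zero at rest and under rotation, and is an energy gradient", {
  pk <- neo_hookean_pk2(diag(3), 3000, 0.49)
  expect_lt(max(abs(pk$S)), 1e-10)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_lt(max(abs(neo_hookean_pk2(R, 3000, 0.49)$S)), 1e-9)
  expect_error(neo_hookean_pk2(diag(c(1, 1, -1)), 3000, 0.49), "positive")
  # uniaxial stretch: P equals the central difference of the stored energy
  lam <- 1.1
  h <- 1e-7
  W <- function(l) neo_hookean_pk2(diag(c(1, 1, l)), 3000, 0.49)$energy_density
  P33 <- neo_hookean_pk2(diag(c(1, 1, lam)), 3000, 0.49)$P[3, 3]
  expect_equal(P33, (W(lam + h) - W(lam - h)) / (2 * h), tolerance = 1e-5)
})

test_that("internal forces vanish for rigid motion and match the energy gradient", {
  cm <- cube_model()
  N <- nrow(cm$grid$nodes)
  expect_lt(max(abs(internal_forces(cm$model, matrix(0, N, 3))$forces)), 1e-12)
  # rigid translation: forces vanish up to accumulation roundoff
  tr <- matrix(rep(c(3, -2, 5), each = N), N, 3)
  expect_lt(max(abs(internal_forces(cm$model, tr)$forces)), 1e-8)
  # energy finite-difference oracle on a random configuration
  set.seed(2)
  U0 <- matrix(rnorm(3 * N, sd = 0.3), N, 3)
  f0 <- internal_forces(cm$model, U0)
  h <- 1e-5
  ks <- sample(3 * N, 10)
  for (k in ks) {
    Up <- U0; Up[k] <- Up[k] + h
    Um <- U0; Um[k] <- Um[k] - h
    fd <- (internal_forces(cm$model, Up)$energy -
           internal_forces(cm$model, Um)$energy) / (2 * h)
    expect_lt(abs(fd - f0$forces[k]) / max(abs(f0$forces)), 1e-5)
  }
})

test_that("static solve: zero loads give zero deformation; prescribed nodes track targets", {
  cm <- cube_model()
  load0 <- data.frame(node = cm$prescribed, ux = 0, uy = 0, uz = 0)
  st <- solve_static(cm$model, load0,
                     mtled_config(ramp_steps = 50, max_steps = 500, tol = 1e-8,
                                  patience = 20))
  expect_lt(max(abs(st$U)), 1e-10)
  # small uniform translation: prescribed nodes track the ramped target
  tr <- data.frame(node = cm$prescribed, ux = 1, uy = -0.5, uz = 0.25)
  st <- solve_static(cm$model, tr,
                     mtled_config(ramp_steps = 100, max_steps = 3000, tol = 1e-8))
  expect_true(st$converged)
  expect_lt(max(abs(st$U[cm$prescribed, 1] - 1)), 1e-12)
  expect_lt(max(abs(st$displacements[cm$prescribed, 1] - 1)), 1e-6)
  # interior follows the rigid translation
  expect_lt(max(abs(sweep(st$displacements, 2, c(1, -0.5, 0.25)))), 1e-6)
  expect_error(solve_static(cm$model, data.frame(node = 1, ux = 0, uy = 0, uz = 0)),
               "prescribed")
})

test_that("material assignment blends fuzzy class moduli convexly", {
  g <- image_grid(c(12, 12, 12), spacing = c(4, 4, 4))
  set.seed(3)
  # two-intensity synthetic image
  v <- array(sample(c(40, 120), 12^3, TRUE), c(12, 12, 12)) + rnorm(12^3, 0, 2)
  img <- scalar_image(v, g)
  mask <- mask_image(array(TRUE, c(12, 12, 12)), g)
  grid <- structured_tet_grid(c(2, 2, 2), c(42, 42, 42), c(4, 4, 4))
  model <- meshless_model(grid, consistency_correction = FALSE)
  m2 <- assign_materials(model, img, mask, class_E = c(2000, 4000))
  expect_true(all(m2$E >= 2000 - 1e-9 & m2$E <= 4000 + 1e-9))
  # single-class config is uniform
  m1 <- assign_materials(model, scalar_image(v * 0 + 50 + rnorm(12^3), g), mask,
                         class_E = c(2500, 2600))
  expect_true(all(is.finite(m1$E)))
  # memberships sum to one: a pure-intensity voxel gets the exact blend
  fit <- fcm(matrix(as.vector(v), ncol = 1), fcm_config(n_clusters = 2))
  expect_lt(max(abs(rowSums(fit$memberships) - 1)), 1e-12)
})
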