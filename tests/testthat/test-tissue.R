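test_that("tensor invariants match the eigenvalue-based formulas", {
  g <- image_grid(c(3, 3, 3))
  # isotropic: MD = d, FA = 0
  iso <- tensor_image(matrix(rep(c(2e-3, 0, 0, 2e-3, 0, 2e-3), 27), 6), g)
  inv <- tensor_invariants(iso)
  expect_equal(as.vector(inv$md$values), rep(2e-3, 27), tolerance = 1e-15)
  expect_equal(max(abs(inv$fa$values)), 0)
  # rank-one: FA = 1
  r1 <- tensor_image(matrix(rep(c(1, 0, 0, 0, 0, 0), 27), 6), g)
  expect_equal(as.vector(tensor_invariants(r1)$fa$values), rep(1, 27))
  # random SPD tensors vs brute-force eigenvalue formula
  set.seed(5)
  t6 <- sapply(1:27, function(i) {
    A <- matrix(rnorm(9), 3)
    mat_to_sym6(crossprod(A) + diag(3) * 0.1)
  })
  inv <- tensor_invariants(tensor_image(t6, g))
  for (i in c(1, 13, 27)) {
    ev <- eigen(sym6_to_mat(t6[, i]), symmetric = TRUE, only.values = TRUE)$values
    md <- mean(ev)
    fa <- sqrt(3 / 2) * sqrt(sum((ev - md)^2) / sum(ev^2))
    expect_equal(as.vector(inv$md$values)[i], md, tolerance = 1e-12)
    expect_equal(as.vector(inv$fa$values)[i], fa, tolerance = 1e-12)
  }
})

test_that("fuzzy C-means recovers separated clusters with a monotone objective", {
  set.seed(21)
  x <- rbind(matrix(rnorm(200, 0, 0.3), ncol = 2),
             matrix(rnorm(200, 8, 0.3), ncol = 2))
  fit <- fcm(x, fcm_config(n_clusters = 2, m = 2))
  expect_lt(max(abs(rowSums(fit$memberships) - 1)), 1e-12)
  expect_true(all(diff(fit$objective) <= 1e-8 * fit$objective[1]))
  hard <- apply(fit$memberships, 1, which.max)
  expect_true(min(apply(fit$memberships, 1, max)) > 0.99)
  expect_equal(unname(fit$centers[1, ]), c(0, 0), tolerance = 0.1)
  expect_equal(unname(fit$centers[2, ]), c(8, 8), tolerance = 0.1)
  # large fuzziness drives memberships toward uniform 1/c
  soft <- fcm(x, fcm_config(n_clusters = 2, m = 100))
  expect_lt(max(abs(soft$memberships - 0.5)), 0.1)
  expect_error(fcm(matrix(1, 10, 1), fcm_config(n_clusters = 2)), "distinct")
})

test_that("fcm agrees with an independent implementation on shared data", {
  skip_if_not_installed("e1071")
  set.seed(33)
  x <- rbind(matrix(rnorm(120, 0, 0.5), ncol = 2),
             matrix(rnorm(120, 5, 0.5), ncol = 2))
  ours <- fcm(x, fcm_config(n_clusters = 2, m = 2, tol = 1e-10))
  ref <- e1071::cmeans(x, centers = ours$centers, m = 2, iter.max = 300)
  ord <- order(ref$centers[, 1])
  expect_equal(unname(ours$centers), unname(ref$centers[ord, ]),
               tolerance = 1e-4)
  expect_lt(max(abs(ours$memberships - ref$membership[, ord])), 1e-3)
})

test_that("two-stage DTI classification recovers the phantom tissues", {
  ph <- classification_phantom(1)
  seg <- classify_brain(ph$dti, ph$mask)
  sel <- ph$labels$values > 0
  expect_gte(mean(seg$values[sel] == ph$labels$values[sel]), 0.99)
  # labels partition the brain mask
  expect_true(all(seg$values[sel] %in% 1:3))
  expect_true(all(seg$values[!sel] == 0))
  # constant features cannot be classified
  iso <- make_synthetic_dti(ph$labels, synthetic_dti_spec(
    list(`1` = rep(1e-3, 3), `2` = rep(1e-3, 3), `3` = rep(1e-3, 3))))
  expect_error(classify_brain(iso, ph$mask), "constant")
})

test_that("head label map fusion builds shells of the configured thickness", {
  spec <- sphere_phantom_spec(c(20, 14), c(2L, 1L), grid_dims = c(56, 56, 56),
                              spacing = c(1.1, 1.1, 1.1))
  lab <- make_sphere_phantom(spec)
  brain <- mask_image(lab$values > 0, lab$grid)
  lm <- build_head_labelmap(lab, brain, shell_mm = 4.4)
  ctr <- voxel_centers(lab$grid)
  r <- sqrt(rowSums(ctr^2))
  skull <- as.vector(lm$values) == 4
  expect_true(all(r[skull] > 20 - 1.1 & r[skull] < 20 + 4.4 + 1.1))
  # shell thickness about 4 voxels at 1.1 mm spacing
  expect_equal(mean(r[skull] - 20 > 0), 1, tolerance = 0.05)
  # classes disjoint & conservation: brain + shells = dilated head mask
  d2 <- dilate_mask(brain, 8.8)
  expect_equal(sum(lm$values > 0), sum(d2$values))
  # no sheet: five classes at most
  expect_true(all(unique(as.vector(lm$values)) %in% 0:5))
  # sheet override
  sheet <- array(FALSE, dim(lm$values)); sheet[1:5, 1:5, 1:5] <- TRUE
  lm2 <- build_head_labelmap(lab, brain, mask_image(sheet, lab$grid), 4.4)
  expect_true(all(lm2$values[sheet] == 6))
  # shells reaching past the grid are clipped with a warning
  spec_s <- sphere_phantom_spec(20, 1L, grid_dims = c(42, 42, 42),
                                spacing = c(1.1, 1.1, 1.1))
  lab_s <- make_sphere_phantom(spec_s)
  brain_s <- mask_image(lab_s$values > 0, lab_s$grid)
  expect_warning(build_head_labelmap(lab_s, brain_s, shell_mm = 4.4), "clipped")
})

test_that("conductivity tensors carry the literature class values and the WM determinant identity", {
  g <- image_grid(c(4, 4, 4))
  lab <- label_image(array(rep(1:6, length.out = 64), c(4, 4, 4)), g)
  ds <- synthetic_dti_spec(
    eigenvalues = stats::setNames(
      rep(list(c(1.7e-3, 0.4e-3, 0.2e-3)), 6), as.character(1:6)),
    field = "radial")
  dti <- make_synthetic_dti(lab, ds)
  cond <- assign_conductivity(lab, dti)
  t6 <- matrix(cond$values, 6)
  labv <- as.vector(lab$values)
  # exact isotropic class values
  expected <- c(gray_matter = 0.33, csf = 1.79, skull = 0.012, scalp = 0.33,
                electrode_sheet = 1e-6)
  codes <- c(gray_matter = 2, csf = 3, skull = 4, scalp = 5, electrode_sheet = 6)
  for (nm in names(expected)) {
    i <- which(labv == codes[[nm]])[1]
    expect_equal(sym6_to_mat(t6[, i]), diag(3) * expected[[nm]],
                 tolerance = 1e-15, label = nm)
  }
  # volume-normalized WM mode: det sigma = sigma_ref^3
  wm <- which(labv == 1)
  dets <- vapply(wm, function(i) det(sym6_to_mat(t6[, i])), numeric(1))
  expect_lt(max(abs(dets - 0.14^3)), 1e-10)
  # isotropic WM tensor maps to sigma_ref * I exactly
  iso <- make_synthetic_dti(lab, synthetic_dti_spec(
    eigenvalues = stats::setNames(rep(list(rep(1e-3, 3)), 6), as.character(1:6))))
  ct <- matrix(assign_conductivity(lab, iso)$values, 6)
  i <- wm[1]
  expect_equal(sym6_to_mat(ct[, i]), diag(3) * 0.14, tolerance = 1e-12)
  # SPD everywhere in the head
  eg <- ecogfwd:::cpp_sym3_eig(t6[, labv > 0, drop = FALSE])
  expect_gt(min(eg$values[3, ]), 0)
  # linear mode scales the diffusion eigenvalues
  sp <- conductivity_spec(wm_mode = "linear", wm_k = 100)
  cl <- matrix(assign_conductivity(lab, dti, sp)$values, 6)
  ev <- ecogfwd:::cpp_sym3_eig(cl[, wm[1], drop = FALSE])$values
  expect_equal(as.vector(ev), 100 * c(1.7e-3, 0.4e-3, 0.2e-3), tolerance = 1e-10)
})
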