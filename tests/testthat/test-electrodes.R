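test_that("bright blobs are segmented into one component each", {
  g <- image_grid(c(40, 40, 40))
  set.seed(6)
  pts <- point_set(as.matrix(expand.grid(c(8, 20, 32), c(8, 20, 32), c(8, 20, 32))))
  ct <- simulate_electrode_ct(pts, g, fwhm_mm = 2)
  seg <- segment_electrodes(ct)
  expect_equal(max(seg$values), 27)
  # a single-voxel noise spike is removed by the size filter
  v <- ct$values
  v[2, 2, 2] <- 2
  seg2 <- segment_electrodes(scalar_image(v, g), min_voxels = 2)
  expect_equal(max(seg2$values), 27)
  # exclusion mask removes a bright shell
  excl <- array(FALSE, c(40, 40, 40))
  excl[1:40, 1:40, 36:40] <- TRUE
  vb <- ct$values
  vb[, , 37] <- 3
  seg3 <- segment_electrodes(scalar_image(vb, g), mask_image(excl, g))
  expect_equal(max(seg3$values), 27)
})

test_that("centroids equal the mean of member voxel centres", {
  g <- image_grid(c(12, 12, 12), spacing = c(1, 1.5, 2), origin = c(-3, 1, 2))
  lab <- array(0L, c(12, 12, 12))
  lab[3, 4, 5] <- 1L                 # single voxel
  lab[7:9, 7:9, 7:9] <- 2L           # symmetric cube
  set.seed(9)
  blob <- which(array(runif(12^3) < 0.08, c(12, 12, 12)) & lab == 0)
  lab[blob] <- 3L
  # relabel into raster-order components? centroids() works per label id;
  # here labels are already 1..3
  cen <- centroids(label_image(lab, g))
  ctr <- voxel_centers(g)
  for (k in 1:3) {
    oracle <- colMeans(ctr[as.vector(lab) == k, , drop = FALSE])
    expect_equal(unname(ps_coords(cen)[k, ]), unname(oracle), tolerance = 1e-12)
  }
})

test_that("electrode displacements subtract projected from original positions", {
  set.seed(1)
  proj <- point_set(matrix(rnorm(30), 10), sprintf("E%d", 1:10))
  shift <- matrix(rnorm(30, sd = 2), 10)
  orig <- point_set(ps_coords(proj) + shift, sprintf("E%d", 1:10))
  ed <- electrode_displacements(electrode_set(orig, proj))
  expect_equal(ed$vectors, shift, tolerance = 1e-12)
  # zero shift
  ed0 <- electrode_displacements(electrode_set(proj, proj))
  expect_equal(max(abs(ed0$vectors)), 0)
  # order invariance: permuting one set leaves the pairing by label intact
  perm <- sample(10)
  orig_p <- point_set(ps_coords(orig)[perm, ], orig$label[perm])
  ed_p <- electrode_displacements(electrode_set(orig_p, proj))
  expect_equal(ed_p$vectors, ed$vectors, tolerance = 1e-12)
  expect_error(electrode_set(point_set(matrix(rnorm(9), 3)), proj), "labels")
})

test_that("MLS interpolation reproduces constants and linear fields", {
  set.seed(12)
  src <- matrix(runif(90, 0, 50), ncol = 3)
  dst <- matrix(runif(60, 10, 40), ncol = 3)
  # constant field: partition of unity
  out <- mls_interpolate(src, matrix(5, 30, 1), dst)
  expect_lt(max(abs(out - 5)), 1e-10)
  # linear field with linear basis
  f <- function(p) 2 + 0.1 * p[, 1] - 0.25 * p[, 2] + 0.07 * p[, 3]
  out <- mls_interpolate(src, cbind(f(src)), dst)
  expect_lt(max(abs(out - f(dst))), 1e-9)
  # evaluation at the source points with interpolating weights
  vals <- matrix(rnorm(90), 30)
  at_src <- mls_interpolate(src, vals, src)
  expect_lt(max(abs(at_src - vals)), 1e-5)
  expect_error(mls_interpolate(src, vals, matrix(c(500, 500, 500), 1),
                               support_radius = 10), "support")
})

test_that("load tables carry one MLS-interpolated row per selected node", {
  surf <- brain_sphere_surface()
  eg <- make_electrode_grid(surf, 8, 8, 10, inward_shift = 3, seed = 2)
  es <- electrode_set(eg$orig, eg$proj)
  # nodes at the electrode positions themselves: interpolating fit returns
  # exactly the electrode displacements
  nodes <- ps_coords(eg$proj)
  lt <- build_load_table(seq_len(64), nodes, es)
  expect_s3_class(lt, "load_table")
  expect_equal(nrow(lt), 64)
  norms <- sqrt(lt$ux^2 + lt$uy^2 + lt$uz^2)
  expect_lt(max(abs(norms - 3)), 1e-6)
  # uniform displacement field reproduces the constant vector everywhere
  orig_u <- point_set(ps_coords(eg$proj) + rep(c(1, 2, -1), each = 64),
                      eg$proj$label)
  es_u <- electrode_set(orig_u, eg$proj)
  sel <- seq(1, 64, by = 3)
  lt_u <- build_load_table(sel, nodes, es_u)
  expect_equal(nrow(lt_u), length(sel))
  expect_lt(max(abs(sweep(as.matrix(lt_u[, 2:4]), 2, c(1, 2, -1)))), 1e-8)
})
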