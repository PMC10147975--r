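test_that("Otsu threshold separates a two-delta histogram and matches brute force", {
  g <- image_grid(c(10, 10, 10))
  v <- rep(c(10, 100), each = 500)
  ot <- otsu_threshold(scalar_image(v, g))
  expect_gt(ot$threshold, 10)
  expect_lt(ot$threshold, 100)
  expect_equal(sum(ot$mask$values), 500)

  # seeded bimodal Gaussian mixture vs exhaustive search over bin cut-points
  set.seed(42)
  x <- c(rnorm(600, 30, 6), rnorm(400, 90, 10))
  img <- scalar_image(x, image_grid(c(10, 10, 10)))
  n_bins <- 128L
  ot <- otsu_threshold(img, n_bins = n_bins)
  rng <- range(x)
  h <- tabulate(pmin(pmax(floor((x - rng[1]) / diff(rng) * n_bins) + 1L, 1L),
                     n_bins), nbins = n_bins)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * diff(rng) / n_bins
  best <- -Inf; best_t <- NA
  for (t in 1:(n_bins - 1)) {       # brute-force between-class variance
    w0 <- sum(h[1:t]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:t] * mids[1:t]) / w0
    m1 <- sum(h[(t + 1):n_bins] * mids[(t + 1):n_bins]) / w1
    bcv <- w0 * w1 * (m0 - m1)^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  expect_equal(ot$threshold, rng[1] + best_t * diff(rng) / n_bins)
  expect_error(otsu_threshold(scalar_image(rep(1, 1000), g)), "constant")
})

test_that("masked Otsu shifts the threshold and confines the output", {
  g <- image_grid(c(10, 10, 10))
  set.seed(7)
  v <- c(rnorm(500, 20, 3), rnorm(500, 80, 5))
  m <- mask_image(c(rep(TRUE, 500), rep(FALSE, 500)), g)  # exclude high mode
  full <- otsu_threshold(scalar_image(v, g))
  masked <- otsu_threshold(scalar_image(v, g), mask = m)
  expect_lt(masked$threshold, full$threshold)
  expect_true(all(!masked$mask$values[!m$values]))
  sens <- otsu_sensitivity(scalar_image(v, g), bin_counts = c(64L, 128L, 256L))
  expect_equal(nrow(sens), 3)
  expect_lt(diff(range(sens$threshold)), diff(range(v)) * 0.05)
})

test_that("connected components match a flood-fill oracle and are deterministic", {
  g <- image_grid(c(10, 10, 10))
  m <- array(FALSE, c(10, 10, 10))
  m[2:3, 2:3, 2:3] <- TRUE
  m[7:8, 7:8, 7:8] <- TRUE
  lab <- connected_components(mask_image(m, g), 26)
  expect_equal(max(lab$values), 2)
  expect_equal(sort(unique(as.vector(lab$values))), 0:2)
  # single voxel
  m1 <- array(FALSE, c(10, 10, 10)); m1[5, 5, 5] <- TRUE
  expect_equal(max(connected_components(mask_image(m1, g))$values), 1)

  # random mask vs an R flood-fill oracle (6-connectivity)
  set.seed(3)
  mr <- array(runif(16^3) < 0.3, c(16, 16, 16))
  lab <- connected_components(mask_image(mr, image_grid(c(16, 16, 16))), 6)$values
  flood <- array(0L, dim(mr)); k <- 0L
  nb <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  for (s in which(mr)) {
    if (flood[s]) next
    k <- k + 1L
    queue <- s
    flood[s] <- k
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ijk <- c((cur - 1) %% 16, ((cur - 1) %/% 16) %% 16, (cur - 1) %/% 256) + 1
      for (q in 1:6) {
        nijk <- ijk + nb[q, ]
        if (any(nijk < 1 | nijk > 16)) next
        lin <- nijk[1] + 16 * (nijk[2] - 1) + 256 * (nijk[3] - 1)
        if (mr[lin] && !flood[lin]) { flood[lin] <- k; queue <- c(queue, lin) }
      }
    }
  }
  # same partition (labels may renumber, but raster-order rule makes them equal)
  expect_equal(as.vector(lab), as.vector(flood))
})

test_that("dilation is extensive, metric and monotone", {
  g <- image_grid(c(15, 15, 15), spacing = c(1.1, 1.1, 1.1))
  m <- array(FALSE, c(15, 15, 15)); m[8, 8, 8] <- TRUE
  mk <- mask_image(m, g)
  expect_identical(dilate_mask(mk, 0)$values, mk$values)
  d44 <- dilate_mask(mk, 4.4)
  # ball of voxels within 4 voxel steps at 1.1 mm spacing
  idx <- which(d44$values, arr.ind = TRUE)
  r <- sqrt(rowSums((sweep(idx, 2, c(8, 8, 8)) * 1.1)^2))
  expect_true(all(r <= 4.4 + 1e-9))
  expect_equal(sum(d44$values), sum(sqrt(rowSums(as.matrix(
    expand.grid(-4:4, -4:4, -4:4))^2)) <= 4))
  d2 <- dilate_mask(mk, 2.2)
  expect_true(all(d44$values[d2$values]))       # monotone
  expect_true(all(d2$values[mk$values]))        # extensive
})

test_that("trilinear resampling is exact at voxel centres and on linear ramps", {
  g <- image_grid(c(9, 9, 9), spacing = c(1, 1.5, 2), origin = c(-1, 2, 0.5))
  ctr <- voxel_centers(g)
  ramp <- 2 + 0.3 * ctr[, 1] - 0.7 * ctr[, 2] + 0.11 * ctr[, 3]
  img <- scalar_image(ramp, g)
  expect_equal(resample_trilinear(img, ctr), ramp, tolerance = 1e-13)
  set.seed(1)
  pts <- cbind(runif(50, -1, 7), runif(50, 2, 13), runif(50, 0.5, 16))
  expect_equal(resample_trilinear(img, pts),
               2 + 0.3 * pts[, 1] - 0.7 * pts[, 2] + 0.11 * pts[, 3],
               tolerance = 1e-12)
  expect_equal(resample_trilinear(img, matrix(c(100, 0, 0), 1),
                                  background = -99), -99)
})
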