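test_that("isosurface of the sphere phantom matches analytic area and volume", {
  s <- small_sphere_surface()
  expect_lt(abs(surface_area(s) - 4 * pi * 100) / (4 * pi * 100), 0.03)
  expect_lt(abs(surface_volume(s) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
  topo <- surface_topology(s)
  expect_true(topo$closed)
  expect_equal(topo$euler, 2)
})

test_that("isosurface of a cube mask is a closed genus-0 surface", {
  g <- image_grid(c(14, 14, 14))
  m <- array(FALSE, c(14, 14, 14))
  m[4:10, 4:10, 4:10] <- TRUE
  topo <- surface_topology(marching_cubes(mask_image(m, g)))
  expect_true(topo$closed)
  expect_true(topo$manifold)
  expect_equal(topo$euler, 2)
  expect_error(marching_cubes(mask_image(array(TRUE, c(14, 14, 14)), g)), "empty")
})

test_that("closest-point projection matches an exhaustive triangle oracle", {
  s <- small_sphere_surface()
  # a point already on the surface stays put
  v1 <- s$vertices[10, , drop = FALSE]
  pr <- project_points_to_surface(point_set(v1, "a"), s)
  expect_lt(max(abs(ps_coords(pr) - v1)), 1e-9)
  # centre projects to (nearly) radius distance
  prc <- project_points_to_surface(point_set(matrix(0, 1, 3), "c"), s)
  expect_equal(sqrt(sum(ps_coords(prc)^2)), 10, tolerance = 0.05)
  # brute-force oracle over all triangles for random points
  set.seed(8)
  pts <- matrix(rnorm(15, sd = 12), ncol = 3)
  pr <- project_points_to_surface(point_set(pts), s)
  d <- attr(pr, "distance")
  for (i in seq_len(nrow(pts))) {
    dmin <- Inf
    for (t in seq_len(nrow(s$triangles))) {
      tri <- s$vertices[s$triangles[t, ], ]
      # dense sampling of the triangle as an independent distance bound
      bc <- as.matrix(expand.grid(seq(0, 1, 0.1), seq(0, 1, 0.1)))
      bc <- bc[rowSums(bc) <= 1, ]
      sm <- cbind(1 - rowSums(bc), bc) %*% tri
      dmin <- min(dmin, sqrt(min(colSums((t(sm) - pts[i, ])^2))))
    }
    expect_lte(d[i], dmin + 1e-9)
    expect_gte(d[i], dmin - 0.2)  # sampling resolution of the oracle
  }
})

test_that("centroid triangulation is planar Delaunay on the fit plane", {
  # 4 coplanar corners -> 2 triangles
  sq <- point_set(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  expect_equal(nrow(triangulate_centroids(sq)$triangles), 2)
  # 8x8 planar grid -> 2 * 7 * 7 triangles
  gr <- as.matrix(expand.grid(1:8, 1:8))
  ps <- point_set(cbind(gr, 0.5))
  tri <- triangulate_centroids(ps)
  expect_equal(nrow(tri$triangles), 98)
  # empty-circumcircle property in the plane
  uv <- gr
  for (t in seq_len(nrow(tri$triangles))) {
    a <- uv[tri$triangles[t, 1], ]; b <- uv[tri$triangles[t, 2], ]
    cc <- uv[tri$triangles[t, 3], ]
    d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) + cc[1] * (a[2] - b[2]))
    ux <- ((sum(a^2)) * (b[2] - cc[2]) + (sum(b^2)) * (cc[2] - a[2]) +
           (sum(cc^2)) * (a[2] - b[2])) / d
    uy <- ((sum(a^2)) * (cc[1] - b[1]) + (sum(b^2)) * (a[1] - cc[1]) +
           (sum(cc^2)) * (b[1] - a[1])) / d
    r2 <- sum((a - c(ux, uy))^2)
    din <- rowSums(sweep(uv, 2, c(ux, uy))^2)
    expect_true(all(din >= r2 * (1 - 1e-9)))
  }
  col <- point_set(cbind(1:5, 2 * (1:5), 0))
  expect_error(triangulate_centroids(col), "collinear")
})

test_that("sheet extrusion produces a closed slab of the right volume", {
  gr <- as.matrix(expand.grid(seq(0, 70, 10), seq(0, 70, 10)))
  sheet <- triangulate_centroids(point_set(cbind(gr, 0)))
  slab <- extrude_sheet(sheet, 4)
  topo <- surface_topology(slab)
  expect_true(topo$closed)
  expect_equal(surface_volume(slab), surface_area(sheet) * 4, tolerance = 0.01)
  slab2 <- extrude_sheet(sheet, 2)
  expect_equal(surface_volume(slab2) / surface_volume(slab), 0.5, tolerance = 0.01)
})

test_that("voxelization is parity-consistent and volume-accurate", {
  s <- small_sphere_surface()
  g <- small_sphere_mask()$grid
  m1 <- voxelize_surface(s, g, axis = 1)
  expect_lt(abs(sum(m1$values) * voxel_volume(g) - 4 / 3 * pi * 1000) /
              (4 / 3 * pi * 1000), 0.03)
  for (ax in 2:3)
    expect_identical(voxelize_surface(s, g, axis = ax)$values, m1$values)
  # far-away grid -> empty mask
  g2 <- image_grid(c(8, 8, 8), origin = c(100, 100, 100))
  expect_equal(sum(voxelize_surface(s, g2)$values), 0)
  # open surfaces are rejected
  open_sheet <- triangulate_centroids(point_set(cbind(as.matrix(
    expand.grid(1:3, 1:3)), 0)))
  expect_error(voxelize_surface(open_sheet, g), "closed")
})

test_that("node selection under a sheet equals a brute-force distance filter", {
  gr <- as.matrix(expand.grid(seq(0, 30, 10), seq(0, 30, 10)))
  sheet <- triangulate_centroids(point_set(cbind(gr, 0)))
  set.seed(10)
  nodes <- point_set(cbind(runif(200, -5, 35), runif(200, -5, 35),
                           runif(200, -8, 8)))
  sel5 <- select_nodes_under_sheet(nodes, sheet, tol = 5)
  cp <- project_points_to_surface(nodes, sheet)
  expect_equal(sel5, which(attr(cp, "distance") <= 5))
  sel2 <- select_nodes_under_sheet(nodes, sheet, tol = 2)
  expect_true(all(sel2 %in% sel5))                       # monotone in tol
  # nodes exactly on the sheet are kept at tol = 0
  on_sheet <- point_set(rbind(c(5, 5, 0), c(50, 50, 40)))
  expect_equal(select_nodes_under_sheet(on_sheet, sheet, tol = 0), 1L)
  expect_warning(select_nodes_under_sheet(point_set(rbind(c(99, 99, 99))),
                                          sheet, tol = 1), "no nodes")
})
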