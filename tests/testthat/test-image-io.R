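test_that("image grid validates geometry and maps indices to world", {
  expect_error(image_grid(c(0, 4, 4)), "dims")
  expect_error(image_grid(c(4, 4, 4), spacing = c(1, -1, 1)), "spacing")
  expect_error(image_grid(c(4, 4, 4), direction = diag(3) * 2), "unit norm")
  g <- image_grid(c(4, 5, 6), spacing = c(1, 1.09375, 1.09375),
                  origin = c(-3, 2, 1))
  ctr <- voxel_centers(g)
  expect_equal(nrow(ctr), 120)
  expect_equal(ctr[1, ], c(-3, 2, 1))
  expect_equal(ctr[2, ], c(-2, 2, 1))                 # first axis fastest
  expect_equal(unname(world_to_index(g, ctr[50, , drop = FALSE])),
               matrix(c((50 - 1) %% 4, ((50 - 1) %/% 4) %% 5, (50 - 1) %/% 20), 1),
               tolerance = 1e-12)
})

test_that("NRRD round trip is lossless for all four image kinds", {
  td <- withr::local_tempdir()
  g <- image_grid(c(8, 7, 6), spacing = c(1, 1.09375, 1.09375),
                  origin = c(-3.5, 2.25, 1))
  set.seed(11)
  imgs <- list(
    scalar = scalar_image(rnorm(8 * 7 * 6), g),
    label = label_image(sample(0:5, 8 * 7 * 6, TRUE), g),
    mask = mask_image(runif(8 * 7 * 6) > 0.5, g),
    vector = vector_image(matrix(rnorm(3 * 8 * 7 * 6), 3), g),
    tensor = tensor_image(matrix(rnorm(6 * 8 * 7 * 6), 6), g))
  for (nm in names(imgs)) {
    p <- file.path(td, paste0(nm, ".nrrd"))
    write_nrrd(imgs[[nm]], p)
    back <- read_nrrd(p, kind = nm)
    expect_identical(back$values, imgs[[nm]]$values, label = nm)
    expect_true(grids_equal(back$grid, g), label = nm)
  }
  # raw encoding round trip as well
  p <- file.path(td, "raw.nrrd")
  write_nrrd(imgs$scalar, p, encoding = "raw")
  expect_identical(read_nrrd(p)$values, imgs$scalar$values)
})

test_that("tensor measurement frame is applied on load", {
  td <- withr::local_tempdir()
  g <- image_grid(c(3, 3, 3))
  set.seed(2)
  t6 <- matrix(rnorm(6 * 27), 6)
  th <- 0.6
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  # hand-write a tensor NRRD with measurement frame R
  p <- file.path(td, "frame.nrrd")
  fmt <- function(v) sprintf("(%.17g,%.17g,%.17g)", v[1], v[2], v[3])
  con <- file(p, "wb")
  writeLines(c("NRRD0005", "type: double", "dimension: 4",
               "space: left-posterior-superior", "sizes: 6 3 3 3",
               "space directions: none (1,0,0) (0,1,0) (0,0,1)",
               "kinds: 3D-symmetric-matrix domain domain domain",
               "endian: little", "encoding: raw", "space origin: (0,0,0)",
               paste("measurement frame:", fmt(R[, 1]), fmt(R[, 2]), fmt(R[, 3])),
               ""), con, sep = "\n")
  writeBin(as.numeric(t6), con, size = 8, endian = "little")
  close(con)
  back <- read_nrrd(p, "tensor")
  # oracle: apply the frame manually, D_world = R D R^T
  for (i in c(1, 9, 27)) {
    D <- sym6_to_mat(t6[, i])
    expect_equal(sym6_to_mat(matrix(back$values, 6)[, i]), R %*% D %*% t(R),
                 tolerance = 1e-12)
  }
})

test_that("unsupported NRRD fields produce explicit errors", {
  td <- withr::local_tempdir()
  p <- file.path(td, "bad.nrrd")
  writeLines(c("NRRD0005", "type: double", "dimension: 3",
               "space: scanner-xyz", "sizes: 2 2 2",
               "encoding: raw", ""), p)
  con <- file(p, "ab")
  writeBin(rep(0, 8), con, size = 8)
  close(con)
  expect_error(read_nrrd(p), "space")
})

test_that("STL and fcsv round trips preserve geometry and labels", {
  td <- withr::local_tempdir()
  s <- small_sphere_surface()
  p <- file.path(td, "s.stl")
  write_stl(s, p)
  r <- read_stl(p)
  expect_equal(nrow(r$triangles), nrow(s$triangles))
  expect_true(surface_topology(r)$closed)
  expect_equal(surface_volume(r), surface_volume(s), tolerance = 1e-5)
  # ASCII variant
  write_stl(s, file.path(td, "a.stl"), ascii = TRUE)
  ra <- read_stl(file.path(td, "a.stl"))
  expect_equal(surface_area(ra), surface_area(s), tolerance = 1e-5)
  # RAS conversion negates x and y
  write_stl(s, file.path(td, "ras.stl"), ras = TRUE)
  rr <- read_stl(file.path(td, "ras.stl"), ras = TRUE)
  expect_equal(surface_volume(rr), surface_volume(s), tolerance = 1e-5)

  ps <- point_set(matrix(rnorm(30), 10), sprintf("E%d", 1:10))
  write_fcsv(ps, file.path(td, "p.fcsv"))
  pb <- read_fcsv(file.path(td, "p.fcsv"))
  expect_equal(pb$label, ps$label)
  expect_equal(ps_coords(pb), ps_coords(ps), tolerance = 1e-7)
})

test_that("Abaqus .inp round trip preserves the tet grid", {
  td <- withr::local_tempdir()
  g <- structured_tet_grid(c(0, 0, 0), c(2, 2, 2), c(2, 2, 2))
  p <- file.path(td, "mesh.inp")
  write_abaqus_inp(g, p)
  back <- read_abaqus_inp(p)
  expect_equal(back$nodes, g$nodes, tolerance = 1e-9)
  expect_equal(back$tets, g$tets)
})

test_that("solution writers and INI configs round-trip sanely", {
  td <- withr::local_tempdir()
  g <- image_grid(c(2, 2, 2))
  mesh <- voxels_to_hexmesh(mask_image(array(TRUE, c(2, 2, 2)), g))
  f1 <- file.path(td, "m.vtu")
  write_vtu(mesh$nodes, mesh$elems, f1,
            point_data = list(phi = seq_len(nrow(mesh$nodes))))
  expect_true(any(grepl("UnstructuredGrid", readLines(f1))))
  write_pvd("m.vtu", file.path(td, "res.pvd"))
  expect_true(any(grepl("DataSet", readLines(file.path(td, "res.pvd")))))
  write_hexmesh_gz(mesh, file.path(td, "m.mesh.gz"))
  sig6 <- matrix(c(1, 0, 0, 1, 0, 1), 6, 8)
  write_element_tensors_gz(sig6, file.path(td, "c.gf.gz"))
  ml <- readLines(gzfile(file.path(td, "m.mesh.gz")))
  expect_true("vertices" %in% ml)
  expect_equal(sum(grepl("^1 ", readLines(gzfile(file.path(td, "c.gf.gz"))))), 8)

  ini <- file.path(td, "solve.ini")
  write_ini(list(solver = list(ramp_steps = 40, max_steps = 200,
                               tolerance = 1e-4, patience = 10)), ini)
  cfg <- solver_config_ini(ini)
  expect_s3_class(cfg, "mtled_config")
  expect_equal(cfg$ramp_steps, 40L)
  expect_equal(cfg$tol, 1e-4)
  back <- read_ini(ini)
  expect_equal(back$solver$max_steps, "200")
})
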