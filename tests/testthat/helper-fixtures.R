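# shared fixtures, built in code (memoised per test run)

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env))
    assign(key, force(expr), envir = fixture_env)
  get(key, envir = fixture_env)
}

# unit sphere phantom (radius 10 mm, 1 mm spacing)
small_sphere_mask <- function() memo("small_sphere_mask", {
  spec <- sphere_phantom_spec(10, 1L, grid_dims = c(32, 32, 32))
  lab <- make_sphere_phantom(spec)
  mask_image(lab$values > 0, lab$grid)
})

small_sphere_surface <- function() memo("small_sphere_surface", {
  marching_cubes(small_sphere_mask())
})

# brain-scale sphere surface for electrode tests (radius 67 mm)
brain_sphere_surface <- function() memo("brain_sphere_surface", {
  spec <- sphere_phantom_spec(67, 1L, grid_dims = c(72, 72, 72),
                              spacing = c(2, 2, 2))
  lab <- make_sphere_phantom(spec)
  marching_cubes(mask_image(lab$values > 0, lab$grid))
})

# 5^3-node cube cloud with all boundary nodes prescribed
cube_model <- function() memo("cube_model", {
  g <- structured_tet_grid(c(0, 0, 0), c(40, 40, 40), c(4, 4, 4))
  presc <- which(apply(g$nodes, 1, function(p)
    any(abs(p) < 1e-9 | abs(p - 40) < 1e-9)))
  list(grid = g, prescribed = presc,
       model = meshless_model(g, prescribed_nodes = presc, E = 3000, nu = 0.49))
})

# three-shell classification phantom (WM 16, GM 24, CSF 30 mm)
classification_phantom <- function(seed) {
  spec <- sphere_phantom_spec(c(30, 24, 16), c(3L, 2L, 1L),
                              grid_dims = c(34, 34, 34), spacing = c(2, 2, 2))
  lab <- make_sphere_phantom(spec)
  ds <- synthetic_dti_spec(
    eigenvalues = list(`1` = c(1.7e-3, 0.3e-3, 0.2e-3),
                       `2` = c(0.85e-3, 0.75e-3, 0.7e-3),
                       `3` = c(3.0e-3, 2.9e-3, 2.9e-3)),
    field = "tangential", noise_sd = 4e-5, seed = seed)
  list(labels = lab, dti = make_synthetic_dti(lab, ds),
       mask = mask_image(lab$values > 0, lab$grid))
}

# deterministic homogeneous-sphere forward setup; returns rdm/mag vs series
sphere_forward_rdm <- function(radius = 80, spacing = 2, sigma = 0.33,
                               n_points = 200, cg_tol = 1e-8) {
  d <- ceiling((2 * radius + 8) / spacing)
  d <- d + (d %% 2 == 0)
  spec <- sphere_phantom_spec(radius, 1L, grid_dims = rep(d, 3),
                              spacing = rep(spacing, 3))
  mesh <- voxels_to_hexmesh(make_sphere_phantom(spec))
  sig6 <- matrix(c(sigma, 0, 0, sigma, 0, sigma), 6, nrow(mesh$elems))
  K <- assemble_system(mesh, sig6)
  dip <- dipole_source(c(0, 0, 0.5 * radius), c(1e-3, 0, 0),
                       sigma0 = diag(3) * sigma)
  rhs <- full_subtraction_rhs(mesh, sig6, dip)
  sol <- solve_potential(K, rhs, tol = cg_tol, max_iter = 8000)
  pts <- (radius - 4) * fib_dirs(n_points)
  num <- sample_potentials(sol, mesh, pts)
  ana <- analytic_dipole_sphere(
    analytic_sphere_model(radius, sigma, c(0, 0, 0.5 * radius),
                          c(1e-3, 0, 0), n_terms = 150), pts)$potential
  rdm_mag(num - mean(num), ana - mean(ana))
}

fib_dirs <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(th), r * sin(th), z)
}
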