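#' Pipeline configuration for the synthetic-phantom workflow
#'
#' Assembles the per-stage parameters of the end-to-end workflow (phantom
#' generation, masking, surface extraction, electrodes, loads, biomechanics,
#' warping, classification, fusion, conductivity, hexahedral meshing,
#' forward solution, metrics). Defaults reproduce a five-layer spherical
#' head phantom study at 2 mm resolution.
#'
#' @param outdir output directory (created if needed).
#' @param seed global integer seed.
#' @param spacing voxel spacing (mm).
#' @param radii layer radii, outer to inner (scalp, skull, CSF, GM, WM core),
#'   mm.
#' @param rows,cols,pitch,inward_shift electrode grid layout.
#' @param dipole_frac fractional dipole depth across the gray-matter shell
#'   (0 = WM core boundary, 1 = GM outer surface); the dipole is kept in the
#'   isotropic GM so the full-subtraction homogeneity assumption holds.
#' @param skip_biomech if TRUE, warped stages are omitted and the forward
#'   problem runs on the unwarped labels.
#' @param with_sheet include the electrode-sheet class in the head label map.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("ecogfwd_"), seed = 1L,
                            spacing = c(2, 2, 2),
                            radii = c(80, 75.6, 71.2, 67, 55),
                            rows = 8L, cols = 8L, pitch = 10,
                            inward_shift = 3, dipole_frac = 0.5,
                            skip_biomech = FALSE, with_sheet = TRUE) {
  stopifnot(all(diff(radii) < 0), length(radii) == 5)
  structure(list(outdir = outdir, seed = as.integer(seed), spacing = spacing,
                 radii = radii, rows = as.integer(rows), cols = as.integer(cols),
                 pitch = pitch, inward_shift = inward_shift,
                 dipole_frac = dipole_frac, skip_biomech = isTRUE(skip_biomech),
                 with_sheet = isTRUE(with_sheet)),
            class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (any(config$spacing <= 0)) stop("pipeline_config: spacing must be positive")
  if (config$pitch <= 0) stop("pipeline_config: pitch must be positive")
  if (config$dipole_frac <= 0 || config$dipole_frac >= 1)
    stop("pipeline_config: dipole_frac must be in (0,1)")
  invisible(config)
}

pipeline_stages <- function() {
  list(phantom = character(), mask = "phantom", surface = "mask",
       electrodes = "surface", loads = c("electrodes", "mask"),
       biomech = "loads", warp = "biomech", classify = "phantom",
       fuse = c("classify", "mask", "electrodes"), conductivity = "fuse",
       hexmesh = "conductivity", forward = "hexmesh",
       metrics = c("forward", "classify"))
}

stage_path <- function(config, ...) file.path(config$outdir, ...)

write_manifest <- function(config, name, inputs, outputs, params) {
  man <- list(stage = name,
              inputs = inputs,
              parameters = params,
              outputs = lapply(stats::setNames(outputs, basename(outputs)),
                               function(f) list(path = f,
                                                md5 = unname(tools::md5sum(f)))),
              tool = paste0("ecogfwd ",
                            as.character(utils::packageVersion("ecogfwd"))))
  path <- stage_path(config, paste0(name, ".manifest.json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

stage_done <- function(config, name)
  file.exists(stage_path(config, paste0(name, ".manifest.json")))

#' Run one pipeline stage
#'
#' Executes the named stage of the phantom workflow, writing its outputs and
#' a manifest (inputs, parameters, output hashes, tool version) under the
#' configured output directory. Dependencies must have been run first.
#'
#' @param name stage name (see names of the internal stage graph:
#'   phantom, mask, surface, electrodes, loads, biomech, warp, classify,
#'   fuse, conductivity, hexmesh, forward, metrics).
#' @param config a [pipeline_config()].
#' @return Invisibly, the list of output files.
#' @export
run_stage <- function(name, config) {
  validate_pipeline_config(config)
  deps <- pipeline_stages()
  if (!name %in% names(deps)) stop("run_stage: unknown stage '", name, "'")
  skipped <- if (config$skip_biomech) c("loads", "biomech", "warp") else character()
  for (d in setdiff(deps[[name]], skipped))
    if (!stage_done(config, d))
      stop("run_stage: stage '", name, "' needs outputs of stage '", d,
           "'; run that stage first")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  fn <- get(paste0("stage_", name), mode = "function")
  out <- fn(config)
  invisible(out)
}

#' Run the whole pipeline
#'
#' Topologically executes all stages (omitting the biomechanics branch when
#' `skip_biomech`) and returns the metrics report.
#'
#' @param config a [pipeline_config()].
#' @return The metrics report (named list), also written to `report.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_pipeline_config(config)
  stages <- names(pipeline_stages())
  if (config$skip_biomech)
    stages <- setdiff(stages, c("loads", "biomech", "warp"))
  for (s in stages) run_stage(s, config)
  jsonlite::read_json(stage_path(config, "report.json"))
}

# ---- stage implementations -------------------------------------------------

phantom_grid_dims <- function(config) {
  d <- as.integer(ceiling((2 * config$radii[1] + 8) / config$spacing))
  d + (d %% 2L == 0L)  # odd counts put voxel centres on even coordinates
}

stage_phantom <- function(config) {
  dims <- phantom_grid_dims(config)
  spec <- sphere_phantom_spec(config$radii, layer_labels = c(5L, 4L, 3L, 2L, 1L),
                              grid_dims = dims, spacing = config$spacing)
  labels <- make_sphere_phantom(spec)
  dspec <- synthetic_dti_spec(
    eigenvalues = list(`1` = c(1.7e-3, 0.3e-3, 0.2e-3),   # WM, high FA
                       `2` = c(0.85e-3, 0.75e-3, 0.7e-3), # GM, low FA
                       `3` = c(3.0e-3, 2.9e-3, 2.9e-3),   # CSF, high MD
                       `4` = c(0.3e-3, 0.3e-3, 0.3e-3),   # skull
                       `5` = c(0.8e-3, 0.8e-3, 0.8e-3)),  # scalp
    field = "tangential", noise_sd = 4e-5, seed = config$seed)
  dti <- make_synthetic_dti(labels, dspec)
  f1 <- stage_path(config, "labels.nrrd")
  f2 <- stage_path(config, "dti.nrrd")
  write_nrrd(labels, f1)
  write_nrrd(dti, f2)
  write_manifest(config, "phantom", list(), c(f1, f2),
                 list(radii = config$radii, spacing = config$spacing,
                      seed = config$seed))
  c(f1, f2)
}

stage_mask <- function(config) {
  labels <- read_nrrd(stage_path(config, "labels.nrrd"), "label")
  brain <- mask_image(labels$values %in% 1:3, labels$grid)
  f <- stage_path(config, "brain_mask.nrrd")
  write_nrrd(brain, f)
  write_manifest(config, "mask", list(labels = "labels.nrrd"), f,
                 list(brain_classes = 1:3))
  f
}

stage_surface <- function(config) {
  brain <- read_nrrd(stage_path(config, "brain_mask.nrrd"), "mask")
  surf <- marching_cubes(brain)
  f <- stage_path(config, "brain.stl")
  write_stl(surf, f)
  write_manifest(config, "surface", list(mask = "brain_mask.nrrd"), f,
                 list(smooth_iterations = 2))
  f
}

stage_electrodes <- function(config) {
  surf <- read_stl(stage_path(config, "brain.stl"))
  eg <- make_electrode_grid(surf, config$rows, config$cols, config$pitch,
                            config$inward_shift, config$seed)
  sheet <- triangulate_centroids(eg$proj)
  slab <- extrude_sheet(sheet, 2 * config$spacing[1])
  f1 <- stage_path(config, "origElectrodes.fcsv")
  f2 <- stage_path(config, "projElectrodes.fcsv")
  f3 <- stage_path(config, "electrode_sheet.stl")
  write_fcsv(eg$orig, f1)
  write_fcsv(eg$proj, f2)
  write_stl(slab, f3)
  write_manifest(config, "electrodes",
                 list(surface = "brain.stl"),
                 c(f1, f2, f3),
                 list(rows = config$rows, cols = config$cols,
                      pitch = config$pitch, inward_shift = config$inward_shift,
                      seed = config$seed))
  c(f1, f2, f3)
}

stage_loads <- function(config) {
  brain <- read_nrrd(stage_path(config, "brain_mask.nrrd"), "mask")
  grid <- mask_tet_grid(brain, coarsen = max(2L, round(12 / config$spacing[1])))
  orig <- read_fcsv(stage_path(config, "origElectrodes.fcsv"))
  proj <- read_fcsv(stage_path(config, "projElectrodes.fcsv"))
  sheet <- read_stl(stage_path(config, "electrode_sheet.stl"))
  nodes_ps <- point_set(grid$nodes, sprintf("N%d", seq_len(nrow(grid$nodes))))
  sel <- select_nodes_under_sheet(nodes_ps, sheet, tol = 5)
  load <- build_load_table(sel, grid$nodes, electrode_set(orig, proj))
  f1 <- stage_path(config, "mesh.inp")
  f2 <- stage_path(config, "load.txt")
  write_abaqus_inp(grid, f1)
  write_load_table(load, f2)
  write_manifest(config, "loads",
                 list(mask = "brain_mask.nrrd", sheet = "electrode_sheet.stl"),
                 c(f1, f2), list(tol_mm = 5))
  c(f1, f2)
}

stage_biomech <- function(config) {
  grid <- read_abaqus_inp(stage_path(config, "mesh.inp"))
  load <- utils::read.table(stage_path(config, "load.txt"),
                            col.names = c("node", "ux", "uy", "uz"))
  model <- meshless_model(grid, prescribed_nodes = load$node)
  state <- solve_static(model, load,
                        mtled_config(ramp_steps = 400L, max_steps = 8000L,
                                     tol = 1e-4, patience = 50L))
  f1 <- stage_path(config, "displacements.csv")
  utils::write.csv(data.frame(node = seq_len(nrow(state$U)),
                              ux = state$U[, 1], uy = state$U[, 2],
                              uz = state$U[, 3]), f1, row.names = FALSE)
  f2 <- stage_path(config, "brain_deformed.vtk")
  write_vtk_grid(grid$nodes, grid$tets, f2,
                 point_data = list(displacement = state$displacements))
  write_manifest(config, "biomech",
                 list(grid = "mesh.inp", load = "load.txt"),
                 c(f1, f2),
                 list(steps = state$steps, converged = state$converged,
                      strain_energy = state$strain_energy))
  assign(".ecogfwd_last_state", state, envir = pipeline_cache)
  c(f1, f2)
}

pipeline_cache <- new.env(parent = emptyenv())

stage_warp <- function(config) {
  labels <- read_nrrd(stage_path(config, "labels.nrrd"), "label")
  dti <- read_nrrd(stage_path(config, "dti.nrrd"), "tensor")
  state <- if (exists(".ecogfwd_last_state", envir = pipeline_cache)) {
    get(".ecogfwd_last_state", envir = pipeline_cache)
  } else {
    # rebuild the solved state from the biomech stage outputs
    grid <- read_abaqus_inp(stage_path(config, "mesh.inp"))
    load <- utils::read.table(stage_path(config, "load.txt"),
                              col.names = c("node", "ux", "uy", "uz"))
    U <- as.matrix(utils::read.csv(stage_path(config, "displacements.csv"))[, 2:4])
    model <- meshless_model(grid, prescribed_nodes = load$node)
    structure(list(U = U, model = model), class = "deformation_state")
  }
  brain <- read_nrrd(stage_path(config, "brain_mask.nrrd"), "mask")
  # evaluate over a dilated brain mask and taper smoothly to zero outside,
  # so the field stays continuous (and invertible) across the brain edge
  support <- dilate_mask(brain, 4 * max(labels$grid$spacing))
  fwd <- field_from_solution(state, labels$grid, support)
  ramp <- pmin(1, pmax(0, 2 * smooth_field(brain$values + 0, 4L)))
  v <- matrix(fwd$values, nrow = 3)
  v <- v * rep(as.vector(ramp), each = 3)
  fwd <- displacement_field(v, labels$grid, "forward")
  bwd <- invert_field(fwd, tol = 0.5 * min(labels$grid$spacing),
                      max_iter = 80L, relax = 0.7, max_fail_frac = 0.01)
  warped_dti <- warp_dti(dti, bwd)
  f1 <- stage_path(config, "warp.nrrd")
  f2 <- stage_path(config, "dti_warped.nrrd")
  write_nrrd(vector_image(fwd$values, labels$grid), f1)
  write_nrrd(warped_dti, f2)
  write_manifest(config, "warp",
                 list(labels = "labels.nrrd", dti = "dti.nrrd"),
                 c(f1, f2), list(inversion_tol_mm = 0.25 * min(labels$grid$spacing)))
  c(f1, f2)
}

stage_classify <- function(config) {
  labels <- read_nrrd(stage_path(config, "labels.nrrd"), "label")
  dti <- read_nrrd(stage_path(config, "dti.nrrd"), "tensor")
  brain <- mask_image(labels$values %in% 1:3, labels$grid)
  seg <- classify_brain(dti, brain, fcm_config(seed = config$seed))
  f <- stage_path(config, "seg.nrrd")
  write_nrrd(seg, f)
  write_manifest(config, "classify",
                 list(labels = "labels.nrrd", dti = "dti.nrrd"), f,
                 list(m = 2, seed = config$seed))
  f
}

stage_fuse <- function(config) {
  seg <- read_nrrd(stage_path(config, "seg.nrrd"), "label")
  brain <- read_nrrd(stage_path(config, "brain_mask.nrrd"), "mask")
  sheet_mask <- NULL
  if (config$with_sheet) {
    slab <- read_stl(stage_path(config, "electrode_sheet.stl"))
    sheet_mask <- voxelize_surface(slab, seg$grid)
  }
  shell <- 2.2 * config$spacing[1]
  lm <- build_head_labelmap(seg, brain, sheet_mask, shell_mm = shell)
  f1 <- stage_path(config, "labelmap.nrrd")
  f2 <- stage_path(config, "ColorTable.ctbl")
  write_nrrd(lm, f1)
  write_color_table(head_classes(), f2)
  write_manifest(config, "fuse",
                 list(seg = "seg.nrrd", mask = "brain_mask.nrrd"),
                 c(f1, f2), list(shell_mm = shell, with_sheet = config$with_sheet))
  c(f1, f2)
}

stage_conductivity <- function(config) {
  lm <- read_nrrd(stage_path(config, "labelmap.nrrd"), "label")
  dti <- read_nrrd(stage_path(config, "dti.nrrd"), "tensor")
  cond <- assign_conductivity(lm, dti)
  f <- stage_path(config, "cond.nrrd")
  write_nrrd(cond, f)
  write_manifest(config, "conductivity",
                 list(labelmap = "labelmap.nrrd", dti = "dti.nrrd"), f,
                 list(wm_mode = "volume_normalized", wm_sigma_ref = 0.14))
  f
}

stage_hexmesh <- function(config) {
  lm <- read_nrrd(stage_path(config, "labelmap.nrrd"), "label")
  cond <- read_nrrd(stage_path(config, "cond.nrrd"), "tensor")
  mesh <- voxels_to_hexmesh(lm)
  f1 <- stage_path(config, "mesh.mesh.gz")
  f2 <- stage_path(config, "cond.gf.gz")
  f3 <- stage_path(config, "hexmesh_summary.json")
  write_hexmesh_gz(mesh, f1)
  write_element_tensors_gz(element_tensors(mesh, cond), f2)
  jsonlite::write_json(list(nodes = nrow(mesh$nodes),
                            elements = nrow(mesh$elems)),
                       f3, auto_unbox = TRUE)
  write_manifest(config, "hexmesh",
                 list(labelmap = "labelmap.nrrd", cond = "cond.nrrd"),
                 c(f1, f2, f3), list())
  c(f1, f2, f3)
}

stage_forward <- function(config) {
  lm <- read_nrrd(stage_path(config, "labelmap.nrrd"), "label")
  cond <- read_nrrd(stage_path(config, "cond.nrrd"), "tensor")
  ctr <- (lm$grid$dims - 1) / 2 * lm$grid$spacing + lm$grid$origin
  # dipole inside the (isotropic) gray-matter shell, at the configured
  # fractional depth between the WM core and the GM outer radius
  r_dip <- config$radii[5] + config$dipole_frac * (config$radii[4] - config$radii[5])
  dip_pos <- ctr + c(0, 0, r_dip)
  # place the dipole in GM with an isotropic local conductivity
  dip <- dipole_source(dip_pos, c(1, 0, 0) * 1e-3,
                       sigma0 = diag(3) * 0.33, homogeneity_radius = 1.5)
  fs <- forward_solve(lm, cond, dip)
  proj <- read_fcsv(stage_path(config, "projElectrodes.fcsv"))
  pots <- tryCatch(sample_potentials(fs$solution, fs$mesh, proj),
                   error = function(e) rep(NA_real_, nrow(proj)))
  f <- stage_path(config, "electrode_potentials.csv")
  utils::write.csv(data.frame(label = proj$label, potential = pots), f,
                   row.names = FALSE)
  f2 <- stage_path(config, "potential.vtu")
  write_vtu(fs$mesh$nodes, fs$mesh$elems, f2,
            point_data = list(potential = fs$solution$potential,
                              correction = fs$solution$correction))
  f3 <- stage_path(config, "results_paraview.pvd")
  write_pvd("potential.vtu", f3)
  write_manifest(config, "forward",
                 list(labelmap = "labelmap.nrrd", cond = "cond.nrrd"),
                 c(f, f2, f3),
                 list(dipole_pos = dip_pos, moment = c(1e-3, 0, 0),
                      cg_iterations = fs$solution$iterations))
  assign(".ecogfwd_last_forward", fs, envir = pipeline_cache)
  c(f, f2, f3)
}

stage_metrics <- function(config) {
  labels <- read_nrrd(stage_path(config, "labels.nrrd"), "label")
  seg <- read_nrrd(stage_path(config, "seg.nrrd"), "label")
  sel <- labels$values %in% 1:3
  acc <- mean(seg$values[sel] == labels$values[sel])
  fs <- get(".ecogfwd_last_forward", envir = pipeline_cache)
  # oracle comparison on a homogeneous-equivalent sphere is only meaningful
  # for the spherical phantom: compare against the 4-layer analytic series
  # built from the phantom radii and the nominal class conductivities
  ctr <- (labels$grid$dims - 1) / 2 * labels$grid$spacing + labels$grid$origin
  man <- jsonlite::read_json(stage_path(config, "forward.manifest.json"))
  dip_pos <- unlist(man$parameters$dipole_pos)
  model <- analytic_sphere_model(
    layer_radii = c(config$radii[4], config$radii[3], config$radii[2],
                    config$radii[1]),
    layer_conductivities = c(0.33, 1.79, 0.012, 0.33),
    dipole_pos = dip_pos - ctr, dipole_moment = unlist(man$parameters$moment),
    n_terms = 600L)  # shallow dipoles need a deep series
  rsample <- config$radii[1] - 2 * config$spacing[1]
  dirs <- fibonacci_sphere(200)
  pts_local <- rsample * dirs
  ana <- analytic_dipole_sphere(model, pts_local)$potential
  num <- tryCatch(sample_potentials(fs$solution, fs$mesh,
                                    sweep(pts_local, 2, ctr, `+`)),
                  error = function(e) NULL)
  met <- list(classification_accuracy = acc)
  if (!is.null(num) && !config$with_sheet && config$skip_biomech) {
    rm <- rdm_mag(num - mean(num), ana - mean(ana))
    met$rdm <- rm$rdm
    met$mag <- rm$mag
  } else if (!is.null(num)) {
    # sheet/deformation perturb the spherical geometry; report the raw
    # comparison as indicative only
    rm <- rdm_mag(num - mean(num), ana - mean(ana))
    met$rdm_indicative <- rm$rdm
    met$mag_indicative <- rm$mag
  }
  met$cg_iterations <- fs$solution$iterations
  met$cg_relres <- fs$solution$relres
  f <- stage_path(config, "report.json")
  jsonlite::write_json(met, f, auto_unbox = TRUE, digits = NA)
  write_manifest(config, "metrics",
                 list(seg = "seg.nrrd", labels = "labels.nrrd"), f, list())
  f
}

# evenly spread directions on the unit sphere (golden-angle spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(th), r * sin(th), z)
}
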