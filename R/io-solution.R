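#' Write a .vtu (XML unstructured grid) file
#'
#' ASCII VTK XML writer for tetrahedral or hexahedral grids with optional
#' per-node fields, plus a ParaView `.pvd` collection index for time series
#' of solutions.
#'
#' @param nodes n x 3 node coordinates (mm).
#' @param cells m x 4 or m x 8 1-based connectivity.
#' @param path output path.
#' @param point_data named list of per-node vectors or n x 3 matrices.
#' @export
write_vtu <- function(nodes, cells, path, point_data = list()) {
  npc <- ncol(cells)
  ctype <- if (npc == 4) 10L else if (npc == 8) 12L else
    stop("write_vtu: cells must have 4 or 8 nodes")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nrow(nodes), nrow(cells))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(sprintf("%.9g %.9g %.9g", nodes[, 1], nodes[, 2], nodes[, 3]), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(apply(cells - 1L, 1, paste, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(as.character(seq_len(nrow(cells)) * npc), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(as.character(rep(ctype, nrow(cells))), con)
  w('        </DataArray>')
  w('      </Cells>')
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        w('        <DataArray type="Float64" Name="%s" NumberOfComponents="3" format="ascii">', nm)
        writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
      } else {
        w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
        writeLines(sprintf("%.9g", v), con)
      }
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' @rdname write_vtu
#' @param files character vector of .vtu paths (relative to the .pvd).
#' @param times numeric time stamps, one per file.
#' @export
write_pvd <- function(files, path, times = seq_along(files) - 1) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c('<?xml version="1.0"?>',
               '<VTKFile type="Collection" version="0.1">',
               '  <Collection>'), con)
  writeLines(sprintf('    <DataSet timestep="%g" part="0" file="%s"/>',
                     times, files), con)
  writeLines(c('  </Collection>', '</VTKFile>'), con)
  invisible(path)
}

#' Write a hex mesh and per-element tensors as compressed plain text
#'
#' `write_hexmesh_gz` stores the node coordinates and element connectivity
#' (with the per-element source label as attribute), and
#' `write_element_tensors_gz` one packed conductivity tensor row per
#' element — the gzip-compressed plain-text mesh / grid-function pairing
#' used by voxel-based FEM workflows.
#'
#' @param mesh a [voxels_to_hexmesh()] mesh.
#' @param path output path (conventionally `*.mesh.gz` / `*.gf.gz`).
#' @export
write_hexmesh_gz <- function(mesh, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(c("ecogfwd hex mesh", "dimension", "3", "", "elements",
               as.character(nrow(mesh$elems))), con)
  writeLines(paste(mesh$labels, 5L,
                   apply(mesh$elems - 1L, 1, paste, collapse = " ")), con)
  writeLines(c("", "vertices", as.character(nrow(mesh$nodes)), "3"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  invisible(path)
}

#' @rdname write_hexmesh_gz
#' @param sig6 6 x m packed tensors (see [element_tensors()]).
#' @export
write_element_tensors_gz <- function(sig6, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(c("ecogfwd element tensors", "components 6 (xx xy xz yy yz zz)",
               as.character(ncol(sig6))), con)
  writeLines(apply(sig6, 2, function(v) paste(sprintf("%.9g", v), collapse = " ")),
             con)
  invisible(path)
}

#' Read and write INI-style solver configuration
#'
#' A minimal `key = value` INI dialect with `[section]` headers, mirroring
#' the configuration files of explicit meshless solvers. `solver_config_ini`
#' maps a `[solver]` section (keys `ramp_steps`, `max_steps`, `tolerance`,
#' `patience`, `mass_scale`) onto an [mtled_config()].
#'
#' @param path file path.
#' @return named list of sections, each a named character list.
#' @export
read_ini <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, ";")]
  out <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
    } else if (grepl("=", ln)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' @rdname read_ini
#' @param config named list of sections.
#' @export
write_ini <- function(config, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sec in names(config)) {
    writeLines(sprintf("[%s]", sec), con)
    for (k in names(config[[sec]]))
      writeLines(sprintf("%s = %s", k, config[[sec]][[k]]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname read_ini
#' @export
solver_config_ini <- function(path) {
  ini <- read_ini(path)
  s <- ini$solver
  if (is.null(s)) stop("solver_config_ini: no [solver] section in ", path)
  num <- function(key, default) if (is.null(s[[key]])) default else as.numeric(s[[key]])
  mtled_config(ramp_steps = as.integer(num("ramp_steps", 500)),
               max_steps = as.integer(num("max_steps", 20000)),
               tol = num("tolerance", 1e-5),
               patience = as.integer(num("patience", 100)),
               mass_scale = num("mass_scale", 2))
}
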