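#' Read and write STL surfaces
#'
#' Binary and ASCII STL. STL files from RAS-world tools can be converted to
#' the internal LPS frame on read (and back on write) with `ras = TRUE`,
#' which negates the first two coordinates.
#'
#' @param path file path.
#' @param ras logical; convert between RAS (file) and LPS (memory).
#' @param merge_tol vertex-welding tolerance in mm (STL stores triangle
#'   soup; coincident vertices are merged).
#' @return [read_stl()] returns a [tri_surface()].
#' @export
read_stl <- function(path, ras = FALSE, merge_tol = 1e-6) {
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  fsize <- file.info(path)$size
  is_binary <- !is.na(ntri) && fsize == 84 + 50 * as.numeric(ntri)
  if (is_binary) {
    tris <- matrix(0, ntri, 9)
    for (t in seq_len(ntri)) {
      rec <- readBin(con, "double", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      tris[t, ] <- rec[4:12]
    }
  } else {
    close(con)
    on.exit(NULL)
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    vv <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                function(s) as.numeric(s[2:4])))
    if (nrow(vv) %% 3 != 0) stop("read_stl: malformed ASCII STL")
    tris <- matrix(as.vector(t(vv)), ncol = 9, byrow = TRUE)
  }
  # rows of tris are (v1x v1y v1z v2x ... v3z); unstack to one vertex per row
  verts <- t(matrix(t(tris), nrow = 3))
  if (ras) verts[, 1:2] <- -verts[, 1:2]
  # weld coincident vertices
  key <- apply(round(verts / merge_tol), 1, paste, collapse = ",")
  uid <- !duplicated(key)
  map <- match(key, key[uid])
  v <- verts[uid, , drop = FALSE]
  f <- matrix(map, ncol = 3, byrow = TRUE)
  drop_degenerate_triangles(tri_surface(v, f))
}

#' @rdname read_stl
#' @param surface a [tri_surface()].
#' @param ascii write ASCII STL instead of binary.
#' @export
write_stl <- function(surface, path, ras = FALSE, ascii = FALSE) {
  v <- surface$vertices
  if (ras) v[, 1:2] <- -v[, 1:2]
  tr <- surface$triangles
  n <- face_normals(surface)
  if (ras) n[, 1:2] <- -n[, 1:2]
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid ecogfwd", con)
    for (t in seq_len(nrow(tr))) {
      writeLines(sprintf("facet normal %g %g %g", n[t, 1], n[t, 2], n[t, 3]), con)
      writeLines(" outer loop", con)
      for (c in 1:3)
        writeLines(sprintf("  vertex %.9g %.9g %.9g",
                           v[tr[t, c], 1], v[tr[t, c], 2], v[tr[t, c], 3]), con)
      writeLines(" endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid ecogfwd", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(tr)), con, size = 4, endian = "little")
    for (t in seq_len(nrow(tr))) {
      writeBin(c(n[t, ], v[tr[t, 1], ], v[tr[t, 2], ], v[tr[t, 3], ]),
               con, size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  }
  invisible(path)
}

#' Read and write 3D Slicer fiducial files (.fcsv)
#'
#' The Markups fiducial CSV dialect (`# Markups fiducial file ...` header).
#' Slicer stores coordinates in RAS by default; they are converted to the
#' internal LPS frame on read according to the `CoordinateSystem` header
#' (and written back as LPS with an explicit header).
#'
#' @param path file path.
#' @return A [point_set()].
#' @export
read_fcsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  ras <- TRUE
  cs <- grep("CoordinateSystem", hdr, value = TRUE)
  if (length(cs) && grepl("LPS|= *1", cs[1])) ras <- FALSE
  dat <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(dat, ",")
  xyz <- do.call(rbind, lapply(fields, function(f) as.numeric(f[2:4])))
  labels <- vapply(fields, function(f) if (length(f) >= 12 && nzchar(f[12])) f[12] else f[1], "")
  if (ras) xyz[, 1:2] <- -xyz[, 1:2]
  point_set(xyz, make.unique(labels))
}

#' @rdname read_fcsv
#' @param points a [point_set()].
#' @export
write_fcsv <- function(points, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# Markups fiducial file version = 4.11",
               "# CoordinateSystem = LPS",
               "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID"),
             con)
  for (i in seq_len(nrow(points)))
    writeLines(sprintf("vtkMRMLMarkupsFiducialNode_%d,%.9g,%.9g,%.9g,0,0,0,1,1,1,0,%s,,",
                       i, points$x[i], points$y[i], points$z[i], points$label[i]), con)
  invisible(path)
}

#' Read an Abaqus-style tetrahedral grid (.inp)
#'
#' Parses `*NODE` and `*ELEMENT` (C3D4) blocks plus optional `*NSET` node
#' sets, as used for the meshless background integration grid.
#'
#' @param path file path.
#' @return A [tet_grid()] with a `node_sets` attribute (named list of
#'   1-based node indices).
#' @export
read_abaqus_inp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\*\\*", lines)]
  sec <- toupper(sub(",.*", "", lines))
  nodes <- NULL
  elems <- NULL
  nsets <- list()
  i <- 1
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^\\*NODE", toupper(ln))) {
      j <- i + 1
      while (j <= length(lines) && !grepl("^\\*", lines[j])) j <- j + 1
      dat <- do.call(rbind, lapply(strsplit(lines[(i + 1):(j - 1)], ","),
                                   function(f) as.numeric(f[1:4])))
      nodes <- dat[order(dat[, 1]), 2:4, drop = FALSE]
      i <- j
    } else if (grepl("^\\*ELEMENT", toupper(ln))) {
      if (!grepl("C3D4", toupper(ln)))
        stop("read_abaqus_inp: only C3D4 tetrahedra are supported")
      j <- i + 1
      while (j <= length(lines) && !grepl("^\\*", lines[j])) j <- j + 1
      dat <- do.call(rbind, lapply(strsplit(lines[(i + 1):(j - 1)], ","),
                                   function(f) as.integer(f[1:5])))
      elems <- dat[order(dat[, 1]), 2:5, drop = FALSE]
      i <- j
    } else if (grepl("^\\*NSET", toupper(ln))) {
      nm <- sub(".*NSET=([^,]+).*", "\\1", ln, ignore.case = TRUE)
      j <- i + 1
      while (j <= length(lines) && !grepl("^\\*", lines[j])) j <- j + 1
      ids <- as.integer(unlist(strsplit(paste(lines[(i + 1):(j - 1)], collapse = ","), ",")))
      nsets[[nm]] <- ids[!is.na(ids)]
      i <- j
    } else {
      i <- i + 1
    }
  }
  if (is.null(nodes) || is.null(elems)) stop("read_abaqus_inp: missing *NODE or *ELEMENT block")
  g <- tet_grid(nodes, elems)
  attr(g, "node_sets") <- nsets
  g
}

#' @rdname read_abaqus_inp
#' @param grid a [tet_grid()].
#' @export
write_abaqus_inp <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(grid$nodes)),
                     grid$nodes[, 1], grid$nodes[, 2], grid$nodes[, 3]), con)
  writeLines("*ELEMENT, TYPE=C3D4", con)
  writeLines(sprintf("%d, %d, %d, %d, %d", seq_len(nrow(grid$tets)),
                     grid$tets[, 1], grid$tets[, 2], grid$tets[, 3], grid$tets[, 4]), con)
  invisible(path)
}

#' Write a legacy VTK unstructured grid
#'
#' ASCII legacy `.vtk` writer for tetrahedral or hexahedral grids with
#' optional point data (scalars or 3-vectors) and cell data, for inspection
#' in ParaView.
#'
#' @param nodes n x 3 node coordinates (mm).
#' @param cells m x 4 (tets) or m x 8 (hexes) 1-based connectivity.
#' @param path output path.
#' @param point_data named list of per-node vectors/matrices.
#' @param cell_data named list of per-cell vectors.
#' @export
write_vtk_grid <- function(nodes, cells, path, point_data = list(),
                           cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(nodes)
  nc <- nrow(cells)
  npc <- ncol(cells)
  ctype <- if (npc == 4) 10L else if (npc == 8) 12L else
    stop("write_vtk_grid: cells must have 4 or 8 nodes")
  writeLines(c("# vtk DataFile Version 3.0", "ecogfwd grid", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  writeLines(sprintf("%.9g %.9g %.9g", nodes[, 1], nodes[, 2], nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nc, nc * (npc + 1)), con)
  writeLines(apply(cbind(npc, cells - 1L), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELL_TYPES %d", nc), con)
  writeLines(as.character(rep(ctype, nc)), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nn), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.9g", v), con)
      }
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", nc), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", cell_data[[nm]]), con)
    }
  }
  invisible(path)
}

#' Write a whitespace load table (node id, ux, uy, uz)
#'
#' @param load a `load_table` data.frame (see [build_load_table()]).
#' @param path output path.
#' @export
write_load_table <- function(load, path) {
  utils::write.table(load, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a tissue class colour table (.ctbl-style)
#'
#' One `label name R G B A` row per class, mirroring the 3D Slicer colour
#' table format.
#'
#' @param classes data.frame with columns `label`, `name`.
#' @param path output path.
#' @export
write_color_table <- function(classes, path) {
  cols <- matrix(c(255, 255, 255, 200, 200, 200, 80, 120, 255,
                   230, 230, 100, 255, 170, 120, 60, 60, 60),
                 ncol = 3, byrow = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(classes))) {
    rgb <- cols[(i - 1) %% nrow(cols) + 1, ]
    writeLines(sprintf("%d %s %d %d %d 255", classes$label[i],
                       gsub(" ", "_", classes$name[i]), rgb[1], rgb[2], rgb[3]), con)
  }
  invisible(path)
}
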