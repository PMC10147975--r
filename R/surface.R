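#' Triangulated surface
#'
#' @param vertices n x 3 matrix of vertex positions (mm, world LPS).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @return A `tri_surface` object.
#' @export
tri_surface <- function(vertices, triangles) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("tri_surface: triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles),
            class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("tri_surface: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Labelled 3D point set (fiducials)
#'
#' @param coords n x 3 matrix (mm, world LPS).
#' @param labels character labels, unique; default `P1..Pn`.
#' @return A data.frame of class `point_set` with columns `label,x,y,z`.
#' @export
point_set <- function(coords, labels = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (any(!is.finite(coords))) stop("point_set: coordinates must be finite")
  if (is.null(labels)) labels <- sprintf("P%d", seq_len(nrow(coords)))
  if (anyDuplicated(labels)) stop("point_set: labels must be unique")
  structure(data.frame(label = as.character(labels), x = coords[, 1],
                       y = coords[, 2], z = coords[, 3],
                       stringsAsFactors = FALSE),
            class = c("point_set", "data.frame"))
}

#' Coordinate matrix of a point set
#' @param ps a [point_set()].
#' @return n x 3 numeric matrix.
#' @export
ps_coords <- function(ps) as.matrix(ps[, c("x", "y", "z")])

# per-face unit normals and areas
face_normals <- function(surface) {
  v <- surface$vertices
  tr <- surface$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

face_areas <- function(surface) {
  v <- surface$vertices
  tr <- surface$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(n^2))
}

# area-weighted vertex normals
vertex_normals <- function(surface) {
  fn <- face_normals(surface) * face_areas(surface)
  tr <- surface$triangles
  n <- matrix(0, nrow(surface$vertices), 3)
  for (c in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], tr[, c])
      n[as.integer(rownames(acc)), d] <- n[as.integer(rownames(acc)), d] + acc
    }
  }
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

#' Total surface area (mm^2)
#' @param surface a [tri_surface()].
#' @export
surface_area <- function(surface) sum(face_areas(surface))

#' Enclosed volume of a closed, outward-oriented surface (mm^3)
#'
#' Signed volume via the divergence theorem; positive for consistent outward
#' orientation.
#' @param surface a [tri_surface()].
#' @export
surface_volume <- function(surface) {
  v <- surface$vertices
  tr <- surface$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  cc <- v[tr[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# edge incidence table: each row an undirected edge with its face count
edge_counts <- function(surface) {
  tr <- surface$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Surface topology summary
#'
#' @param surface a [tri_surface()].
#' @return list with `n_vertices`, `n_edges`, `n_faces`, `euler`
#'   (V - E + F), `closed` (every edge shared by exactly two triangles) and
#'   `manifold` (no edge with more than two faces).
#' @export
surface_topology <- function(surface) {
  ec <- edge_counts(surface)
  used <- sort(unique(as.vector(surface$triangles)))
  list(n_vertices = length(used), n_edges = length(ec),
       n_faces = nrow(surface$triangles),
       euler = length(used) - length(ec) + nrow(surface$triangles),
       closed = all(ec == 2), manifold = all(ec <= 2))
}

# small separable 6-neighbour box smoothing used before isosurfacing binary
# masks (marching on raw 0/1 data produces staircase geometry)
smooth_field <- function(a, iterations = 2L) {
  d <- dim(a)
  for (it in seq_len(iterations)) {
    s <- a * 6
    w <- rep(6, length(a)); dim(w) <- d
    s[-1, , ] <- s[-1, , ] + a[-d[1], , ]
    s[-d[1], , ] <- s[-d[1], , ] + a[-1, , ]
    s[, -1, ] <- s[, -1, ] + a[, -d[2], ]
    s[, -d[2], ] <- s[, -d[2], ] + a[, -1, ]
    s[, , -1] <- s[, , -1] + a[, , -d[3]]
    s[, , -d[3]] <- s[, , -d[3]] + a[, , -1]
    w[-1, , ] <- w[-1, , ] + 1; w[-d[1], , ] <- w[-d[1], , ] + 1
    w[, -1, ] <- w[, -1, ] + 1; w[, -d[2], ] <- w[, -d[2], ] + 1
    w[, , -1] <- w[, , -1] + 1; w[, , -d[3]] <- w[, , -d[3]] + 1
    a <- s / w
  }
  a
}

#' Extract an isosurface from a mask or scalar image
#'
#' Marching-tetrahedra isosurfacing (the tetrahedral-decomposition variant of
#' marching cubes): each voxel cell is split into six tetrahedra sharing the
#' cell diagonal, which yields a watertight, consistently outward-oriented
#' triangulation of the isosurface in world coordinates. Binary masks are
#' lightly box-smoothed first (`smooth_iterations`), as is standard practice
#' when building surface models from segmentations; pass 0 to disable.
#'
#' @param image a [mask_image()] or [scalar_image()].
#' @param isovalue iso level; default 0.5 for masks.
#' @param smooth_iterations smoothing passes applied to binary input (default 3).
#' @return A [tri_surface()].
#' @export
marching_cubes <- function(image, isovalue = NULL, smooth_iterations = 3L) {
  stopifnot(inherits(image, c("mask_image", "scalar_image")))
  field <- image$values + 0
  if (inherits(image, "mask_image")) {
    if (is.null(isovalue)) isovalue <- 0.5
    if (smooth_iterations > 0) field <- smooth_field(field, smooth_iterations)
  }
  if (is.null(isovalue)) stop("marching_cubes: isovalue required for scalar images")
  if (max(field) <= isovalue || min(field) >= isovalue)
    stop("marching_cubes: the isosurface is empty at isovalue ", isovalue)
  res <- cpp_marching_tets(as.numeric(field), image$grid$dims, isovalue)
  vw <- index_to_world(image$grid, res$vertices)
  s <- tri_surface(vw, res$triangles)
  drop_degenerate_triangles(s)
}

drop_degenerate_triangles <- function(surface, tol = 1e-12) {
  a <- face_areas(surface)
  keep <- a > tol * max(a)
  tr <- surface$triangles[keep, , drop = FALSE]
  used <- sort(unique(as.vector(tr)))
  remap <- integer(nrow(surface$vertices))
  remap[used] <- seq_along(used)
  tri_surface(surface$vertices[used, , drop = FALSE],
              matrix(remap[tr], ncol = 3))
}

#' Project points to their closest points on a surface
#'
#' Maps each point to the closest point on the triangulated surface
#' (point-to-triangle distance); the perpendicular foot for points near a
#' smooth patch. Labels are preserved.
#'
#' @param points a [point_set()].
#' @param surface a [tri_surface()].
#' @return A [point_set()] of projected points, with attribute `"distance"`.
#' @export
project_points_to_surface <- function(points, surface) {
  stopifnot(inherits(points, "point_set"), inherits(surface, "tri_surface"))
  if (nrow(surface$triangles) == 0) stop("project_points_to_surface: empty surface")
  cp <- cpp_closest_point(ps_coords(points), surface$vertices, surface$triangles)
  out <- point_set(cp$point, points$label)
  attr(out, "distance") <- cp$distance
  attr(out, "triangle") <- cp$triangle
  out
}

# ---- 2D Delaunay (Bowyer-Watson), used for the electrode sheet -------------

delaunay2d <- function(p) {
  n <- nrow(p)
  stopifnot(n >= 3)
  # super-triangle
  ctr <- colMeans(p)
  rad <- 3 * max(sqrt(rowSums(sweep(p, 2, ctr)^2))) + 1
  sup <- rbind(ctr + rad * c(0, 2), ctr + rad * c(-1.8, -1), ctr + rad * c(1.8, -1))
  pts <- rbind(p, sup)
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), 1, 3)
  circum <- function(t) {
    a <- pts[t[1], ]; b <- pts[t[2], ]; cc <- pts[t[3], ]
    d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) + cc[1] * (a[2] - b[2]))
    if (abs(d) < 1e-300) return(c(Inf, Inf, Inf))
    ux <- ((a[1]^2 + a[2]^2) * (b[2] - cc[2]) + (b[1]^2 + b[2]^2) * (cc[2] - a[2]) +
           (cc[1]^2 + cc[2]^2) * (a[2] - b[2])) / d
    uy <- ((a[1]^2 + a[2]^2) * (cc[1] - b[1]) + (b[1]^2 + b[2]^2) * (a[1] - cc[1]) +
           (cc[1]^2 + cc[2]^2) * (b[1] - a[1])) / d
    c(ux, uy, sqrt((a[1] - ux)^2 + (a[2] - uy)^2))
  }
  cc <- t(apply(tris, 1, circum))
  for (i in seq_len(n)) {
    px <- pts[i, ]
    bad <- which(sqrt((cc[, 1] - px[1])^2 + (cc[, 2] - px[2])^2) <= cc[, 3] * (1 + 1e-12))
    if (length(bad) == 0) stop("triangulate_centroids: degenerate (collinear?) points")
    # cavity boundary: edges of bad triangles not shared by two bad triangles
    be <- do.call(rbind, lapply(bad, function(t) {
      tr <- tris[t, ]
      rbind(tr[c(1, 2)], tr[c(2, 3)], tr[c(3, 1)])
    }))
    key <- paste(pmin(be[, 1], be[, 2]), pmax(be[, 1], be[, 2]))
    keep <- key %in% names(which(table(key) == 1))
    boundary <- be[keep, , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    newt <- cbind(boundary, i)
    tris <- rbind(tris, newt)
    cc <- rbind(cc, t(apply(newt, 1, circum)))
  }
  keep <- rowSums(matrix(tris %in% (n + 1L):(n + 3L), nrow(tris))) == 0
  tris[keep, , drop = FALSE]
}

#' Triangulate electrode centroids into a sheet surface
#'
#' Projects the points to their best-fit plane (principal components),
#' Delaunay-triangulates in 2D, and lifts the triangulation back to the
#' original 3D points, producing the open electrode-sheet surface.
#'
#' @param points a [point_set()] with at least 3 non-collinear points.
#' @return A [tri_surface()].
#' @export
triangulate_centroids <- function(points) {
  stopifnot(inherits(points, "point_set"), nrow(points) >= 3)
  xyz <- ps_coords(points)
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  if (sv$d[2] < 1e-9 * sv$d[1])
    stop("triangulate_centroids: points are collinear")
  uv <- sweep(xyz, 2, ctr) %*% sv$v[, 1:2]
  tri_surface(xyz, delaunay2d(uv))
}

#' Extrude an open sheet into a closed slab
#'
#' Offsets the sheet by half the thickness along its vertex normals on both
#' sides and stitches the boundary with side-wall triangles, producing a
#' closed (watertight) surface.
#'
#' @param sheet an open [tri_surface()].
#' @param thickness slab thickness in mm (> 0).
#' @return A closed [tri_surface()].
#' @export
extrude_sheet <- function(sheet, thickness) {
  stopifnot(inherits(sheet, "tri_surface"), thickness > 0)
  vn <- vertex_normals(sheet)
  nv <- nrow(sheet$vertices)
  top <- sheet$vertices + thickness / 2 * vn
  bot <- sheet$vertices - thickness / 2 * vn
  verts <- rbind(top, bot)
  tr <- sheet$triangles
  faces <- rbind(tr, cbind(tr[, 1], tr[, 3], tr[, 2]) + nv)
  # boundary half-edges in face winding order
  he <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  bnd <- he[key %in% names(which(table(key) == 1)), , drop = FALSE]
  walls <- rbind(cbind(bnd[, 1] + nv, bnd[, 2] + nv, bnd[, 2]),
                 cbind(bnd[, 1] + nv, bnd[, 2], bnd[, 1]))
  out <- tri_surface(verts, rbind(faces, walls))
  topo <- surface_topology(out)
  if (!topo$closed)
    stop("extrude_sheet: extrusion failed to close (self-intersecting sheet?)")
  if (surface_volume(out) < 0)  # flip if inward-oriented
    out$triangles <- out$triangles[, c(1, 3, 2)]
  out
}

#' Voxelize a closed surface
#'
#' Marks every voxel whose centre lies inside the watertight surface, using
#' a ray-parity test. The parity result is independent of the ray axis; the
#' axis is exposed for verification.
#'
#' @param surface a closed [tri_surface()].
#' @param grid an [image_grid()].
#' @param axis ray direction (1, 2 or 3).
#' @return A [mask_image()].
#' @export
voxelize_surface <- function(surface, grid, axis = 1L) {
  stopifnot(inherits(surface, "tri_surface"), inherits(grid, "image_grid"))
  topo <- surface_topology(surface)
  if (!topo$closed)
    stop("voxelize_surface: surface is not closed (", topo$n_edges,
         " edges, not all shared by 2 faces)")
  vi <- world_to_index(grid, surface$vertices)
  m <- cpp_voxelize(vi, surface$triangles, grid$dims, as.integer(axis) - 1L)
  mask_image(m, grid)
}

#' Select surface nodes lying under an electrode sheet
#'
#' Returns the indices of nodes whose closest-point distance to the sheet is
#' at most `tol` (mm), in ascending index order. An empty selection raises a
#' warning.
#'
#' @param nodes a [point_set()] (e.g. brain-surface mesh nodes).
#' @param sheet a [tri_surface()].
#' @param tol distance tolerance in mm (default 5).
#' @return integer vector of row indices into `nodes`.
#' @export
select_nodes_under_sheet <- function(nodes, sheet, tol = 5) {
  stopifnot(inherits(nodes, "point_set"), inherits(sheet, "tri_surface"), tol >= 0)
  cp <- cpp_closest_point(ps_coords(nodes), sheet$vertices, sheet$triangles)
  idx <- which(cp$distance <= tol + 1e-12)
  if (length(idx) == 0)
    warning("select_nodes_under_sheet: no nodes within ", tol, " mm of the sheet")
  sort(idx)
}
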