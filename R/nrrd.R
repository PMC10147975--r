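#' Read an NRRD image
#'
#' Reads scalar, label, mask, displacement-vector and symmetric-tensor NRRD
#' volumes (detached headers are not supported). The world frame must be
#' `left-posterior-superior` (LPS, the package-internal frame) or
#' `right-anterior-superior` (RAS), which is converted to LPS by negating the
#' first two world axes. Tensor volumes (`kinds: 3D-symmetric-matrix`) have
#' their measurement frame applied on load, so in-memory tensors are always
#' expressed in world axes.
#'
#' @param path file path.
#' @param kind one of `"auto"`, `"scalar"`, `"label"`, `"mask"`, `"vector"`,
#'   `"tensor"`; `"auto"` infers from the header kinds and dimension.
#' @return An [scalar_image()]-family object.
#' @export
read_nrrd <- function(path, kind = "auto") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("read_nrrd: not an NRRD file: ", path)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("read_nrrd: unexpected end of header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr("^[^:]+:=?", line))
    key <- trimws(sub(":=?$", "", kv))
    val <- trimws(sub("^[^:]+:=?", "", line))
    hdr[[tolower(key)]] <- val
  }

  dim_n <- as.integer(hdr[["dimension"]])
  sizes <- as.integer(strsplit(hdr[["sizes"]], "[ \t]+")[[1]])
  type <- hdr[["type"]]
  enc <- tolower(hdr[["encoding"]])
  endian <- if (!is.null(hdr[["endian"]])) hdr[["endian"]] else "little"
  kinds <- if (!is.null(hdr[["kinds"]])) strsplit(hdr[["kinds"]], "[ \t]+")[[1]] else rep("domain", dim_n)

  space <- hdr[["space"]]
  ras <- FALSE
  if (!is.null(space)) {
    sp <- tolower(space)
    if (sp %in% c("right-anterior-superior", "ras")) ras <- TRUE
    else if (!sp %in% c("left-posterior-superior", "lps"))
      stop("read_nrrd: unsupported space '", space, "' (need LPS or RAS)")
  }

  parse_vecs <- function(s) {
    m <- regmatches(s, gregexpr("\\(([^)]*)\\)|none", s))[[1]]
    lapply(m, function(v) {
      if (v == "none") return(NULL)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
    })
  }

  dom <- which(kinds %in% c("domain", "space"))
  chan <- setdiff(seq_len(dim_n), dom)
  if (length(dom) != 3L) stop("read_nrrd: need exactly 3 domain axes")
  if (length(chan) > 1L) stop("read_nrrd: at most one non-domain axis supported")
  if (length(chan) == 1L && chan != 1L)
    stop("read_nrrd: non-domain axis must be the fastest axis")

  sd <- hdr[["space directions"]]
  if (is.null(sd)) {
    dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    dirs <- Filter(Negate(is.null), parse_vecs(sd))
  }
  if (length(dirs) != 3L) stop("read_nrrd: need 3 space direction vectors")
  D <- do.call(cbind, dirs)
  spacing <- sqrt(colSums(D^2))
  direction <- sweep(D, 2, spacing, `/`)
  origin <- c(0, 0, 0)
  if (!is.null(hdr[["space origin"]]))
    origin <- parse_vecs(hdr[["space origin"]])[[1]]

  if (ras) {  # RAS -> LPS: negate x and y world components
    flip <- diag(c(-1, -1, 1))
    direction <- flip %*% direction
    origin <- as.numeric(flip %*% origin)
  }

  nval <- prod(sizes)
  raw <- readBin(con, "raw", n = 1e9)
  if (enc == "gzip") raw <- memDecompress(raw, type = "gzip")
  else if (enc != "raw") stop("read_nrrd: unsupported encoding '", enc, "'")

  rtype <- switch(type,
    "double" = list(what = "double", size = 8),
    "float" = list(what = "double", size = 4),
    "int" = , "signed int" = , "int32" = list(what = "integer", size = 4),
    "short" = , "int16" = , "signed short" = list(what = "integer", size = 2),
    "uchar" = , "uint8" = , "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
    stop("read_nrrd: unsupported type '", type, "'"))
  vals <- readBin(raw, rtype$what, n = nval, size = rtype$size,
                  signed = if (rtype$size > 1) TRUE else isTRUE(rtype$signed),
                  endian = endian)
  if (length(vals) != nval) stop("read_nrrd: truncated data block")

  nchan <- if (length(chan) == 1L) sizes[1] else 0L
  gdims <- if (nchan) sizes[-1] else sizes
  grid <- image_grid(gdims, spacing, origin, direction)

  if (kind == "auto") {
    kind <- if (nchan == 0L) "scalar"
      else if (nchan == 3L) "vector"
      else if (nchan == 6L) "tensor"
      else stop("read_nrrd: cannot infer image kind for ", nchan, " channels")
    if (nchan == 6L && !any(kinds == "3D-symmetric-matrix"))
      stop("read_nrrd: 6-channel axis without kind '3D-symmetric-matrix'")
  }

  img <- switch(kind,
    scalar = scalar_image(vals, grid),
    label = label_image(vals, grid),
    mask = mask_image(vals != 0, grid),
    vector = {
      v <- vector_image(vals, grid)
      if (ras) {
        v$values[1, , , ] <- -v$values[1, , , ]
        v$values[2, , , ] <- -v$values[2, , , ]
      }
      v
    },
    tensor = {
      t6 <- matrix(vals, nrow = 6)
      Rm <- diag(3)
      if (!is.null(hdr[["measurement frame"]])) {
        mf <- Filter(Negate(is.null), parse_vecs(hdr[["measurement frame"]]))
        Rm <- do.call(cbind, mf)
      }
      if (ras) Rm <- diag(c(-1, -1, 1)) %*% Rm
      if (max(abs(Rm - diag(3))) > 1e-12) t6 <- rotate_sym6(t6, Rm)
      tensor_image(t6, grid, frame = diag(3))
    },
    stop("read_nrrd: unknown kind '", kind, "'"))
  img
}

#' Write an NRRD image
#'
#' Writes the image in the LPS frame with `space directions =
#' direction %*% diag(spacing)` and gzip- or raw-encoded little-endian data.
#' Tensors are written with an identity measurement frame (they are held in
#' world axes in memory).
#'
#' @param image an `ecog_image`.
#' @param path output path.
#' @param encoding `"gzip"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(image, path, encoding = "gzip") {
  stopifnot(inherits(image, "ecog_image"))
  g <- image$grid
  v <- image$values
  kind1 <- switch(class(image)[1],
    scalar_image = NULL, label_image = NULL, mask_image = NULL,
    vector_image = "vector", tensor_image = "3D-symmetric-matrix")
  type <- switch(class(image)[1],
    label_image = "int", mask_image = "uchar", "double")
  sizes <- if (is.null(kind1)) g$dims else dim(v)
  kinds <- c(kind1, rep("domain", 3))
  sd <- g$direction %*% diag(g$spacing)
  fmt_vec <- function(x) sprintf("(%.17g,%.17g,%.17g)", x[1], x[2], x[3])
  hdr <- c(
    "NRRD0005",
    "# generated by ecogfwd",
    paste0("type: ", type),
    paste0("dimension: ", length(sizes)),
    "space: left-posterior-superior",
    paste0("sizes: ", paste(sizes, collapse = " ")),
    paste0("space directions: ",
           paste(c(if (!is.null(kind1)) "none",
                   vapply(1:3, function(j) fmt_vec(sd[, j]), "")), collapse = " ")),
    paste0("kinds: ", paste(kinds, collapse = " ")),
    "endian: little",
    paste0("encoding: ", encoding),
    paste0("space origin: ", fmt_vec(g$origin)),
    if (inherits(image, "tensor_image"))
      "measurement frame: (1,0,0) (0,1,0) (0,0,1)",
    "")
  dat <- switch(type,
    double = writeBin(as.numeric(v), raw(), size = 8, endian = "little"),
    int = writeBin(as.integer(v), raw(), size = 4, endian = "little"),
    uchar = as.raw(as.integer(v)))
  if (encoding == "gzip") dat <- memCompress(dat, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(dat, con)
  invisible(path)
}
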