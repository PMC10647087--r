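#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Coordinates are taken verbatim as millimetres (the convention for
#' CT-derived surface files); pass `unit = "m"` for files written in
#' metres, which are scaled by 1000 on load. STL files may be binary or
#' ASCII (auto-detected); PLY support is ASCII format 1.0; OBJ reads `v`
#' and (triangular) `f` records. STL facet soup is welded by exact
#' vertex-coordinate match.
#'
#' @param path file path.
#' @param format `"stl"`, `"ply"` or `"obj"`; default inferred from the
#'   file extension.
#' @param unit `"mm"` (default, no rescale) or `"m"`.
#' @return A [shoulder_mesh()].
#' @export
read_mesh <- function(path, format = NULL, unit = c("mm", "m")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) abort(sprintf("cannot read mesh: no such file '%s'", path))
  if (file.size(path) == 0) abort(sprintf("cannot read mesh: '%s' is empty", path))
  format <- format %||% tolower(tools::file_ext(path))
  m <- switch(format,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path),
    abort(sprintf("unsupported mesh format '%s'", format))
  )
  if (unit == "m") m$vertices <- m$vertices * 1000
  shoulder_mesh(m$vertices, m$faces)
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' PLY output can carry one scalar per vertex as a float `quality`
#' property, the channel used to hand distance colour maps to downstream
#' viewers; the scalar round-trips through [read_mesh_scalar()].
#'
#' @param mesh a [shoulder_mesh()].
#' @param path output path.
#' @param format `"ply"`, `"stl"` (binary), `"stl_ascii"` or `"obj"`;
#'   default inferred from the extension (`.stl` writes binary).
#' @param per_vertex_scalar optional numeric vector, one value per vertex
#'   (PLY only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, per_vertex_scalar = NULL) {
  validate_mesh(mesh)
  format <- format %||% tolower(tools::file_ext(path))
  if (!is.null(per_vertex_scalar)) {
    if (length(per_vertex_scalar) != nrow(mesh$vertices)) {
      abort("per_vertex_scalar must have one value per vertex")
    }
    if (format != "ply") abort("per-vertex scalars are only supported for PLY output")
  }
  switch(format,
    ply = write_ply(mesh, path, per_vertex_scalar),
    stl = write_stl_binary(mesh, path),
    stl_ascii = write_stl_ascii(mesh, path),
    obj = write_obj(mesh, path),
    abort(sprintf("unsupported mesh format '%s'", format))
  )
  invisible(path)
}

#' Read the per-vertex scalar channel of a PLY file
#' @param path PLY file written by [write_mesh()] with a scalar.
#' @return Numeric vector (the `quality` property), or `NULL` if absent.
#' @export
read_mesh_scalar <- function(path) {
  read_ply(path)$scalar
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- STL --------------------------------------------------------------------

read_stl <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  if (sz >= 84) {
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!is.na(n) && n >= 0 && sz == 84 + 50 * n) {
      return(read_stl_binary_body(con, n))
    }
  }
  close(con)
  on.exit()
  read_stl_ascii(path)
}

read_stl_binary_body <- function(con, n) {
  raw <- readBin(con, "raw", 50 * n)
  idx <- rep(seq(0, by = 50, length.out = n), each = 48) + seq_len(48)
  fl <- readBin(raw[idx], "numeric", size = 4, n = 12 * n, endian = "little")
  m <- matrix(fl, ncol = 12, byrow = TRUE)  # normal xyz + 3 vertices
  V <- matrix(t(m[, 4:12, drop = FALSE]), ncol = 3, byrow = TRUE)
  weld_facets(V)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) abort(sprintf("'%s' parses as neither binary nor ASCII STL", path))
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  V <- do.call(rbind, nums)
  if (nrow(V) %% 3 != 0) abort("ASCII STL has a non-multiple-of-3 vertex count")
  weld_facets(V)
}

# Weld an unindexed facet soup (3 rows per triangle) into an indexed mesh.
weld_facets <- function(V) {
  key <- paste(V[, 1], V[, 2], V[, 3], sep = "_")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  list(vertices = V[uk, , drop = FALSE],
       faces = matrix(idx, ncol = 3, byrow = TRUE),
       scalar = NULL)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(f)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(n), con, size = 4, endian = "little")
  nrm <- facet_normals(v, f)
  block <- cbind(nrm, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                 v[f[, 3], , drop = FALSE])
  for (i in seq_len(n)) {
    writeBin(as.numeric(block[i, ]), con, size = 4, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  nrm <- facet_normals(v, f)
  out <- c("solid mesh",
           unlist(lapply(seq_len(nrow(f)), function(i) {
             c(sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
               "    outer loop",
               sprintf("      vertex %.9g %.9g %.9g",
                       v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
               "    endloop",
               "  endfacet")
           })),
           "endsolid mesh")
  writeLines(out, path)
}

facet_normals <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-30)
}

# -- PLY (ASCII 1.0) --------------------------------------------------------

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) abort(sprintf("'%s' is not a PLY file (no end_header)", path))
  head <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format\\s+ascii", head))) {
    abort("only ASCII PLY is supported")
  }
  nv <- as.integer(sub("^element\\s+vertex\\s+", "", grep("^element\\s+vertex", head, value = TRUE)[1]))
  nf <- as.integer(sub("^element\\s+face\\s+", "", grep("^element\\s+face", head, value = TRUE)[1]))
  # vertex property names, in order
  vstart <- grep("^element\\s+vertex", head)[1]
  vend <- grep("^element\\s", head)
  vend <- min(c(vend[vend > vstart], endh))
  props <- sub("^property\\s+\\S+\\s+", "",
               grep("^property\\s", head[vstart:(vend - 1)], value = TRUE))
  body <- lines[(endh + 1):length(lines)]
  vt <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  V <- matrix(as.numeric(unlist(vt)), nrow = nv, byrow = TRUE)
  ix <- match(c("x", "y", "z"), props)
  if (any(is.na(ix))) abort("PLY vertex element lacks x/y/z properties")
  scalar <- if ("quality" %in% props) V[, match("quality", props)] else NULL
  ft <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  Fm <- t(vapply(ft, function(x) {
    if (as.integer(x[1]) != 3L) abort("only triangular PLY faces are supported")
    as.integer(x[2:4])
  }, integer(3)))
  list(vertices = V[, ix, drop = FALSE], faces = Fm + 1L, scalar = scalar)
}

write_ply <- function(mesh, path, scalar = NULL) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  head <- c("ply", "format ascii 1.0",
            sprintf("element vertex %d", nrow(v)),
            "property float x", "property float y", "property float z",
            if (!is.null(scalar)) "property float quality",
            sprintf("element face %d", nrow(f)),
            "property list uchar int vertex_indices",
            "end_header")
  vb <- if (is.null(scalar)) {
    sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  } else {
    sprintf("%.9g %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3], scalar)
  }
  fb <- sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])
  writeLines(c(head, vb, fb), path)
}

# -- OBJ --------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl) || !length(fl)) abort(sprintf("'%s' has no OBJ geometry", path))
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(x) as.numeric(x[2:4])))
  Fm <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    ids <- as.integer(sub("/.*$", "", x[-1]))
    if (length(ids) != 3L) abort("only triangular OBJ faces are supported")
    ids
  }))
  list(vertices = V, faces = Fm, scalar = NULL)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
}
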