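#' Triangle surface mesh of a bone
#'
#' A `shoulder_mesh` is an indexed triangle surface in millimetres: an
#' `n x 3` matrix of vertex coordinates, an `m x 3` integer matrix of
#' 1-based vertex indices, and an optional set of named face labels
#' (disjoint subsets of faces, e.g. `"acromion"`) used to restrict
#' distance queries to an anatomical subregion.
#'
#' Validation enforces: all coordinates finite, all face indices within
#' range, no degenerate faces (triangle area must exceed `1e-9` mm^2), and
#' pairwise-disjoint label sets.
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param face_labels optional named list of integer face-index vectors.
#' @return An object of class `shoulder_mesh`.
#' @examples
#' m <- shoulder_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                    matrix(c(1L, 2L, 3L), 1))
#' mesh_area(m)
#' @export
shoulder_mesh <- function(vertices, faces, face_labels = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  m <- structure(list(vertices = vertices, faces = faces,
                      face_labels = face_labels),
                 class = "shoulder_mesh")
  validate_mesh(m)
}

validate_mesh <- function(m) {
  v <- m$vertices
  f <- m$faces
  if (!is.matrix(v) || ncol(v) != 3L) abort("vertices must be an n x 3 matrix")
  if (!is.matrix(f) || ncol(f) != 3L) abort("faces must be an m x 3 matrix")
  if (nrow(f) < 1L) abort("mesh has no faces")
  if (!all(is.finite(v))) abort("non-finite vertex coordinates")
  if (min(f) < 1L || max(f) > nrow(v)) abort("face index out of range")
  a <- tri_areas(v, f)
  bad <- which(a <= 1e-9)
  if (length(bad)) {
    abort(sprintf("degenerate face(s) with area <= 1e-9 mm^2: first offender face %d",
                  bad[1]))
  }
  if (!is.null(m$face_labels)) {
    lab <- m$face_labels
    if (is.null(names(lab)) || any(!nzchar(names(lab)))) {
      abort("face_labels must be a named list")
    }
    all_idx <- unlist(lab, use.names = FALSE)
    if (length(all_idx) && (min(all_idx) < 1L || max(all_idx) > nrow(f))) {
      abort("face label index out of range")
    }
    if (anyDuplicated(all_idx)) abort("face label sets must be disjoint")
  }
  m
}

tri_areas <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.shoulder_mesh <- function(x, ...) {
  lab <- if (is.null(x$face_labels)) "none" else
    paste(sprintf("%s (%d)", names(x$face_labels),
                  lengths(x$face_labels)), collapse = ", ")
  cat(sprintf("<shoulder_mesh> %d vertices, %d faces; labels: %s\n",
              nrow(x$vertices), nrow(x$faces), lab))
  invisible(x)
}

#' Total surface area of a mesh
#' @param mesh a [shoulder_mesh()].
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) sum(tri_areas(mesh$vertices, mesh$faces))

#' Restrict a mesh to one face label
#'
#' Returns the sub-mesh consisting of the faces carrying `label`
#' (vertices are kept as-is; unreferenced vertices are retained so vertex
#' indexing stays stable).
#'
#' @param mesh a [shoulder_mesh()].
#' @param label label name; must exist and be non-empty.
#' @return A `shoulder_mesh` with only the labelled faces.
#' @export
mesh_subset <- function(mesh, label) {
  idx <- mesh$face_labels[[label]]
  if (is.null(idx) || length(idx) == 0L) {
    abort(sprintf("face label '%s' missing or empty", label))
  }
  shoulder_mesh(mesh$vertices, mesh$faces[idx, , drop = FALSE])
}

#' Merge meshes, concatenating vertices, faces and labels
#'
#' @param ... `shoulder_mesh` objects. Labels are offset to the merged
#'   face numbering; identically named labels are unioned.
#' @return A single `shoulder_mesh`.
#' @export
mesh_merge <- function(...) {
  parts <- list(...)
  voff <- 0L
  foff <- 0L
  V <- list(); F <- list(); L <- list()
  for (p in parts) {
    V[[length(V) + 1L]] <- p$vertices
    F[[length(F) + 1L]] <- p$faces + voff
    if (!is.null(p$face_labels)) {
      for (nm in names(p$face_labels)) {
        L[[nm]] <- c(L[[nm]], p$face_labels[[nm]] + foff)
      }
    }
    voff <- voff + nrow(p$vertices)
    foff <- foff + nrow(p$faces)
  }
  shoulder_mesh(do.call(rbind, V), do.call(rbind, F),
                face_labels = if (length(L)) L else NULL)
}

# ---------------------------------------------------------------------------
# Rigid transforms

#' Rigid transform (rotation + translation)
#'
#' Carrier for the per-step humerus rotation: a proper rotation matrix
#' (orthonormal, det +1) and a translation vector in mm.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric vector, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L) {
    abort("rotation must be 3x3 and translation length 3")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 || det(rotation) < 0) {
    abort("rotation must be orthonormal with det +1")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Rotation about an axis through a point
#'
#' @param axis length-3 direction (normalised internally).
#' @param angle_deg rotation angle, degrees (right-hand rule).
#' @param center point the axis passes through, mm.
#' @return A [rigid_transform()].
#' @export
rotation_about_axis <- function(axis, angle_deg, center = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  # re-orthonormalise against accumulated rounding
  s <- svd(R)
  R <- s$u %*% t(s$v)
  rigid_transform(R, as.numeric(center - R %*% center))
}

#' Compose two rigid transforms (apply `b` first, then `a`)
#' @param a,b [rigid_transform()] objects.
#' @return The composite [rigid_transform()].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Apply a rigid transform to a mesh or point set
#'
#' Vertices map to `R v + t`; pairwise distances are preserved to
#' floating-point accuracy.
#'
#' @param x a [shoulder_mesh()] or an n x 3 point matrix.
#' @param transform a [rigid_transform()].
#' @return Object of the same type as `x`.
#' @export
apply_transform <- function(x, transform) {
  if (!inherits(transform, "rigid_transform")) {
    transform <- rigid_transform(transform$rotation, transform$translation)
  }
  tp <- function(P) {
    sweep(P %*% t(transform$rotation), 2, transform$translation, "+")
  }
  if (inherits(x, "shoulder_mesh")) {
    shoulder_mesh(tp(x$vertices), x$faces, x$face_labels)
  } else if (is.matrix(x)) {
    tp(x)
  } else if (is.numeric(x) && length(x) == 3L) {
    as.numeric(transform$rotation %*% x) + transform$translation
  } else {
    abort("cannot transform object of this type")
  }
}
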