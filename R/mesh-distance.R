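#' Distance from a point to a triangle
#'
#' Exact closed-form closest point on a triangle (vertex / edge / face
#' region decomposition), with the barycentric coordinates of the contact.
#'
#' @param p length-3 point, mm.
#' @param tri 3 x 3 matrix, one triangle vertex per row.
#' @return A list with `distance` (mm), `closest` (point on the triangle)
#'   and `barycentric` (coordinates of `closest`, non-negative, summing
#'   to 1).
#' @examples
#' tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' point_triangle_distance(c(1, 1, 0), tri)$distance  # 1/sqrt(2)
#' @export
point_triangle_distance <- function(p, tri) {
  tri <- as.matrix(tri)
  if (!all(dim(tri) == c(3L, 3L))) abort("tri must be a 3 x 3 matrix")
  a <- 0.5 * sqrt(sum(vcross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])^2))
  if (a <= 1e-9) abort("degenerate triangle (area <= 1e-9 mm^2)")
  cpp_point_tri(as.numeric(p), tri)
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

mesh_pair_inputs <- function(a, b, restrict_a) {
  if (!is.null(restrict_a)) a <- mesh_subset(a, restrict_a)
  list(VA = a$vertices, FA = a$faces - 1L, VB = b$vertices, FB = b$faces - 1L)
}

#' Minimum distance between two meshes (exhaustive scan)
#'
#' Exact minimum over all triangle pairs, by the closed-form
#' triangle-triangle distance. Interpenetrating or touching surfaces give
#' distance 0 (unsigned; no penetration depth is computed). Quadratic in
#' the number of faces -- this is the reference oracle; use
#' [min_distance_fast()] for production queries.
#'
#' @param a,b [shoulder_mesh()] objects.
#' @param restrict_a optional face-label name of `a`; the query then only
#'   considers that subregion (e.g. `"acromion"`).
#' @return A list with `distance` (mm), `point_a`, `point_b` (closest
#'   points, mm) and `face_a`, `face_b` (1-based face indices; `face_a`
#'   refers to the restricted sub-mesh when `restrict_a` is given).
#' @export
min_distance_brute <- function(a, b, restrict_a = NULL) {
  x <- mesh_pair_inputs(a, b, restrict_a)
  cpp_mesh_distance_brute(x$VA, x$FA, x$VB, x$FB)
}

#' Minimum distance between two meshes (BVH accelerated)
#'
#' Identical contract and results as [min_distance_brute()]: a dual
#' bounding-volume-hierarchy traversal with branch-and-bound pruning on
#' box distances, with the same closed-form triangle-triangle primitive at
#' the leaves, so the minimum is exact (not approximate).
#'
#' @inheritParams min_distance_brute
#' @return Same structure as [min_distance_brute()].
#' @export
min_distance_fast <- function(a, b, restrict_a = NULL) {
  x <- mesh_pair_inputs(a, b, restrict_a)
  cpp_mesh_distance_bvh(x$VA, x$FA, x$VB, x$FB)
}

#' Per-vertex distance field
#'
#' Distance from every vertex of `a` to the surface of `b` -- the quantity
#' colour-mapped on the scapula to visualise where the subacromial space
#' narrows (minimum distance rendered red).
#'
#' @param a,b [shoulder_mesh()] objects.
#' @return Numeric vector, one distance (mm) per vertex of `a`.
#' @export
per_vertex_distance_field <- function(a, b) {
  cpp_point_mesh(a$vertices, b$vertices, b$faces - 1L)$distance
}
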