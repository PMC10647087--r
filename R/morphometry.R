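#' Critical shoulder angle (CSA) from a 3D shoulder model
#'
#' The CSA is the angle, at the inferior glenoid rim IG, between the
#' glenoid line IG to SG and the line from IG to the most lateral point of
#' the acromion, measured in the corrected coronal plane. All points
#' (IG, SG and every vertex of the `"acromion"`-labelled region) are first
#' projected orthogonally onto the [measurement_plane()]; the lateral
#' acromion point is the projected vertex maximising the signed lateral
#' coordinate (the in-plane direction perpendicular to IG-SG, positive on
#' the acromion side), ties broken by the most inferior candidate.
#'
#' @param model a [shoulder_model()].
#' @return One-row [tibble::tibble] with `measure`, `value_deg`, the
#'   selected vertex (`vertex_x/y/z`, on the unprojected mesh) and the
#'   plane definition, class `angle_measurement`.
#' @export
measure_csa <- function(model) {
  lm <- model$landmarks
  plane <- measurement_plane(model$scapula_frame, lm)
  acr_faces <- model$scapula$face_labels$acromion
  if (is.null(acr_faces) || !length(acr_faces)) abort("no 'acromion' face label")
  vidx <- sort(unique(as.vector(model$scapula$faces[acr_faces, , drop = FALSE])))
  V <- model$scapula$vertices[vidx, , drop = FALSE]
  ig <- project_to_plane(lm$IG, plane)
  sg <- project_to_plane(lm$SG, plane)
  P <- project_to_plane(V, plane)
  u <- unit(sg - ig)                         # superior, along the glenoid line
  lat <- vcross(plane$normal, u)
  lat <- unit(lat - sum(lat * u) * u)
  centroid <- colMeans(P)
  if (sum((centroid - ig) * lat) < 0) lat <- -lat  # positive on the acromion side
  rel <- sweep(P, 2, ig)
  lcoord <- as.numeric(rel %*% lat)
  scoord <- as.numeric(rel %*% u)
  top <- which(lcoord >= max(lcoord) - 1e-9)
  pick <- top[which.min(scoord[top])]        # most inferior among ties
  w <- P[pick, ] - ig
  value <- angle_between(sg - ig, w)
  new_angle_measurement("csa", value, V[pick, ], plane)
}

#' Greater tuberosity angle (GTA) from a 3D shoulder model
#'
#' The GTA is the angle, at the humeral head centre, between the proximal
#' direction of the diaphyseal axis (translated to the joint centre) and
#' the line to the most superolateral point of the greater tuberosity,
#' in the corrected coronal plane. Candidate vertices are humeral
#' vertices within `1.4 x` the fitted head radius of the joint centre,
#' on the lateral side, whose projected polar angle from the proximal ray
#' lies in (10, 90) degrees; the tuberosity point is the candidate whose
#' planar distance from the projected centre is largest. A purely
#' spherical head makes all candidates equidistant: a degenerate-tie
#' warning is issued and the smallest-angle candidate returned.
#'
#' @param model a [shoulder_model()].
#' @return One-row tibble as in [measure_csa()].
#' @export
measure_gta <- function(model) {
  plane <- measurement_plane(model$scapula_frame, model$landmarks)
  C <- project_to_plane(model$gh_center, plane)
  prox <- -model$shaft_axis$direction
  prox <- prox - sum(prox * plane$normal) * plane$normal
  if (sqrt(sum(prox^2)) < 1e-9) abort("shaft axis is normal to the measurement plane")
  prox <- unit(prox)
  # lateral in-plane direction: from the glenoid towards the joint centre
  glen <- project_to_plane((model$landmarks$SG + model$landmarks$IG) / 2, plane)
  lat0 <- C - glen
  lat <- lat0 - sum(lat0 * prox) * prox
  if (sqrt(sum(lat^2)) < 1e-9) abort("degenerate lateral direction")
  lat <- unit(lat)
  V <- model$humerus$vertices
  r3 <- sqrt(rowSums(sweep(V, 2, model$gh_center)^2))
  P <- project_to_plane(V, plane)
  rel <- sweep(P, 2, C)
  a_prox <- as.numeric(rel %*% prox)
  a_lat <- as.numeric(rel %*% lat)
  phi <- atan2(a_lat, a_prox) * 180 / pi
  cand <- which(r3 <= 1.4 * model$gh_radius & phi > 10 & phi < 90)
  if (!length(cand)) abort("no tuberosity prominence found")
  rad <- sqrt(a_prox[cand]^2 + a_lat[cand]^2)
  near <- which(rad >= max(rad) - 0.05)
  if (diff(range(phi[cand][near])) > 10) {
    warn("tuberosity selection is degenerate (near-spherical head); returning the smallest-angle candidate")
    pick <- cand[near[which.min(phi[cand][near])]]
  } else {
    top <- which(rad >= max(rad) - 1e-9)
    pick <- cand[top[which.min(phi[cand][top])]]
  }
  new_angle_measurement("gta", phi[pick], V[pick, ], plane)
}

angle_between <- function(a, b) {
  acos(pmin(1, pmax(-1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

new_angle_measurement <- function(name, value, vertex, plane) {
  out <- tibble(measure = name, value_deg = as.numeric(value),
                vertex_x = vertex[1], vertex_y = vertex[2], vertex_z = vertex[3],
                plane_point_x = plane$point[1], plane_point_y = plane$point[2],
                plane_point_z = plane$point[3],
                plane_normal_x = plane$normal[1], plane_normal_y = plane$normal[2],
                plane_normal_z = plane$normal[3])
  class(out) <- c("angle_measurement", class(out))
  out
}

#' Measure CSA, GTA and their sum
#'
#' @param model a [shoulder_model()].
#' @return One-row tibble with `csa_deg`, `gta_deg`, `sum_deg`.
#' @export
measure_angles <- function(model) {
  csa <- measure_csa(model)
  gta <- measure_gta(model)
  tibble(csa_deg = csa$value_deg, gta_deg = gta$value_deg,
         sum_deg = csa$value_deg + gta$value_deg)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation, the standard variant for method-reproducibility claims.
#' From the two-way ANOVA decomposition with n subjects (rows) and k
#' raters/repeats (columns):
#'
#'   ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))
#'
#' where MSR, MSC, MSE are the subject, rater and residual mean squares.
#' Unlike the consistency variant, a constant offset between raters
#' lowers ICC(2,1) (absolute agreement).
#'
#' @param measurements numeric matrix, subjects x raters (>= 3 rows,
#'   >= 2 columns, no missing cells).
#' @return ICC value in `[-1, 1]`.
#' @examples
#' x <- matrix(rnorm(20), 10, 2)
#' repeatability_icc(cbind(x[, 1], x[, 1]))  # identical raters: 1
#' @export
repeatability_icc <- function(measurements) {
  M <- as.matrix(measurements)
  if (ncol(M) < 2L) abort("need at least 2 raters/repeats (columns)")
  if (nrow(M) < 3L) abort("need at least 3 subjects (rows)")
  if (anyNA(M)) abort("missing cells are not supported")
  if (max(M) - min(M) < 1e-12) abort("constant measurements: ICC undefined")
  n <- nrow(M); k <- ncol(M)
  grand <- mean(M)
  ssr <- k * sum((rowMeans(M) - grand)^2)
  ssc <- n * sum((colMeans(M) - grand)^2)
  sst <- sum((M - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
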