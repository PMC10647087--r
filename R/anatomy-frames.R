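#' Least-squares sphere fit
#'
#' Fits a sphere to a point cloud: a linear algebraic fit (Coope's
#' formulation, `|x|^2 = 2 c.x + (r^2 - |c|^2)`) followed by geometric
#' Levenberg-Marquardt refinement of the orthogonal residuals
#' `|x_i - c| - r`. Used for the glenohumeral joint centre from the
#' humeral-head surface.
#'
#' @param points n x 3 matrix of points, mm; at least 4, not coplanar.
#' @return List with `center` (mm), `radius` (mm) and `rms_residual`
#'   (root-mean-square orthogonal residual, mm).
#' @examples
#' pts <- rbind(c(24, 0, 0), c(-24, 0, 0), c(0, 24, 0),
#'              c(0, -24, 0), c(0, 0, 24), c(0, 0, -24))
#' fit_sphere(pts)  # center (0,0,0), radius 24
#' @export
fit_sphere <- function(points) {
  P <- as.matrix(points)
  if (nrow(P) < 4L) abort("sphere fit needs at least 4 points")
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr), nu = 0, nv = 0)$d
  if (sv[3] < 1e-8 * max(sv[1], 1e-12)) abort("sphere fit needs non-coplanar points")
  # algebraic fit
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  sol <- qr.solve(A, b)
  c0 <- sol[1:3]
  r0 <- sqrt(max(sol[4] + sum(c0^2), 1e-12))
  # geometric refinement
  resfun <- function(par) sqrt(rowSums(sweep(P, 2, par[1:3])^2)) - par[4]
  fit <- minpack.lm::nls.lm(par = c(c0, r0), fn = resfun,
                            control = minpack.lm::nls.lm.control(maxiter = 100))
  par <- fit$par
  res <- resfun(par)
  list(center = unname(par[1:3]), radius = unname(par[4]),
       rms_residual = sqrt(mean(res^2)))
}

#' Select humeral-head surface points for the joint-centre fit
#'
#' Orients the humerus along its principal axis, keeps the vertices of the
#' proximal third (the head end, recognised as the end with the larger
#' radial spread about the axis), then removes tuberosity/shaft outliers
#' in a single residual-trimming pass: points whose orthogonal sphere-fit
#' residual exceeds twice the median residual are dropped. A mesh with no
#' clear elongation (principal extent ratio below 1.5, e.g. an isolated
#' head sphere) is used in full.
#'
#' @param humerus a [shoulder_mesh()].
#' @param hint_region optional face-label name; its vertices are used
#'   instead of the proximal-third heuristic (trimming still applies).
#' @return n x 3 matrix of selected points.
#' @export
select_head_points <- function(humerus, hint_region = NULL) {
  V <- humerus$vertices
  if (!is.null(hint_region)) {
    sub <- mesh_subset(humerus, hint_region)
    sel <- V[sort(unique(as.vector(sub$faces))), , drop = FALSE]
  } else {
    ctr <- colMeans(V)
    pc <- prcomp(V, center = TRUE, scale. = FALSE)
    t1 <- pc$x[, 1]
    ext <- apply(pc$x, 2, function(s) diff(range(s)))
    if (ext[1] / max(ext[3], 1e-9) < 1.5) {
      sel <- V
    } else {
      radial <- sqrt(pc$x[, 2]^2 + pc$x[, 3]^2)
      third <- diff(range(t1)) / 3
      top <- t1 >= max(t1) - third
      bottom <- t1 <= min(t1) + third
      head_is_top <- mean(radial[top]) >= mean(radial[bottom])
      sel <- V[if (head_is_top) top else bottom, , drop = FALSE]
    }
  }
  if (nrow(sel) < 4L) abort("fewer than 4 candidate head points")
  fit0 <- fit_sphere(sel)
  res <- abs(sqrt(rowSums(sweep(sel, 2, fit0$center)^2)) - fit0$radius)
  keep <- res <= max(2 * median(res), 1e-6)
  sel <- sel[keep, , drop = FALSE]
  if (nrow(sel) < 100L) {
    warn(sprintf("only %d head points selected; sphere fit may be unstable", nrow(sel)))
  }
  if (nrow(sel) < 4L) abort("fewer than 4 head points after residual trimming")
  fit1 <- fit_sphere(sel)
  if (fit1$rms_residual > 0.02 * fit1$radius) {
    warn(sprintf(paste0("head sphere fit looks degenerate ",
                        "(rms residual %.2f mm for radius %.1f mm)"),
                 fit1$rms_residual, fit1$radius))
  }
  sel
}

# ---------------------------------------------------------------------------
# Frames

new_frame <- function(origin, x, y, z, option = "isb") {
  fr <- structure(list(origin = as.numeric(origin), x = as.numeric(x),
                       y = as.numeric(y), z = as.numeric(z), option = option),
                  class = "bone_frame")
  M <- cbind(fr$x, fr$y, fr$z)
  if (max(abs(crossprod(M) - diag(3))) > 1e-9) abort("frame axes not orthonormal")
  if (abs(sum(fr$x * vcross(fr$y, fr$z)) - 1) > 1e-9) abort("frame not right-handed")
  fr
}

#' @export
print.bone_frame <- function(x, ...) {
  cat(sprintf("<bone_frame> (%s) origin [%.2f %.2f %.2f]\n",
              x$option, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

unit <- function(v) v / sqrt(sum(v^2))

#' Scapular bone coordinate system (ISB convention)
#'
#' Wu et al. scapula convention: origin at the acromial angle AA; z along
#' the scapular spine from the trigonum spinae TS to AA; x normal to the
#' scapular plane (through AI, AA, TS); y completes the right-handed
#' frame. The sign of the plane normal is fixed deterministically from
#' the glenoid landmarks: it is chosen so that the inferior-to-superior
#' glenoid direction IG to SG has a positive y-component in the resulting
#' frame.
#'
#' @param landmarks named list of 3D points (mm) with at least AA, TS,
#'   AI, SG, IG; see [read_landmarks()].
#' @return A `bone_frame`.
#' @export
scapula_frame_isb <- function(landmarks) {
  lm <- validate_landmarks(landmarks, require = c("AA", "TS", "AI", "SG", "IG"))
  z <- lm$AA - lm$TS
  if (sqrt(sum(z^2)) < 1e-9) abort("AA and TS coincide")
  z <- unit(z)
  n <- vcross(lm$AA - lm$AI, lm$TS - lm$AI)
  if (sqrt(sum(n^2)) < 2) abort("scapular landmarks are collinear (plane area <= 1 mm^2)")
  x <- unit(n)
  y <- vcross(z, x)
  if (sum((lm$SG - lm$IG) * y) < 0) {
    x <- -x
    y <- vcross(z, x)
  }
  new_frame(lm$AA, x, y, z, option = "isb_scapula")
}

#' Humeral bone coordinate system
#'
#' With both epicondyle landmarks (EL lateral, EM medial) present the ISB
#' humerus frame is built: origin at the glenohumeral centre, y from the
#' epicondyle midpoint towards the joint centre, x normal to the plane of
#' EL, EM and the joint centre (pointing the same way as the scapular
#' anterior axis). Shoulder CT rarely covers the elbow, so without
#' epicondyles a documented fallback is used: y is the reversed
#' diaphyseal direction (pointing proximally) and x is the scapular
#' frame's anterior axis projected orthogonal to y. The `option` field
#' records which construction produced the frame.
#'
#' @param gh_center glenohumeral joint centre (mm).
#' @param landmarks named landmark list (may contain EL, EM).
#' @param shaft_axis list with `point` and `direction` (pointing distal),
#'   from [diaphyseal_axis()]; required when epicondyles are absent.
#' @param scapula_frame the scapular `bone_frame`; required for the
#'   fallback construction.
#' @return A `bone_frame` with option `"isb_humerus"` or
#'   `"shaft_fallback"`.
#' @export
humerus_frame <- function(gh_center, landmarks = NULL, shaft_axis = NULL,
                          scapula_frame = NULL) {
  has_epi <- !is.null(landmarks) && !is.null(landmarks$EL) && !is.null(landmarks$EM)
  if (has_epi) {
    mid <- (landmarks$EL + landmarks$EM) / 2
    y <- unit(gh_center - mid)
    x <- unit(vcross(y, landmarks$EL - landmarks$EM))
    if (!is.null(scapula_frame) && sum(x * scapula_frame$x) < 0) {
      # keep the anterior sense consistent with the scapula
      x <- -x
    }
    z <- vcross(x, y)
    new_frame(gh_center, x, y, z, option = "isb_humerus")
  } else {
    if (is.null(shaft_axis)) abort("need either epicondyles (EL, EM) or a shaft_axis")
    if (is.null(scapula_frame)) abort("fallback humerus frame needs the scapula frame")
    y <- unit(-shaft_axis$direction)           # proximal
    x <- scapula_frame$x - sum(scapula_frame$x * y) * y
    if (sqrt(sum(x^2)) < 1e-9) abort("scapular anterior axis parallel to shaft")
    x <- unit(x)
    z <- vcross(x, y)
    new_frame(gh_center, x, y, z, option = "shaft_fallback")
  }
}

#' Diaphyseal (shaft) axis of the humerus
#'
#' Fits a line through the centroids of equally spaced cross-sections of
#' the distal half of the bone's principal-axis extent. The direction
#' points distally (away from the head). At least roughly 40 mm of shaft
#' must be present.
#'
#' @param humerus a [shoulder_mesh()].
#' @param n_sections number of cross-section slabs (at least 10).
#' @return List with `point` (on the axis), `direction` (unit, distal),
#'   and `rms` (centroid-to-line rms, mm).
#' @export
diaphyseal_axis <- function(humerus, n_sections = 12L) {
  n_sections <- max(10L, as.integer(n_sections))
  V <- humerus$vertices
  pc <- prcomp(V, center = TRUE, scale. = FALSE)
  t1 <- pc$x[, 1]
  if (diff(range(t1)) < 80) abort("humerus too short: need >= 40 mm of shaft")
  radial <- sqrt(pc$x[, 2]^2 + pc$x[, 3]^2)
  third <- diff(range(t1)) / 3
  head_is_top <- mean(radial[t1 >= max(t1) - third]) >=
    mean(radial[t1 <= min(t1) + third])
  # distal half of the extent = opposite end from the head; the tolerance
  # keeps a cross-section ring that sits exactly on the cutoff intact
  ext <- diff(range(t1))
  tol <- 1e-9 * ext
  half <- if (head_is_top) t1 <= min(t1) + ext / 2 + tol else
    t1 >= max(t1) - ext / 2 - tol
  td <- t1[half]
  Vd <- V[half, , drop = FALSE]
  br <- seq(min(td), max(td), length.out = n_sections + 1)
  bin <- cut(td, br, include.lowest = TRUE)
  cent <- do.call(rbind, lapply(split(seq_along(td), bin), function(ix) {
    if (length(ix) >= 3) colMeans(Vd[ix, , drop = FALSE]) else NULL
  }))
  if (is.null(cent) || nrow(cent) < 10L) abort("too few usable shaft cross-sections")
  mu <- colMeans(cent)
  sv <- svd(sweep(cent, 2, mu))
  dir <- sv$v[, 1]
  # distal sense: towards the shaft end of the principal axis
  distal_ref <- pc$rotation[, 1] * (if (head_is_top) -1 else 1)
  if (sum(dir * distal_ref) < 0) dir <- -dir
  proj <- sweep(cent, 2, mu) %*% dir
  perp <- sweep(cent, 2, mu) - proj %*% t(dir)
  list(point = unname(mu), direction = unname(unit(dir)),
       rms = sqrt(mean(rowSums(perp^2))))
}

#' Corrected-coronal measurement plane
#'
#' The scapula-coronal plane in which CSA and GTA are measured: normal
#' along the scapular frame's anterior axis, passing through the inferior
#' glenoid rim landmark IG. All angle measurements are taken after
#' orthogonal projection onto this plane.
#'
#' @param scapula_frame scapular `bone_frame`.
#' @param landmarks landmark list containing IG.
#' @return List with `point` and unit `normal`.
#' @export
measurement_plane <- function(scapula_frame, landmarks) {
  lm <- validate_landmarks(landmarks, require = "IG")
  list(point = lm$IG, normal = unit(scapula_frame$x))
}

#' Orthogonal projection onto a plane
#' @param points n x 3 matrix or length-3 vector.
#' @param plane list with `point` and `normal` (see [measurement_plane()]).
#' @return Projected points, same shape as the input.
#' @export
project_to_plane <- function(points, plane) {
  n <- unit(plane$normal)
  if (is.matrix(points)) {
    d <- as.numeric(sweep(points, 2, plane$point) %*% n)
    points - outer(d, n)
  } else {
    points - sum((points - plane$point) * n) * n
  }
}

# ---------------------------------------------------------------------------
# Landmarks

#' Read / write anatomical landmarks (JSON)
#'
#' Landmark files are JSON objects mapping names to `[x, y, z]`
#' millimetre coordinates in the same frame as the meshes. Scapular
#' measurements require AA (angulus acromialis), TS (trigonum spinae),
#' AI (angulus inferior), SG and IG (superior/inferior glenoid rim);
#' EL/EM (humeral epicondyles) and GT_APEX are optional.
#'
#' @param path JSON file path.
#' @return Named list of length-3 numeric vectors.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) abort(sprintf("landmarks file not found: '%s'", path))
  lm <- jsonlite::read_json(path, simplifyVector = TRUE)
  lm <- lapply(lm, as.numeric)
  validate_landmarks(lm)
}

#' @rdname read_landmarks
#' @param landmarks named list of length-3 numeric vectors.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(lapply(landmarks, unname), path, digits = NA)
  invisible(path)
}

validate_landmarks <- function(landmarks, require = NULL) {
  if (is.null(names(landmarks)) || anyDuplicated(names(landmarks))) {
    abort("landmarks must have unique names")
  }
  bad <- names(landmarks)[vapply(landmarks, function(p) {
    length(p) != 3L || !all(is.finite(p))
  }, logical(1))]
  if (length(bad)) abort(sprintf("landmark '%s' is not a finite 3D point", bad[1]))
  miss <- setdiff(require, names(landmarks))
  if (length(miss)) {
    abort(sprintf("missing required landmark(s): %s", paste(miss, collapse = ", ")))
  }
  if (all(c("AA", "TS", "AI") %in% names(landmarks))) {
    a2 <- sqrt(sum(vcross(landmarks$AA - landmarks$AI,
                          landmarks$TS - landmarks$AI)^2)) / 2
    if (a2 <= 1) abort("AA, TS, AI are (near-)collinear: triangle area <= 1 mm^2")
  }
  landmarks
}
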