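#' Assemble a patient-specific shoulder model
#'
#' Derives the patient-specific biomechanical parameters from the two bone
#' meshes and the landmark set: glenohumeral joint centre and radius by
#' sphere fitting of the humeral head ([select_head_points()] +
#' [fit_sphere()]), diaphyseal shaft axis, the ISB scapular frame and the
#' humeral frame (epicondyle-based when EL/EM are present, shaft-axis
#' fallback otherwise). The scapula must carry an `"acromion"` face label
#' -- acromio-humeral distance queries are restricted to it.
#'
#' @param scapula scapular [shoulder_mesh()] with an `"acromion"` label.
#' @param humerus humeral [shoulder_mesh()].
#' @param landmarks named landmark list (see [read_landmarks()]).
#' @param head_region optional face label of `humerus` to restrict the
#'   head-point selection.
#' @return An object of class `shoulder_model`.
#' @export
shoulder_model <- function(scapula, humerus, landmarks, head_region = NULL) {
  validate_mesh(scapula)
  validate_mesh(humerus)
  if (is.null(scapula$face_labels$acromion) ||
      length(scapula$face_labels$acromion) == 0L) {
    abort("scapula must carry a non-empty 'acromion' face label")
  }
  landmarks <- validate_landmarks(landmarks,
                                  require = c("AA", "TS", "AI", "SG", "IG"))
  pts <- select_head_points(humerus, hint_region = head_region)
  fit <- fit_sphere(pts)
  if (fit$radius <= 0) abort("non-positive fitted head radius")
  bb <- apply(humerus$vertices, 2, range)
  if (any(fit$center < bb[1, ] - fit$radius) ||
      any(fit$center > bb[2, ] + fit$radius)) {
    abort("fitted glenohumeral centre lies far outside the humerus")
  }
  shaft <- diaphyseal_axis(humerus)
  sframe <- scapula_frame_isb(landmarks)
  hframe <- humerus_frame(fit$center, landmarks, shaft_axis = shaft,
                          scapula_frame = sframe)
  structure(list(
    scapula = scapula,
    humerus = humerus,
    landmarks = landmarks,
    gh_center = fit$center,
    gh_radius = fit$radius,
    gh_rms = fit$rms_residual,
    shaft_axis = shaft,
    scapula_frame = sframe,
    humerus_frame = hframe
  ), class = "shoulder_model")
}

#' @export
print.shoulder_model <- function(x, ...) {
  cat(sprintf(paste0("<shoulder_model>\n",
                     "  scapula: %d faces (%d acromion), humerus: %d faces\n",
                     "  gh centre [%.2f %.2f %.2f] mm, radius %.2f mm (rms %.3f)\n",
                     "  humerus frame: %s\n"),
              nrow(x$scapula$faces), length(x$scapula$face_labels$acromion),
              nrow(x$humerus$faces),
              x$gh_center[1], x$gh_center[2], x$gh_center[3],
              x$gh_radius, x$gh_rms, x$humerus_frame$option))
  invisible(x)
}

#' Apply a rigid transform to a whole shoulder model
#'
#' Transforms both meshes and the landmarks and re-derives the joint
#' parameters, so equivariance of every measurement under rigid motion can
#' be exercised directly.
#'
#' @param model a [shoulder_model()].
#' @param transform a [rigid_transform()].
#' @return A new `shoulder_model`.
#' @export
transform_model <- function(model, transform) {
  shoulder_model(apply_transform(model$scapula, transform),
                 apply_transform(model$humerus, transform),
                 lapply(model$landmarks, apply_transform, transform = transform))
}
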