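#' Simulation settings for the scaption sweep
#'
#' Defaults follow the dynamic-impingement protocol: elevation from 0 to
#' 120 degrees in the scapular plane, 1 degree per time step, subacromial
#' impingement flagged when the minimum acromio-humeral distance falls
#' below 6 mm (the conventional soft-tissue thickness allowance).
#'
#' @param theta_max maximum elevation angle, degrees.
#' @param step angle increment per time step, degrees (0 < step <= theta_max).
#' @param threshold impingement threshold on the AHD, mm (> 0).
#' @param vertex_field_at optional vector of angles (degrees) at which a
#'   per-vertex distance field over the full scapula is recorded for
#'   colour-map export.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(theta_max = 120, step = 1, threshold = 6,
                              vertex_field_at = NULL) {
  if (!(step > 0 && step <= theta_max)) abort("need 0 < step <= theta_max")
  if (threshold <= 0) abort("threshold must be positive")
  structure(list(theta_max = theta_max, step = step, threshold = threshold,
                 vertex_field_at = vertex_field_at),
            class = "simulation_config")
}

#' Scaption rotation axis
#'
#' Pure scaption is a rotation of the humerus about the scapular-plane
#' normal through the glenohumeral centre. The sign of the axis is chosen
#' so that positive rotation carries the lateral direction (scapular
#' frame z) towards the superior direction (frame y) -- i.e. the arm
#' elevates.
#'
#' @param model a [shoulder_model()].
#' @return List with unit `axis`, `center` (the glenohumeral centre) and
#'   `sense` (+1).
#' @export
scaption_axis <- function(model) {
  fr <- model$scapula_frame
  axis <- unit(fr$x)
  if (sum(vcross(axis, fr$z) * fr$y) < 0) axis <- -axis
  list(axis = axis, center = model$gh_center, sense = 1)
}

#' Simulate scaption and record the acromio-humeral distance
#'
#' The humerus rotates rigidly about the [scaption_axis()] in increments
#' of `config$step` degrees from its as-given pose; the scapula stays
#' fixed. At each step the minimum distance between the
#' `"acromion"`-labelled scapular subregion and the humerus is computed
#' exactly ([min_distance_fast()]). The impingement-free range of motion
#' (IF-ROM) is the smallest grid angle at which the AHD drops below the
#' threshold, or `theta_max` if it never does. Interpenetration clamps
#' the AHD to 0 (counted as impingement). Optional per-vertex distance
#' fields over the whole scapula surface provide colour-map data
#' (minimum distance = red in the conventional rendering).
#'
#' @param model a [shoulder_model()] (scapula must carry the
#'   `"acromion"` label).
#' @param config a [simulation_config()].
#' @param pre_rotation_deg optional offset added to the starting pose
#'   (the as-given pose is taken as 0 degrees of elevation).
#' @return A `scaption_result`: `sweep` tibble (`theta_deg`, `ahd_mm`,
#'   `impinged`, contact points on both bones), `if_rom_deg`,
#'   `first_impingement_deg` (NA when none), `threshold_mm`,
#'   `vertex_fields`, plus the axis actually used.
#' @export
simulate_scaption <- function(model, config = simulation_config(),
                              pre_rotation_deg = 0) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  acr <- mesh_subset(model$scapula, "acromion")
  ax <- scaption_axis(model)
  humerus <- model$humerus
  if (pre_rotation_deg != 0) {
    humerus <- apply_transform(
      humerus, rotation_about_axis(ax$axis, pre_rotation_deg, ax$center))
  }
  angles <- seq(0, config$theta_max, by = config$step)
  sw <- cpp_sweep(acr$vertices, acr$faces - 1L,
                  humerus$vertices, humerus$faces - 1L,
                  ax$center, ax$axis, angles * pi / 180)
  ahd <- pmax(sw$distance, 0)
  hit <- which(ahd < config$threshold)
  if_rom <- if (length(hit)) angles[hit[1]] else config$theta_max
  first <- if (length(hit)) angles[hit[1]] else NA_real_
  fields <- NULL
  if (!is.null(config$vertex_field_at)) {
    fields <- lapply(config$vertex_field_at, function(th) {
      tr <- rotation_about_axis(ax$axis, -th, ax$center)
      P <- apply_transform(model$scapula$vertices, tr)
      cpp_point_mesh(P, humerus$vertices, humerus$faces - 1L)$distance
    })
    names(fields) <- as.character(config$vertex_field_at)
  }
  structure(list(
    sweep = tibble(
      theta_deg = angles, ahd_mm = ahd, impinged = ahd < config$threshold,
      contact_scapula_x = sw$point_scapula[, 1],
      contact_scapula_y = sw$point_scapula[, 2],
      contact_scapula_z = sw$point_scapula[, 3],
      contact_humerus_x = sw$point_humerus[, 1],
      contact_humerus_y = sw$point_humerus[, 2],
      contact_humerus_z = sw$point_humerus[, 3]),
    if_rom_deg = if_rom,
    first_impingement_deg = first,
    threshold_mm = config$threshold,
    config = config,
    axis = ax,
    vertex_fields = fields,
    interpenetration_policy = "clamp_to_zero"
  ), class = "scaption_result")
}

#' @export
print.scaption_result <- function(x, ...) {
  cat(sprintf(paste0("<scaption_result> %d steps to %g deg; ",
                     "min AHD %.2f mm; IF-ROM %g deg (threshold %g mm)\n"),
              nrow(x$sweep), max(x$sweep$theta_deg), min(x$sweep$ahd_mm),
              x$if_rom_deg, x$threshold_mm))
  invisible(x)
}

#' @rdname simulate_scaption
#' @param x a `scaption_result`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.scaption_result <- function(x, ...) x$sweep

#' @rdname simulate_scaption
#' @exportS3Method generics::glance
glance.scaption_result <- function(x, ...) {
  i <- which.min(x$sweep$ahd_mm)
  tibble(if_rom_deg = x$if_rom_deg,
         first_impingement_deg = x$first_impingement_deg,
         min_ahd_mm = x$sweep$ahd_mm[i],
         theta_at_min_deg = x$sweep$theta_deg[i],
         threshold_mm = x$threshold_mm,
         n_steps = nrow(x$sweep))
}

#' @rdname simulate_scaption
#' @param object a `scaption_result`.
#' @exportS3Method ggplot2::autoplot
autoplot.scaption_result <- function(object, ...) {
  ggplot2::ggplot(object$sweep, ggplot2::aes(x = .data$theta_deg, y = .data$ahd_mm)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = object$threshold_mm, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$if_rom_deg, linetype = "dotted") +
    ggplot2::labs(x = "scaption angle (deg)",
                  y = "minimum acromio-humeral distance (mm)",
                  title = sprintf("IF-ROM = %g deg", object$if_rom_deg)) +
    ggplot2::theme_minimal()
}

#' Export a scaption sweep to CSV (and colour-map PLY snapshots)
#'
#' Writes `<prefix>_ahd.csv` with one row per time step. When the result
#' carries per-vertex distance fields and the scapula mesh is supplied,
#' one PLY per requested angle is written with the field as the vertex
#' `quality` property (`<prefix>_field_<angle>.ply`).
#'
#' @param result a `scaption_result`.
#' @param out_prefix output path prefix.
#' @param scapula the scapula [shoulder_mesh()] the fields refer to.
#' @return Character vector of files written, invisibly.
#' @export
ahd_report <- function(result, out_prefix, scapula = NULL) {
  csv <- paste0(out_prefix, "_ahd.csv")
  write.csv(result$sweep, csv, row.names = FALSE)
  files <- csv
  if (!is.null(result$vertex_fields) && !is.null(scapula)) {
    for (nm in names(result$vertex_fields)) {
      f <- paste0(out_prefix, "_field_", nm, ".ply")
      write_mesh(scapula, f, format = "ply",
                 per_vertex_scalar = result$vertex_fields[[nm]])
      files <- c(files, f)
    }
  }
  invisible(files)
}
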