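#' Read / write face-label sidecar files (JSON)
#'
#' Mesh formats do not carry region labels, so labels travel in a JSON
#' sidecar mapping label names to 1-based face indices.
#'
#' @param path JSON path.
#' @return Named list of integer vectors.
#' @export
read_face_labels <- function(path) {
  if (!file.exists(path)) abort(sprintf("face-label file not found: '%s'", path))
  lab <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(lab, as.integer)
}

#' @rdname read_face_labels
#' @param labels named list of integer face-index vectors.
#' @export
write_face_labels <- function(labels, path) {
  jsonlite::write_json(labels, path)
  invisible(path)
}

default_config <- function() {
  list(
    seed = 1L,
    generate = list(csa_deg = 36, gta_deg = 70, edge_length = 1),
    cohort = list(n_rct = 44, n_control = 17, edge_length = 1),
    simulate = list(theta_max = 120, step = 1, threshold = 6),
    measure = list(scapula = NULL, humerus = NULL, landmarks = NULL,
                   labels = NULL)
  )
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: '%s'", config))
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  modifyList(default_config(), as.list(config))
}

#' Run a pipeline command
#'
#' Thin orchestration over the package functions, suitable for scripted
#' use: each run resolves its configuration (YAML or JSON file, or a
#' list; angles in degrees, distances in mm), executes one command and
#' writes its artifacts plus a resolved-config copy and a JSON summary
#' (seed, key results) into `out_dir`. Outputs are deterministic under
#' the configured seed.
#'
#' Commands: `"generate"` (one synthetic shoulder: meshes + landmarks +
#' labels + params), `"cohort"` (sampled cohort manifest CSV),
#' `"measure"` (CSA/GTA from mesh + landmark files), `"simulate"`
#' (scaption sweep CSV + summary for one model), `"stats"` (group
#' comparison + correlation battery from a cohort CSV), `"end_to_end"`
#' (full synthetic cohort analysis).
#'
#' @param command one of the commands above.
#' @param config list, or path to a YAML/JSON config file.
#' @param out_dir output directory (created if needed).
#' @return The summary list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(command = c("generate", "cohort", "measure",
                                     "simulate", "stats", "end_to_end"),
                         config = list(), out_dir = ".") {
  command <- match.arg(command)
  cfg <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out_dir, "resolved_config.yaml"))
  summary <- switch(command,
    generate = pipeline_generate(cfg, out_dir),
    cohort = pipeline_cohort(cfg, out_dir),
    measure = pipeline_measure(cfg, out_dir),
    simulate = pipeline_simulate(cfg, out_dir),
    stats = pipeline_stats(cfg, out_dir),
    end_to_end = pipeline_end_to_end(cfg, out_dir))
  summary$command <- command
  summary$seed <- cfg$seed
  summary$package_version <- as.character(utils::packageVersion("scaption"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

pipeline_generate <- function(cfg, out_dir) {
  g <- cfg$generate
  p <- synthetic_params(csa_deg = g$csa_deg, gta_deg = g$gta_deg,
                        edge_length = g$edge_length, seed = cfg$seed)
  model <- make_shoulder(p)
  write_mesh(model$scapula, file.path(out_dir, "scapula.ply"))
  write_mesh(model$humerus, file.path(out_dir, "humerus.ply"))
  write_landmarks(model$landmarks, file.path(out_dir, "landmarks.json"))
  write_face_labels(model$scapula$face_labels, file.path(out_dir, "scapula_labels.json"))
  jsonlite::write_json(unclass(p), file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  list(csa_target_deg = p$csa_deg, gta_target_deg = p$gta_deg,
       scapula_faces = nrow(model$scapula$faces),
       humerus_faces = nrow(model$humerus$faces))
}

pipeline_cohort <- function(cfg, out_dir) {
  co <- cfg$cohort
  cp <- cohort_params(n_rct = co$n_rct, n_control = co$n_control,
                      edge_length = co$edge_length, seed = cfg$seed)
  subjects <- sample_cohort(cp)
  manifest <- subjects[, c("subject_id", "group", "csa_target_deg",
                           "gta_target_deg", "clipped")]
  write.csv(manifest, file.path(out_dir, "cohort_manifest.csv"), row.names = FALSE)
  list(n = nrow(subjects), n_clipped = sum(subjects$clipped))
}

load_model_from_config <- function(cfg) {
  m <- cfg$measure
  for (f in c("scapula", "humerus", "landmarks")) {
    if (is.null(m[[f]])) abort(sprintf("config must set measure$%s (file path)", f))
  }
  landmarks <- read_landmarks(m$landmarks)
  scap <- read_mesh(m$scapula)
  if (!is.null(m$labels)) {
    scap$face_labels <- read_face_labels(m$labels)
  }
  shoulder_model(scap, read_mesh(m$humerus), landmarks)
}

pipeline_measure <- function(cfg, out_dir) {
  model <- load_model_from_config(cfg)
  ang <- measure_angles(model)
  out <- list(csa_deg = ang$csa_deg, gta_deg = ang$gta_deg, sum_deg = ang$sum_deg)
  jsonlite::write_json(out, file.path(out_dir, "angles.json"),
                       auto_unbox = TRUE, digits = NA)
  out
}

pipeline_simulate <- function(cfg, out_dir) {
  model <- load_model_from_config(cfg)
  s <- cfg$simulate
  config <- simulation_config(theta_max = s$theta_max, step = s$step,
                              threshold = s$threshold,
                              vertex_field_at = s$vertex_field_at)
  res <- simulate_scaption(model, config)
  ahd_report(res, file.path(out_dir, "scaption"), scapula = model$scapula)
  as.list(glance(res))
}

pipeline_stats <- function(cfg, out_dir) {
  if (is.null(cfg$stats$table)) abort("config must set stats$table (cohort CSV path)")
  tb <- cohort_table(read.csv(cfg$stats$table))
  gc <- group_compare(tb)
  cr <- correlation_battery(tb)
  write.csv(gc, file.path(out_dir, "group_comparison.csv"), row.names = FALSE)
  write.csv(cr, file.path(out_dir, "correlations.csv"), row.names = FALSE)
  setNames(as.list(cr$estimate),
           paste0(cr$method, "_", sub("_deg", "", cr$var1), "_",
                  sub("_deg", "", cr$var2)))
}

pipeline_end_to_end <- function(cfg, out_dir) {
  co <- cfg$cohort
  cp <- cohort_params(n_rct = co$n_rct, n_control = co$n_control,
                      edge_length = co$edge_length, seed = cfg$seed)
  s <- cfg$simulate
  config <- simulation_config(theta_max = s$theta_max, step = s$step,
                              threshold = s$threshold)
  res <- end_to_end_cohort(cp, config)
  write.csv(res$table, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  write.csv(res$group_comparison, file.path(out_dir, "group_comparison.csv"),
            row.names = FALSE)
  write.csv(res$correlations, file.path(out_dir, "correlations.csv"),
            row.names = FALSE)
  as.list(glance(res))
}
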