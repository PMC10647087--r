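#' Parameters of the synthetic shoulder generator
#'
#' Defines a parametric bone pair in a canonical pose -- glenohumeral
#' centre at the origin, +x lateral, +y superior, z normal to the
#' scapular (coronal) plane -- built from solid primitives that admit
#' closed-form distances:
#'
#' * humerus: head sphere (radius `head_radius`), greater-tuberosity
#'   sphere (radius `tuberosity_radius`) whose apex sits exactly at polar
#'   angle `gta_deg` from the proximal axis at radius
#'   `head_radius + bump_height`, and a shaft cylinder along -y;
#' * scapula: acromion box (undersurface `acromion_height` above the
#'   joint centre, lateral extent solved in closed form so the measured
#'   CSA equals `csa_deg`), a glenoid disc facing the head across
#'   `glenoid_gap`, and a coarse medial body strut (excluded from AHD).
#'
#' When `bump_height` is `NULL` it defaults to the GTA-coupled prominence
#' `clamp(4.8 + 0.22 (GTA - 70) + 0.033 max(GTA - 70, 0)^2, 0.5, 9)` mm:
#' in this family a larger greater tuberosity angle comes with a more
#' prominent tuberosity, so elevation brings a tall tuberosity under the
#' acromial undersurface sooner -- the mechanism behind the negative
#' GTA/IF-ROM association. `bump_height = 0` gives a purely spherical
#' head (useful as an analytic control: the AHD is then constant over
#' the sweep).
#'
#' @param csa_deg target critical shoulder angle, degrees (about 22-57
#'   for the default geometry; the lateral acromion extent must exceed
#'   its medial edge).
#' @param gta_deg target greater tuberosity angle, degrees (0, 90).
#' @param head_radius humeral head radius, mm.
#' @param bump_height tuberosity prominence beyond the head sphere, mm,
#'   or `NULL` for the GTA-coupled default.
#' @param tuberosity_radius radius of the tuberosity sphere, mm
#'   (< `head_radius`).
#' @param shaft_radius,shaft_length shaft cylinder dimensions, mm.
#' @param acromion_height height of the acromial undersurface above the
#'   joint centre, mm (> `head_radius`).
#' @param acromion_medial_x medial edge of the acromion box, mm.
#' @param acromion_thickness,acromion_depth box thickness (superior) and
#'   antero-posterior depth, mm.
#' @param glenoid_radius glenoid disc radius, mm.
#' @param glenoid_gap articular gap between disc and head surface, mm.
#' @param edge_length target mesh edge length, mm.
#' @param seed integer recorded for provenance (generation itself is
#'   deterministic).
#' @return A `synthetic_params` list, with the solved lateral acromion
#'   extent `x1`.
#' @export
synthetic_params <- function(csa_deg = 36, gta_deg = 70,
                             head_radius = 25, bump_height = NULL,
                             tuberosity_radius = 8,
                             shaft_radius = 12, shaft_length = 120,
                             acromion_height = 34, acromion_medial_x = -10,
                             acromion_thickness = 6, acromion_depth = 15,
                             glenoid_radius = 15, glenoid_gap = 4,
                             edge_length = 1, seed = 1L) {
  if (!(gta_deg > 0 && gta_deg < 90)) abort("need 0 < gta_deg < 90")
  if (!(csa_deg > 20 && csa_deg < 60)) abort("need 20 < csa_deg < 60")
  if (is.null(bump_height)) bump_height <- default_bump_height(gta_deg)
  if (!(head_radius > tuberosity_radius && tuberosity_radius > 0)) {
    abort("need head_radius > tuberosity_radius > 0")
  }
  if (acromion_height <= head_radius) abort("acromion must clear the head: acromion_height > head_radius")
  if (bump_height < 0) abort("bump_height must be >= 0")
  glen_x <- -(head_radius + glenoid_gap)
  # lateral acromion corner (x1, acromion_height) seen from IG = (glen_x, -glenoid_radius):
  # tan(CSA) = (x1 - glen_x) / (acromion_height + glenoid_radius)
  x1 <- (acromion_height + glenoid_radius) * tan(csa_deg * pi / 180) + glen_x
  if (x1 <= acromion_medial_x) {
    abort(sprintf("csa_deg = %g is unsolvable: lateral extent %.2f does not exceed the medial edge %.2f",
                  csa_deg, x1, acromion_medial_x))
  }
  structure(list(
    csa_deg = csa_deg, gta_deg = gta_deg,
    head_radius = head_radius, bump_height = bump_height,
    tuberosity_radius = tuberosity_radius,
    shaft_radius = shaft_radius, shaft_length = shaft_length,
    acromion_height = acromion_height, acromion_medial_x = acromion_medial_x,
    acromion_thickness = acromion_thickness, acromion_depth = acromion_depth,
    glenoid_radius = glenoid_radius, glenoid_gap = glenoid_gap,
    glenoid_x = glen_x, x1 = x1,
    edge_length = edge_length, seed = as.integer(seed)
  ), class = "synthetic_params")
}

#' GTA-coupled default tuberosity prominence
#'
#' The default coupling between the greater tuberosity angle and the
#' prominence of the tuberosity beyond the head sphere (mm); see
#' [synthetic_params()].
#'
#' @param gta_deg greater tuberosity angle, degrees.
#' @return Bump height, mm.
#' @export
default_bump_height <- function(gta_deg) {
  pmin(pmax(4.8 + 0.22 * (gta_deg - 70) + 0.033 * pmax(gta_deg - 70, 0)^2,
            0.5), 9)
}

acromion_box_bounds <- function(p) {
  list(lo = c(p$acromion_medial_x, p$acromion_height, -p$acromion_depth / 2),
       hi = c(p$x1, p$acromion_height + p$acromion_thickness,
              p$acromion_depth / 2))
}

drop_unused_vertices <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  shoulder_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(remap[mesh$faces], ncol = 3),
                mesh$face_labels)
}

#' Generate a synthetic shoulder model
#'
#' Tessellates the primitives of [synthetic_params()] (tuberosity apex
#' placed as an exact mesh vertex; acromion box corners exact), attaches
#' canonical landmarks such that the ISB scapular frame reproduces the
#' canonical axes and the glenoid line lies in the coronal plane, and
#' assembles the result through the standard [shoulder_model()] pipeline
#' -- the joint centre, shaft axis and frames are *fitted* from the
#' meshes, not copied from the generator truth. Generation is
#' deterministic: identical parameters give identical meshes.
#'
#' @param params a [synthetic_params()].
#' @return A [shoulder_model()].
#' @export
make_shoulder <- function(params) {
  p <- params
  el <- p$edge_length
  dir <- c(sin(p$gta_deg * pi / 180), cos(p$gta_deg * pi / 180), 0)
  # --- humerus
  head <- icosphere(p$head_radius, c(0, 0, 0), el)
  shaft_top <- -0.8 * p$head_radius
  shaft <- cylinder_mesh(c(0, shaft_top, 0),
                         c(0, shaft_top - p$shaft_length, 0),
                         p$shaft_radius, el)
  parts <- list(head, shaft)
  if (p$bump_height > 0.02) {
    d <- p$head_radius + p$bump_height - p$tuberosity_radius
    tub <- uv_sphere(p$tuberosity_radius, d * dir, dir, el)
    # keep every face with at least one vertex outside the head sphere, so
    # the exposed prominence is covered right up to the intersection circle
    rv <- sqrt(rowSums(tub$vertices^2))
    vr <- matrix(rv[tub$faces], ncol = 3)
    keep <- which(pmax(vr[, 1], vr[, 2], vr[, 3]) >= p$head_radius)
    if (length(keep)) {
      tub <- drop_unused_vertices(
        shoulder_mesh(tub$vertices, tub$faces[keep, , drop = FALSE]))
      parts <- c(parts, list(tub))
    }
  }
  humerus <- do.call(mesh_merge, parts)
  # --- scapula
  bb <- acromion_box_bounds(p)
  acr <- box_mesh(bb$lo, bb$hi, el)
  acr$face_labels <- list(acromion = seq_len(nrow(acr$faces)))
  glen <- disc_mesh(c(p$glenoid_x, 0, 0), c(1, 0, 0), p$glenoid_radius, el)
  glen$face_labels <- list(glenoid = seq_len(nrow(glen$faces)))
  body <- box_mesh(c(-70, -70, -2), c(p$glenoid_x - 2, 36, 2), 8)
  body$face_labels <- list(body = seq_len(nrow(body$faces)))
  scapula <- mesh_merge(acr, glen, body)
  landmarks <- list(
    AA = c(2, 40, 0), TS = c(-58, 40, 0), AI = c(-58, -75, 0),
    SG = c(p$glenoid_x, p$glenoid_radius, 0),
    IG = c(p$glenoid_x, -p$glenoid_radius, 0),
    GT_APEX = (p$head_radius + p$bump_height) * dir)
  model <- shoulder_model(scapula, humerus, landmarks)
  model$params <- p
  model
}

# point-to-box distance, rows of P
dist_point_box <- function(P, lo, hi) {
  if (!is.matrix(P)) P <- matrix(P, 1)
  D <- pmax(sweep(-P, 2, lo, "+"), 0) + pmax(sweep(P, 2, hi, "-"), 0)
  sqrt(rowSums(D^2))
}

#' Closed-form acromio-humeral distance of the synthetic family
#'
#' Exact AHD of the solid primitives at elevation `theta`: the minimum of
#' the acromion-box distances to the head sphere, to the rotated
#' tuberosity sphere and to the rotated shaft cylinder (the latter via
#' exact minimisation of the convex point-to-box distance along the
#' shaft segment), clamped at 0 for interpenetration. Because all mesh
#' vertices lie exactly on these primitives, the mesh simulator's AHD can
#' exceed this value only by the tessellation chord error.
#'
#' @param params a [synthetic_params()].
#' @param theta_deg elevation angle(s), degrees (vectorised).
#' @return AHD in mm, same length as `theta_deg`.
#' @export
closed_form_ahd <- function(params, theta_deg) {
  p <- params
  bb <- acromion_box_bounds(p)
  vapply(theta_deg, function(th) {
    head <- dist_point_box(c(0, 0, 0), bb$lo, bb$hi) - p$head_radius
    best <- head
    if (p$bump_height > 0.02) {
      d <- p$head_radius + p$bump_height - p$tuberosity_radius
      phi <- (p$gta_deg - th) * pi / 180
      cc <- d * c(sin(phi), cos(phi), 0)
      best <- min(best, dist_point_box(cc, bb$lo, bb$hi) - p$tuberosity_radius)
    }
    a <- th * pi / 180
    R <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    shaft_top <- -0.8 * p$head_radius
    p0 <- as.numeric(R %*% c(0, shaft_top, 0))
    p1 <- as.numeric(R %*% c(0, shaft_top - p$shaft_length, 0))
    sh <- optimize(function(t) dist_point_box(p0 + t * (p1 - p0), bb$lo, bb$hi),
                   c(0, 1), tol = 1e-9)$objective - p$shaft_radius
    max(0, min(best, sh))
  }, numeric(1))
}

#' Closed-form impingement-free range of motion
#'
#' Scans [closed_form_ahd()] on the simulation grid and reports the first
#' angle below the threshold (or `theta_max`), plus the continuous
#' crossing angle refined by root bracketing to 0.01 degrees.
#'
#' @param params a [synthetic_params()].
#' @param threshold impingement threshold, mm.
#' @param theta_max,step sweep grid, degrees.
#' @return List with `if_rom_deg` (grid answer) and `crossing_deg`
#'   (continuous; `NA` when the curve never crosses).
#' @export
closed_form_ifrom <- function(params, threshold = 6, theta_max = 120, step = 1) {
  grid <- seq(0, theta_max, by = step)
  ahd <- closed_form_ahd(params, grid)
  i <- which(ahd < threshold)
  if (!length(i)) {
    return(list(if_rom_deg = theta_max, crossing_deg = NA_real_))
  }
  i <- i[1]
  if (i == 1L) return(list(if_rom_deg = 0, crossing_deg = 0))
  f <- function(th) closed_form_ahd(params, th) - threshold
  root <- uniroot(f, c(grid[i - 1L], grid[i]), tol = 0.005)$root
  list(if_rom_deg = grid[i], crossing_deg = root)
}

#' Two-group cohort parameters
#'
#' Defaults reproduce the study conditions of the source cohort: 44
#' rotator-cuff-tear shoulders (CSA 41.3 +/- 5.4 deg, GTA 73.9 +/- 4.4
#' deg) and 17 controls (CSA 36.8 +/- 4.1, GTA 68.3 +/- 3.5), with CSA
#' and GTA sampled independently (the observed correlation between them
#' is near zero). Samples are clipped to the generator's validity ranges
#' (CSA 25-57, GTA 59-85 degrees); clipping is recorded per subject.
#'
#' @param n_rct,n_control group sizes.
#' @param rct_csa,rct_gta,control_csa,control_gta length-2 `c(mean, sd)`
#'   vectors, degrees.
#' @param edge_length mesh resolution handed to [synthetic_params()], mm.
#' @param seed integer RNG seed; sampling is fully deterministic given it.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_rct = 44, n_control = 17,
                          rct_csa = c(41.3, 5.4), rct_gta = c(73.9, 4.4),
                          control_csa = c(36.8, 4.1), control_gta = c(68.3, 3.5),
                          edge_length = 1, seed = 1L) {
  stopifnot(n_rct > 0, n_control > 0,
            rct_csa[2] > 0, rct_gta[2] > 0, control_csa[2] > 0, control_gta[2] > 0)
  structure(list(n_rct = n_rct, n_control = n_control,
                 rct_csa = rct_csa, rct_gta = rct_gta,
                 control_csa = control_csa, control_gta = control_gta,
                 csa_range = c(25, 57), gta_range = c(59, 85),
                 edge_length = edge_length, seed = as.integer(seed)),
            class = "cohort_params")
}

with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Sample a synthetic two-group cohort
#'
#' Draws per-subject CSA and GTA independently from the group normal
#' distributions of [cohort_params()], clips to the generator validity
#' ranges, and returns one row per subject with the generator parameters
#' as a list-column.
#'
#' @param cp a [cohort_params()].
#' @return Tibble with `subject_id`, `group` (`"RCT"`/`"CONTROL"`),
#'   `csa_target_deg`, `gta_target_deg`, `clipped`, `params`.
#' @export
sample_cohort <- function(cp) {
  draws <- with_preserved_seed(cp$seed, {
    g <- rep(c("RCT", "CONTROL"), c(cp$n_rct, cp$n_control))
    csa <- c(rnorm(cp$n_rct, cp$rct_csa[1], cp$rct_csa[2]),
             rnorm(cp$n_control, cp$control_csa[1], cp$control_csa[2]))
    gta <- c(rnorm(cp$n_rct, cp$rct_gta[1], cp$rct_gta[2]),
             rnorm(cp$n_control, cp$control_gta[1], cp$control_gta[2]))
    list(g = g, csa = csa, gta = gta)
  })
  csa_c <- pmin(pmax(draws$csa, cp$csa_range[1]), cp$csa_range[2])
  gta_c <- pmin(pmax(draws$gta, cp$gta_range[1]), cp$gta_range[2])
  clipped <- (csa_c != draws$csa) | (gta_c != draws$gta)
  if (any(clipped)) {
    warn(sprintf("%d subject(s) clipped to the generator validity ranges",
                 sum(clipped)))
  }
  tibble(
    subject_id = sprintf("S%03d", seq_along(draws$g)),
    group = draws$g,
    csa_target_deg = csa_c,
    gta_target_deg = gta_c,
    clipped = clipped,
    params = purrr::map2(csa_c, gta_c, function(cs, gt) {
      synthetic_params(csa_deg = cs, gta_deg = gt,
                       edge_length = cp$edge_length, seed = cp$seed)
    })
  )
}
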