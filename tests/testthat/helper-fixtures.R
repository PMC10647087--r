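# Shared fixtures. Random meshes are triangle soups (no shared vertices);
# expensive grid/cohort computations are memoised across test files.

random_soup <- function(n_tri, shift = 0, scale = 1) {
  V <- matrix(rnorm(9 * n_tri), ncol = 3) * scale
  V[, 1] <- V[, 1] + shift
  shoulder_mesh(V, matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE))
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

random_rigid <- function(tmax = 20) {
  rigid_transform(random_rotation(), runif(3, -tmax, tmax))
}

# coarse shoulder for quick unit tests
coarse_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_shoulder(synthetic_params(csa_deg = 36, gta_deg = 74,
                                               edge_length = 2))
    }
    cache
  }
})

canonical_landmarks <- function() {
  list(AA = c(2, 40, 0), TS = c(-58, 40, 0), AI = c(-58, -75, 0),
       SG = c(-29, 15, 0), IG = c(-29, -15, 0))
}

# -- acceptance fixtures (computed once, at the study resolution) -----------

acceptance_env <- new.env(parent = emptyenv())

# 5 x 5 CSA x GTA grid at 1.0 mm edge length: measured angles, simulated
# IF-ROM and the closed-form oracle IF-ROM per cell.
acceptance_grid <- function() {
  if (!is.null(acceptance_env$grid)) return(acceptance_env$grid)
  cells <- expand.grid(csa = c(30, 33, 36, 39, 42),
                       gta = c(62, 66, 70, 74, 78))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    p <- synthetic_params(csa_deg = cells$csa[i], gta_deg = cells$gta[i],
                          edge_length = 1)
    model <- make_shoulder(p)
    ang <- measure_angles(model)
    sim <- simulate_scaption(model)
    tibble::tibble(csa_target = cells$csa[i], gta_target = cells$gta[i],
                   csa_meas = ang$csa_deg, gta_meas = ang$gta_deg,
                   ifrom_sim = sim$if_rom_deg,
                   ifrom_oracle = closed_form_ifrom(p)$if_rom_deg)
  })
  acceptance_env$grid <- dplyr::bind_rows(rows)
  acceptance_env$grid
}

# seeded 44 + 17 end-to-end cohort at 1.0 mm edge length
acceptance_cohort <- function() {
  if (is.null(acceptance_env$cohort)) {
    acceptance_env$cohort <- suppressWarnings(
      end_to_end_cohort(cohort_params(seed = 1, edge_length = 1)))
  }
  acceptance_env$cohort
}
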