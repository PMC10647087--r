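test_that("simulation config validates its ranges", {
  expect_error(simulation_config(step = 0), "0 < step")
  expect_error(simulation_config(step = 130), "0 < step")
  expect_error(simulation_config(threshold = -1), "positive")
})

test_that("the scaption axis elevates the arm: the tuberosity apex swings towards superior", {
  m <- coarse_model()
  ax <- scaption_axis(m)
  # axis is the scapular plane normal through the joint centre
  expect_lt(abs(abs(sum(ax$axis * m$scapula_frame$x)) - 1), 1e-9)
  expect_equal(ax$center, m$gh_center)
  apex <- m$landmarks$GT_APEX
  pol <- function(p) atan2(sum((p - m$gh_center) * m$scapula_frame$z),
                           sum((p - m$gh_center) * m$scapula_frame$y)) * 180 / pi
  prev <- pol(apex)
  for (th in c(10, 20, 40, 60)) {
    cur <- pol(apply_transform(apex, rotation_about_axis(ax$axis, th, ax$center)))
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("scaption axis is equivariant under rigid motion", {
  m <- coarse_model()
  ax0 <- scaption_axis(m)
  withr::with_seed(41, {
    tr <- random_rigid()
    ax1 <- scaption_axis(transform_model(m, tr))
    expect_lt(max(abs(ax1$axis - as.numeric(tr$rotation %*% ax0$axis))), 1e-6)
    expect_lt(max(abs(ax1$center - apply_transform(ax0$center, tr))), 0.5)
  })
})

test_that("a spherical head yields a flat AHD curve and full IF-ROM", {
  m <- make_shoulder(synthetic_params(csa_deg = 36, gta_deg = 70,
                                      bump_height = 0, edge_length = 2))
  sim <- simulate_scaption(m)
  expect_equal(sim$if_rom_deg, 120)
  expect_true(is.na(sim$first_impingement_deg))
  expect_lt(max(sim$sweep$ahd_mm) - min(sim$sweep$ahd_mm), 0.2)
  # analytic clearance: undersurface height minus head radius = 9 mm
  expect_equal(mean(sim$sweep$ahd_mm), 9, tolerance = 0.05 / 9)
})

test_that("IF-ROM semantics at the boundaries and threshold monotonicity", {
  m <- coarse_model()
  sim6 <- simulate_scaption(m)
  # threshold above the whole curve: impinged from the first step
  simhi <- simulate_scaption(m, simulation_config(threshold = 50))
  expect_equal(simhi$if_rom_deg, 0)
  # first-crossing semantics on the recorded grid
  i <- which(sim6$sweep$ahd_mm < sim6$threshold_mm)[1]
  expect_equal(sim6$if_rom_deg, sim6$sweep$theta_deg[i])
  expect_true(all(sim6$sweep$ahd_mm[seq_len(i - 1)] >= sim6$threshold_mm))
  # raising the threshold never increases IF-ROM (recomputed from one curve)
  ifrom_at <- function(thr) {
    j <- which(sim6$sweep$ahd_mm < thr)[1]
    if (is.na(j)) 120 else sim6$sweep$theta_deg[j]
  }
  thr <- seq(1, 12, by = 0.5)
  expect_true(all(diff(vapply(thr, ifrom_at, numeric(1))) <= 0))
})

test_that("halving the step changes IF-ROM by at most the original step", {
  m <- coarse_model()
  s1 <- simulate_scaption(m, simulation_config(step = 1))
  s05 <- simulate_scaption(m, simulation_config(step = 0.5))
  expect_lte(abs(s1$if_rom_deg - s05$if_rom_deg), 1)
})

test_that("sweep results carry valid contact points on both surfaces", {
  m <- coarse_model()
  sim <- simulate_scaption(m, simulation_config(theta_max = 40, step = 5))
  sw <- sim$sweep
  acr <- mesh_subset(m$scapula, "acromion")
  for (k in c(1, nrow(sw))) {
    pa <- c(sw$contact_scapula_x[k], sw$contact_scapula_y[k], sw$contact_scapula_z[k])
    ph <- c(sw$contact_humerus_x[k], sw$contact_humerus_y[k], sw$contact_humerus_z[k])
    # the gap between reported contacts equals the reported AHD
    expect_equal(sqrt(sum((pa - ph)^2)), sw$ahd_mm[k], tolerance = 1e-9)
    # scapular contact lies on the (fixed) acromion surface
    expect_lt(cpp_point_mesh(rbind(pa), acr$vertices, acr$faces - 1L)$distance, 1e-6)
  }
})

test_that("missing acromion label is an error", {
  m <- coarse_model()
  bare <- m
  bare$scapula$face_labels <- NULL
  expect_error(simulate_scaption(bare), "acromion")
})

test_that("the AHD report round-trips and reproduces IF-ROM from the CSV", {
  m <- coarse_model()
  sim <- simulate_scaption(m, simulation_config(vertex_field_at = c(0, 40)))
  prefix <- file.path(withr::local_tempdir(), "run")
  files <- ahd_report(sim, prefix, scapula = m$scapula)
  expect_equal(length(files), 3L)  # csv + 2 field snapshots
  tab <- read.csv(paste0(prefix, "_ahd.csv"))
  expect_equal(nrow(tab), 121L)
  j <- which(tab$ahd_mm < sim$threshold_mm)[1]
  ifrom_csv <- if (is.na(j)) 120 else tab$theta_deg[j]
  expect_equal(ifrom_csv, sim$if_rom_deg)
  # the colour-map snapshot carries one distance per scapula vertex
  f0 <- read_mesh_scalar(paste0(prefix, "_field_0.ply"))
  expect_equal(length(f0), nrow(m$scapula$vertices))
  expect_true(all(f0 >= 0))
  # at angle 0 the field minimum approaches the acromion-restricted AHD from below
  expect_lte(min(f0), sim$sweep$ahd_mm[1] + 2)
})

test_that("vertex fields use the full scapula while AHD uses only the acromion", {
  m <- coarse_model()
  sim <- simulate_scaption(m, simulation_config(theta_max = 10, step = 10,
                                                vertex_field_at = 0))
  f <- sim$vertex_fields[["0"]]
  # glenoid vertices sit ~gap from the head: far below the acromial AHD
  expect_lt(min(f), 4 + 0.5)
  expect_gt(sim$sweep$ahd_mm[1], 6)
})
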