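test_that("parameter validation enforces the geometric feasibility window", {
  expect_error(synthetic_params(csa_deg = 15), "20 < csa_deg")
  expect_error(synthetic_params(gta_deg = 95), "gta_deg < 90")
  expect_error(synthetic_params(csa_deg = 21), "unsolvable")
  expect_error(synthetic_params(head_radius = 7, tuberosity_radius = 8),
               "head_radius > tuberosity_radius")
  p <- synthetic_params(csa_deg = 36)
  # closed-form lateral extent: the solved corner reproduces the target CSA
  csa_back <- atan2(p$x1 - p$glenoid_x, p$acromion_height + p$glenoid_radius) * 180 / pi
  expect_equal(csa_back, 36, tolerance = 1e-9)
})

test_that("the GTA-coupled prominence is monotone and clamped", {
  g <- seq(59, 85, by = 0.5)
  h <- default_bump_height(g)
  expect_true(all(diff(h) >= 0))
  expect_true(all(h >= 0.5 & h <= 9))
  expect_equal(default_bump_height(70), 4.8)
})

test_that("generation is deterministic: identical parameters give identical meshes", {
  p <- synthetic_params(csa_deg = 38, gta_deg = 72, edge_length = 2.5)
  m1 <- make_shoulder(p)
  m2 <- make_shoulder(p)
  expect_identical(m1$humerus$vertices, m2$humerus$vertices)
  expect_identical(m1$scapula$vertices, m2$scapula$vertices)
  expect_identical(m1$landmarks, m2$landmarks)
  expect_identical(m1$gh_center, m2$gh_center)
})

test_that("the tuberosity apex is an exact mesh vertex at the requested angle", {
  p <- synthetic_params(csa_deg = 36, gta_deg = 74, edge_length = 2)
  m <- make_shoulder(p)
  apex <- (p$head_radius + p$bump_height) *
    c(sin(74 * pi / 180), cos(74 * pi / 180), 0)
  dmin <- min(sqrt(rowSums(sweep(m$humerus$vertices, 2, apex)^2)))
  expect_lt(dmin, 1e-9)
})

test_that("closed-form AHD: spherical-head limit and a hand-computed corner case", {
  p0 <- synthetic_params(csa_deg = 36, gta_deg = 70, bump_height = 0)
  ahd <- closed_form_ahd(p0, seq(0, 120, by = 7.5))
  # box directly above the centre: clearance = undersurface height - head radius
  expect_equal(ahd, rep(9, length(ahd)), tolerance = 1e-9)

  # at theta = 0 the tuberosity sits lateral of the box footprint, below the
  # undersurface: distance is to the lateral corner edge
  p <- synthetic_params(csa_deg = 36, gta_deg = 74)
  d <- p$head_radius + p$bump_height - p$tuberosity_radius
  cc <- d * c(sin(74 * pi / 180), cos(74 * pi / 180))
  expect_gt(cc[1], p$x1)
  expect_lt(cc[2], p$acromion_height)
  corner <- sqrt((cc[1] - p$x1)^2 + (p$acromion_height - cc[2])^2) -
    p$tuberosity_radius
  expect_equal(closed_form_ahd(p, 0), min(9, corner), tolerance = 1e-9)
})

test_that("closed-form IF-ROM: grid vs continuous crossing and no-impingement cap", {
  p <- synthetic_params(csa_deg = 41, gta_deg = 74)
  cf <- closed_form_ifrom(p)
  expect_lte(cf$if_rom_deg - cf$crossing_deg, 1)
  expect_gte(cf$if_rom_deg, cf$crossing_deg)
  # curve never dips below threshold -> capped at the sweep end
  p0 <- synthetic_params(csa_deg = 36, gta_deg = 70, bump_height = 0)
  cf0 <- closed_form_ifrom(p0)
  expect_equal(cf0$if_rom_deg, 120)
  expect_true(is.na(cf0$crossing_deg))
})

test_that("mesh simulation tracks the closed-form curve within tessellation error", {
  p <- synthetic_params(csa_deg = 39, gta_deg = 74, edge_length = 1)
  m <- make_shoulder(p)
  sim <- simulate_scaption(m, simulation_config(step = 5))
  oracle <- closed_form_ahd(p, sim$sweep$theta_deg)
  # vertices on the primitives: mesh distance can only exceed the solid one
  expect_true(all(sim$sweep$ahd_mm >= oracle - 1e-9))
  expect_lt(max(abs(sim$sweep$ahd_mm - oracle)), 0.3)
})

test_that("mesh-vs-oracle discrepancy shrinks with mesh refinement", {
  p <- function(e) synthetic_params(csa_deg = 39, gta_deg = 74, edge_length = e)
  angles <- seq(0, 120, by = 15)
  disc <- vapply(c(2, 1, 0.5), function(e) {
    pp <- p(e)
    sim <- simulate_scaption(make_shoulder(pp), simulation_config(step = 15))
    max(abs(sim$sweep$ahd_mm - closed_form_ahd(pp, angles)))
  }, numeric(1))
  expect_true(all(diff(disc) < 0.05))   # decreasing within noise
  expect_lt(disc[3], 0.15)              # converged to the chord-error floor
})

test_that("cohort sampling reproduces the group distributions deterministically", {
  cp <- cohort_params(seed = 7)
  s1 <- suppressWarnings(sample_cohort(cp))
  s2 <- suppressWarnings(sample_cohort(cp))
  expect_identical(s1$csa_target_deg, s2$csa_target_deg)
  expect_equal(nrow(s1), 61L)
  rct <- s1[s1$group == "RCT", ]
  ctl <- s1[s1$group == "CONTROL", ]
  # sample mean within 2 standard errors of the target mean
  expect_lt(abs(mean(rct$csa_target_deg) - 41.3), 2 * 5.4 / sqrt(44))
  expect_lt(abs(mean(ctl$gta_target_deg) - 68.3), 2 * 3.5 / sqrt(17))
  # the group GTA difference is detectable at the design effect size
  expect_lt(t.test(rct$gta_target_deg, ctl$gta_target_deg)$p.value, 0.05)
  # independence of the two angles (finite-sample bound)
  expect_lt(abs(cor(s1$csa_target_deg, s1$gta_target_deg)), 0.25)
})

test_that("sampling does not disturb the caller's RNG stream", {
  set.seed(123)
  x1 <- rnorm(1)
  set.seed(123)
  invisible(suppressWarnings(sample_cohort(cohort_params(seed = 5))))
  x2 <- rnorm(1)
  expect_identical(x1, x2)
})
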