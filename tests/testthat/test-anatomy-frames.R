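test_that("sphere fit is exact on symmetric noise-free points", {
  pts <- rbind(c(24, 0, 0), c(-24, 0, 0), c(0, 24, 0),
               c(0, -24, 0), c(0, 0, 24), c(0, 0, -24))
  fit <- fit_sphere(pts)
  expect_equal(fit$center, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(fit$radius, 24, tolerance = 1e-9)
  expect_lt(fit$rms_residual, 1e-9)
})

test_that("sphere fit rejects degenerate inputs", {
  expect_error(fit_sphere(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))),
               "at least 4")
  coplanar <- cbind(matrix(rnorm(8), 4), 0)
  expect_error(fit_sphere(coplanar), "non-coplanar")
})

test_that("sphere fit recovers noisy parameters, cross-checked against an independent optimiser", {
  withr::with_seed(5, {
    truth_c <- c(10, -5, 3); truth_r <- 25
    dir <- matrix(rnorm(1500), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    pts <- sweep(dir * truth_r, 2, truth_c, "+") + matrix(rnorm(1500, sd = 0.1), ncol = 3)
    fit <- fit_sphere(pts)
    expect_lt(sqrt(sum((fit$center - truth_c)^2)), 0.05)
    expect_lt(abs(fit$radius - truth_r), 0.05)
    # independent nonlinear least squares (Nelder-Mead from a perturbed start)
    obj <- function(par) sum((sqrt(rowSums(sweep(pts, 2, par[1:3])^2)) - par[4])^2)
    om <- optim(c(truth_c + 1, truth_r - 2), obj, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
    expect_lt(sqrt(sum((fit$center - om$par[1:3])^2)), 1e-3)
    expect_lt(abs(fit$radius - om$par[4]), 1e-3)
  })
})

test_that("sphere-fit centre error stays below 0.1 mm across seeded noise draws", {
  errs <- withr::with_seed(17, {
    vapply(1:50, function(i) {
      dir <- matrix(rnorm(900), ncol = 3)
      dir <- dir / sqrt(rowSums(dir^2))
      pts <- sweep(dir * 25, 2, c(1, 2, 3), "+") + matrix(rnorm(900, sd = 0.2), ncol = 3)
      sqrt(sum((fit_sphere(pts)$center - c(1, 2, 3))^2))
    }, numeric(1))
  })
  expect_lt(median(errs), 0.1)
})

test_that("head-point selection recovers the head radius despite tuberosity and shaft", {
  m <- coarse_model()
  expect_lt(abs(m$gh_radius - 25), 0.5)
  expect_lt(sqrt(sum(m$gh_center^2)), 0.5)
})

test_that("a pure sphere is used in full and a bare shaft is flagged", {
  s <- icosphere(25, c(3, 2, 1), edge_length = 2)
  sel <- select_head_points(s)
  expect_equal(nrow(sel), nrow(s$vertices))
  expect_lt(abs(fit_sphere(sel)$radius - 25), 1e-6)

  cyl <- cylinder_mesh(c(0, 0, 0), c(0, -100, 0), 12, edge_length = 2)
  expect_warning(select_head_points(cyl), "degenerate")
})

test_that("ISB scapular frame reproduces the canonical axes of the generator pose", {
  fr <- scapula_frame_isb(canonical_landmarks())
  expect_equal(fr$origin, c(2, 40, 0))
  expect_equal(fr$z, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(fr$y, c(0, 1, 0), tolerance = 1e-9)
  expect_equal(abs(fr$x[3]), 1, tolerance = 1e-9)  # plane normal
})

test_that("frames are equivariant under rigid motion and reject bad landmarks", {
  lm <- canonical_landmarks()
  fr0 <- scapula_frame_isb(lm)
  withr::with_seed(23, {
    for (i in 1:10) {
      tr <- random_rigid()
      fr1 <- scapula_frame_isb(lapply(lm, apply_transform, transform = tr))
      for (ax in c("x", "y", "z")) {
        expect_lt(max(abs(fr1[[ax]] - as.numeric(tr$rotation %*% fr0[[ax]]))), 1e-9)
      }
    }
  })
  lm$TS <- lm$AA
  expect_error(scapula_frame_isb(lm), "collinear|coincide")
})

test_that("humerus frame: shaft fallback and epicondylar construction agree when constructed to", {
  lm <- canonical_landmarks()
  sf <- scapula_frame_isb(lm)
  shaft <- list(point = c(0, -50, 0), direction = c(0, -1, 0))
  fb <- humerus_frame(c(0, 0, 0), lm, shaft_axis = shaft, scapula_frame = sf)
  expect_equal(fb$option, "shaft_fallback")
  expect_equal(fb$y, c(0, 1, 0), tolerance = 1e-9)   # antiparallel to shaft direction
  # epicondyles symmetric about the shaft-axis extension
  lm$EL <- c(12, -150, 0); lm$EM <- c(-12, -150, 0)
  isb <- humerus_frame(c(0, 0, 0), lm, scapula_frame = sf)
  expect_equal(isb$option, "isb_humerus")
  for (ax in c("x", "y", "z")) {
    expect_lt(acos(pmin(1, sum(isb[[ax]] * fb[[ax]]))), 1e-6)
  }
  expect_error(humerus_frame(c(0, 0, 0), canonical_landmarks()), "shaft_axis")
})

test_that("diaphyseal axis recovers the shaft direction", {
  m <- coarse_model()
  ax <- m$shaft_axis
  # distal direction within 0.5 degrees of -y
  expect_lt(acos(pmin(1, sum(ax$direction * c(0, -1, 0)))) * 180 / pi, 0.5)
  expect_lt(ax$rms, 1)  # sub-millimetre centroid scatter about the fitted line
  # perfect cylinder: exact axis
  cyl <- cylinder_mesh(c(0, 0, 0), c(0, -100, 0), 12, edge_length = 2)
  axc <- diaphyseal_axis(cyl)
  expect_lt(acos(pmin(1, abs(sum(axc$direction * c(0, -1, 0))))) * 180 / pi, 1e-6)
  expect_lt(axc$rms, 1e-9)
  # too-short shaft
  expect_error(diaphyseal_axis(icosphere(25, edge_length = 3)), "too short")
  # rigid-transform equivariance
  withr::with_seed(31, {
    tr <- random_rigid()
    ax2 <- diaphyseal_axis(apply_transform(m$humerus, tr))
    expect_lt(max(abs(ax2$direction - as.numeric(tr$rotation %*% ax$direction))), 1e-6)
  })
})

test_that("measurement plane is the canonical coronal plane and projection is idempotent", {
  lm <- canonical_landmarks()
  pl <- measurement_plane(scapula_frame_isb(lm), lm)
  expect_equal(pl$point, lm$IG)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-9)
  withr::with_seed(13, {
    P <- matrix(rnorm(30, sd = 20), ncol = 3)
    P1 <- project_to_plane(P, pl)
    expect_equal(project_to_plane(P1, pl), P1, tolerance = 1e-12)
    # projected points lie in the plane
    expect_lt(max(abs(sweep(P1, 2, pl$point) %*% pl$normal)), 1e-9)
    # plane equivariance
    tr <- random_rigid()
    lm2 <- lapply(lm, apply_transform, transform = tr)
    pl2 <- measurement_plane(scapula_frame_isb(lm2), lm2)
    expect_lt(max(abs(abs(sum(pl2$normal * as.numeric(tr$rotation %*% pl$normal))) - 1)), 1e-9)
    expect_equal(pl2$point, apply_transform(lm$IG, tr))
  })
})

test_that("landmark JSON round-trips and validation catches missing names", {
  lm <- canonical_landmarks()
  f <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, f)
  lm2 <- read_landmarks(f)
  expect_equal(lm2, lm)
  expect_error(validate_landmarks(lm[-1], require = "AA"), "missing required")
  expect_error(read_landmarks("nope.json"), "landmarks file not found")
})
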