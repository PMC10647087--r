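tri0 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))

test_that("point-triangle distance matches the analytic regions", {
  # face region
  r <- point_triangle_distance(c(0, 0, 1), tri0)
  expect_equal(r$distance, 1)
  expect_equal(r$closest, c(0, 0, 0))
  # vertex region
  r <- point_triangle_distance(c(2, 0, 0), tri0)
  expect_equal(r$distance, 1)
  expect_equal(r$closest, c(1, 0, 0))
  # edge region: closest point midway along the hypotenuse
  r <- point_triangle_distance(c(1, 1, 0), tri0)
  expect_equal(r$distance, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(r$closest, c(0.5, 0.5, 0))
  expect_error(point_triangle_distance(c(0, 0, 1),
                                       rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "degenerate")
})

test_that("closest points stay on the triangle (barycentric property)", {
  withr::with_seed(11, {
    tri <- matrix(rnorm(9), 3)
    for (i in 1:200) {
      r <- point_triangle_distance(rnorm(3, sd = 3), tri)
      expect_true(all(r$barycentric >= -1e-9))
      expect_lt(abs(sum(r$barycentric) - 1), 1e-9)
      recon <- as.numeric(t(tri) %*% r$barycentric)
      expect_lt(max(abs(recon - r$closest)), 1e-9)
    }
  })
})

test_that("accelerated query equals the exhaustive scan on random meshes", {
  withr::with_seed(42, {
    for (i in 1:30) {
      a <- random_soup(sample(5:60, 1))
      b <- random_soup(sample(5:60, 1), shift = runif(1, 0, 8))
      rb <- min_distance_brute(a, b)
      rf <- min_distance_fast(a, b)
      expect_lt(abs(rb$distance - rf$distance), 1e-9)
      # symmetry
      expect_lt(abs(min_distance_fast(b, a)$distance - rf$distance), 1e-9)
    }
  })
})

test_that("identical and interpenetrating meshes report zero distance", {
  a <- random_soup(20)
  expect_equal(min_distance_fast(a, a)$distance, 0)
  # two crossing triangles
  t1 <- shoulder_mesh(tri0, matrix(1:3, 1))
  t2 <- shoulder_mesh(rbind(c(0.2, 0.2, -0.5), c(0.3, 0.2, 0.5), c(0.2, 0.3, 0.5)),
                      matrix(1:3, 1))
  expect_equal(min_distance_brute(t1, t2)$distance, 0)
  expect_equal(min_distance_fast(t1, t2)$distance, 0)
})

test_that("tessellated spheres recover the analytic gap", {
  s1 <- icosphere(1, c(0, 0, 0), edge_length = 0.06)
  s2 <- icosphere(1, c(4, 0, 0), edge_length = 0.06)
  expect_gt(nrow(s1$faces), 10000)
  d <- min_distance_fast(s1, s2)$distance
  expect_gte(d, 2)            # chords lie inside the spheres
  expect_lt(d - 2, 0.05)      # tessellation chord error bound
})

test_that("distances are invariant under a common rigid motion", {
  withr::with_seed(3, {
    a <- random_soup(30)
    b <- random_soup(30, shift = 5)
    d0 <- min_distance_fast(a, b)$distance
    for (i in 1:10) {
      tr <- random_rigid()
      d1 <- min_distance_fast(apply_transform(a, tr), apply_transform(b, tr))$distance
      expect_lt(abs(d1 - d0), 1e-9)
    }
  })
})

test_that("label restriction queries only the labelled faces", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(0, 0, 5), c(1, 0, 5), c(0, 1, 5))
  a <- shoulder_mesh(V, rbind(c(1L, 2L, 3L), c(4L, 5L, 6L)),
                     face_labels = list(far = 2L))
  b <- shoulder_mesh(sweep(tri0, 2, c(0, 0, -1), "+"), matrix(1:3, 1))
  expect_equal(min_distance_fast(a, b)$distance, 1)
  expect_equal(min_distance_fast(a, b, restrict_a = "far")$distance, 6)
  expect_equal(min_distance_brute(a, b, restrict_a = "far")$distance, 6)
})

test_that("per-vertex distance field matches sphere geometry and the minimum query", {
  a <- icosphere(10, c(0, 0, 0), edge_length = 1.5)
  expect_equal(per_vertex_distance_field(a, a), rep(0, nrow(a$vertices)))
  b <- icosphere(10, c(25, 0, 0), edge_length = 1.5)
  f <- per_vertex_distance_field(a, b)
  expect_true(all(f >= 5 - 0.1 & f <= 25 + 0.1))
  # the minimum of the field is consistent with the mesh-mesh minimum
  dmin <- min_distance_fast(a, b)$distance
  expect_gte(min(f), dmin - 1e-9)
  expect_lt(min(f) - dmin, 1.5)  # within one edge length
  # argmin vertex close to the reported closest point
  va <- a$vertices[which.min(f), ]
  expect_lt(sqrt(sum((va - min_distance_fast(a, b)$point_a)^2)), 1.5)
})
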