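# Parametric surface tessellations for the synthetic shoulder. All return
# shoulder_mesh objects with vertices exactly on the analytic primitive, so
# mesh-based distances are never smaller than the solid-primitive distances
# (chords lie inside); that one-sided bound is relied on by the oracle tests.

# Icosphere: subdivided icosahedron, vertices projected to the sphere.
# Subdivision level chosen so the edge length is <= edge_length.
icosphere <- function(radius, center = c(0, 0, 0), edge_length = 1) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  base_edge <- sqrt(sum((V[1, ] - V[12, ])^2)) * radius
  nsub <- max(0L, ceiling(log2(base_edge / edge_length)))
  nsub <- min(nsub, 7L)
  for (s in seq_len(nsub)) {
    edges <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    uk <- !duplicated(ekey)
    ue <- edges[uk, , drop = FALSE]
    mid <- (V[ue[, 1], ] + V[ue[, 2], ]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    midx <- nrow(V) + match(ekey, ekey[uk])
    V <- rbind(V, mid)
    m12 <- midx[seq_len(nrow(F))]
    m23 <- midx[nrow(F) + seq_len(nrow(F))]
    m31 <- midx[2 * nrow(F) + seq_len(nrow(F))]
    F <- rbind(cbind(F[, 1], m12, m31),
               cbind(F[, 2], m23, m12),
               cbind(F[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  shoulder_mesh(sweep(V * radius, 2, center, "+"), F)
}

# Orthonormal rotation taking +z to the unit direction d.
rotation_to_direction <- function(d) {
  d <- d / sqrt(sum(d^2))
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- vcross(ref, d)
  u <- u / sqrt(sum(u^2))
  v <- vcross(d, u)
  cbind(u, v, d)
}

# Longitude/latitude sphere with the pole vertex exactly at
# center + radius * pole_dir (used so the tuberosity apex is an exact
# mesh vertex).
uv_sphere <- function(radius, center = c(0, 0, 0), pole_dir = c(0, 0, 1),
                      edge_length = 1) {
  nth <- max(4L, as.integer(ceiling(pi * radius / edge_length)))  # latitude bands
  nph <- max(6L, as.integer(ceiling(2 * pi * radius / edge_length)))  # longitude
  th <- seq(0, pi, length.out = nth + 1)
  inner <- th[c(-1, -length(th))]
  ph <- seq(0, 2 * pi, length.out = nph + 1)[-(nph + 1)]
  g <- expand.grid(ph = ph, th = inner)
  ring <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  V <- rbind(c(0, 0, 1), ring, c(0, 0, -1))
  npole <- 1L
  id <- function(i, j) npole + (i - 1L) * nph + ((j - 1L) %% nph) + 1L  # ring i, slot j
  Fs <- list()
  Fs[[1]] <- cbind(1L, vapply(seq_len(nph), function(j) id(1L, j), integer(1)),
                   vapply(seq_len(nph), function(j) id(1L, j + 1L), integer(1)))
  nring <- length(inner)
  if (nring > 1) {
    for (i in seq_len(nring - 1L)) {
      a <- vapply(seq_len(nph), function(j) id(i, j), integer(1))
      b <- vapply(seq_len(nph), function(j) id(i, j + 1L), integer(1))
      c2 <- vapply(seq_len(nph), function(j) id(i + 1L, j), integer(1))
      d2 <- vapply(seq_len(nph), function(j) id(i + 1L, j + 1L), integer(1))
      Fs[[length(Fs) + 1L]] <- rbind(cbind(a, b, c2), cbind(b, d2, c2))
    }
  }
  south <- nrow(V)
  Fs[[length(Fs) + 1L]] <-
    cbind(south, vapply(seq_len(nph), function(j) id(nring, j + 1L), integer(1)),
          vapply(seq_len(nph), function(j) id(nring, j), integer(1)))
  F <- do.call(rbind, Fs)
  R <- rotation_to_direction(pole_dir)
  shoulder_mesh(sweep((V %*% t(R)) * radius, 2, center, "+"), F)
}

# Axis-aligned box with gridded faces (corner vertices exact).
box_mesh <- function(lo, hi, edge_length = 1) {
  gridface <- function(uax, vax, wax, wval, flip) {
    nu <- max(1L, as.integer(ceiling((hi[uax] - lo[uax]) / edge_length)))
    nv <- max(1L, as.integer(ceiling((hi[vax] - lo[vax]) / edge_length)))
    us <- seq(lo[uax], hi[uax], length.out = nu + 1)
    vs <- seq(lo[vax], hi[vax], length.out = nv + 1)
    g <- expand.grid(u = us, v = vs)
    V <- matrix(0, nrow(g), 3)
    V[, uax] <- g$u; V[, vax] <- g$v; V[, wax] <- wval
    id <- function(i, j) (j - 1L) * (nu + 1L) + i
    i <- rep(seq_len(nu), nv)
    j <- rep(seq_len(nv), each = nu)
    a <- id(i, j); b <- id(i + 1L, j); c2 <- id(i, j + 1L); d2 <- id(i + 1L, j + 1L)
    F <- rbind(cbind(a, b, d2), cbind(a, d2, c2))
    if (flip) F <- F[, c(1, 3, 2)]
    shoulder_mesh(V, F)
  }
  mesh_merge(
    gridface(1, 3, 2, lo[2], flip = TRUE),   # bottom (undersurface)
    gridface(1, 3, 2, hi[2], flip = FALSE),  # top
    gridface(1, 2, 3, lo[3], flip = FALSE),
    gridface(1, 2, 3, hi[3], flip = TRUE),
    gridface(2, 3, 1, lo[1], flip = FALSE),
    gridface(2, 3, 1, hi[1], flip = TRUE))
}

# Flat disc: concentric rings at constant angular resolution, normal n.
disc_mesh <- function(center, normal, radius, edge_length = 1) {
  nr <- max(2L, as.integer(ceiling(radius / edge_length)))
  na <- max(8L, as.integer(ceiling(2 * pi * radius / edge_length)))
  ph <- seq(0, 2 * pi, length.out = na + 1)[-(na + 1)]
  rs <- seq(0, radius, length.out = nr + 1)[-1]
  g <- expand.grid(ph = ph, r = rs)
  V2 <- rbind(c(0, 0), cbind(g$r * cos(g$ph), g$r * sin(g$ph)))
  id <- function(i, j) 1L + (i - 1L) * na + ((j - 1L) %% na) + 1L
  Fs <- list(cbind(1L, vapply(seq_len(na), function(j) id(1L, j), integer(1)),
                   vapply(seq_len(na), function(j) id(1L, j + 1L), integer(1))))
  if (nr > 1) {
    for (i in seq_len(nr - 1L)) {
      a <- vapply(seq_len(na), function(j) id(i, j), integer(1))
      b <- vapply(seq_len(na), function(j) id(i, j + 1L), integer(1))
      c2 <- vapply(seq_len(na), function(j) id(i + 1L, j), integer(1))
      d2 <- vapply(seq_len(na), function(j) id(i + 1L, j + 1L), integer(1))
      Fs[[length(Fs) + 1L]] <- rbind(cbind(a, b, d2), cbind(a, d2, c2))
    }
  }
  R <- rotation_to_direction(normal)
  V <- cbind(V2, 0) %*% t(R)
  shoulder_mesh(sweep(V, 2, center, "+"), do.call(rbind, Fs))
}

# Open cylinder from p0 to p1 (no caps).
cylinder_mesh <- function(p0, p1, radius, edge_length = 1) {
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  d <- axis / len
  nl <- max(1L, as.integer(ceiling(len / edge_length)))
  na <- max(8L, as.integer(ceiling(2 * pi * radius / edge_length)))
  ph <- seq(0, 2 * pi, length.out = na + 1)[-(na + 1)]
  ts <- seq(0, 1, length.out = nl + 1)
  g <- expand.grid(ph = ph, t = ts)
  ring <- cbind(radius * cos(g$ph), radius * sin(g$ph), g$t * len)
  R <- rotation_to_direction(d)
  V <- sweep(ring %*% t(R), 2, p0, "+")
  id <- function(i, j) (i - 1L) * na + ((j - 1L) %% na) + 1L
  Fs <- list()
  for (i in seq_len(nl)) {
    a <- vapply(seq_len(na), function(j) id(i, j), integer(1))
    b <- vapply(seq_len(na), function(j) id(i, j + 1L), integer(1))
    c2 <- vapply(seq_len(na), function(j) id(i + 1L, j), integer(1))
    d2 <- vapply(seq_len(na), function(j) id(i + 1L, j + 1L), integer(1))
    Fs[[length(Fs) + 1L]] <- rbind(cbind(a, b, d2), cbind(a, d2, c2))
  }
  shoulder_mesh(V, do.call(rbind, Fs))
}
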