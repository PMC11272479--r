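# Shared fixtures and independent oracles for the test suite. Meshes are
# generated in code at test time; the limb fixture is cached per session.

.fixtures <- new.env(parent = emptyenv())

test_limb <- function(n_angular = 96, n_axial = 64) {
  key <- sprintf("limb_%d_%d", n_angular, n_axial)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_limb(limb_spec(n_angular = n_angular,
                                                n_axial = n_axial))
  }
  .fixtures[[key]]
}

# mid-sized realistic profile (category mid values)
test_profile <- function() {
  rectification_profile(PT = 5.8, FH = 2.1, MP = 3.2, LP = 3.6,
                        TC = 2.7, DE = 5.8, LMC = 5.5, VR = 4.3)
}

profile_sizes <- function(p) {
  unlist(p[c("PT", "FH", "MP", "LP", "TC", "DE", "LMC")])
}

# open cylinder (no caps), axis +z starting at z = 0
make_cylinder <- function(radius = 10, length = 200, n_angular = 360,
                          n_rings = 50, taper_to = radius) {
  th <- 2 * pi * (seq_len(n_angular) - 1) / n_angular
  z <- seq(0, length, length.out = n_rings)
  r <- seq(radius, taper_to, length.out = n_rings)
  V <- cbind(rep(r, each = n_angular) * cos(rep(th, n_rings)),
             rep(r, each = n_angular) * sin(rep(th, n_rings)),
             rep(z, each = n_angular))
  i <- rep(seq_len(n_angular), n_rings - 1)
  j <- rep(seq_len(n_rings - 1), each = n_angular)
  a <- (j - 1) * n_angular + i
  b <- (j - 1) * n_angular + (i %% n_angular) + 1
  cc <- j * n_angular + i
  d <- j * n_angular + (i %% n_angular) + 1
  surface_mesh(V, rbind(cbind(a, b, d), cbind(a, d, cc)))
}

# surface of revolution with an arbitrary radius profile
make_revolution <- function(radius_fun, length = 100, n_angular = 180,
                            n_rings = 60) {
  make_cyl <- make_cylinder(1, length, n_angular, n_rings)
  z <- make_cyl$vertices[, 3]
  r <- radius_fun(z)
  V <- cbind(make_cyl$vertices[, 1] * r, make_cyl$vertices[, 2] * r, z)
  surface_mesh(V, make_cyl$faces)
}

make_cube <- function() {
  V <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  F <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = 0
    c(5, 6, 8), c(5, 8, 7),   # z = 1
    c(1, 2, 6), c(1, 6, 5),   # y = 0
    c(3, 7, 8), c(3, 8, 4),   # y = 1
    c(1, 5, 7), c(1, 7, 3),   # x = 0
    c(2, 4, 8), c(2, 8, 6))   # x = 1
  surface_mesh(V, F)
}

# regular icosahedron: exactly isotropic vertex covariance
make_icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
             c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
             c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  surface_mesh(V, F)
}

tetra_stl_text <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  lines <- c("solid tetra")
  for (i in seq_len(nrow(f))) {
    lines <- c(lines, "  facet normal 0 0 0", "    outer loop",
               sprintf("      vertex %g %g %g", v[f[i, ], 1], v[f[i, ], 2],
                       v[f[i, ], 3]),
               "    endloop", "  endfacet")
  }
  c(lines, "endsolid tetra")
}

# random rigid transform with bounded magnitude
random_pose <- function(max_angle_deg, max_trans_mm) {
  ax <- stats::rnorm(3)
  rigid_transform(rotation_about_axis(ax, stats::runif(1, 0, max_angle_deg)),
                  stats::runif(3, -1, 1) * max_trans_mm / sqrt(3))
}

# --- independent oracles -----------------------------------------------------

# exhaustive Mann-Whitney two-sided p: enumerate all group-A assignments
mwu_enumerate <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(ix) sum(rk[ix]) - na * (na + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p = min(1, p))
}

# Spearman rho by the explicit midrank Pearson formula
spearman_direct <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# closest distance from point p to triangle (a, b, c) by dense barycentric
# sampling -- slow but independent of the compiled implementation
pt_tri_dist_sampled <- function(p, a, b, c, n = 60) {
  s <- seq(0, 1, length.out = n)
  best <- Inf
  for (u in s) {
    vmax <- 1 - u
    vs <- seq(0, vmax, length.out = max(2, ceiling(n * vmax)))
    q <- outer(rep(1, length(vs)), a) + u * outer(rep(1, length(vs)), b - a)
    q <- q + vs %o% (c - a)
    best <- min(best, min(sqrt(rowSums((q - outer(rep(1, length(vs)), p))^2))))
  }
  best
}

# section area oracle: collect the plane-crossing segments with independent
# code, then integrate r(theta)^2 / 2 with planar rays from the centroid
# (valid for the star-shaped sections used in tests)
section_area_polar <- function(mesh, z_level, n_rays = 1440) {
  V <- mesh$vertices
  F <- mesh$faces
  d <- V[, 3] - z_level
  segs <- list()
  for (f in seq_len(nrow(F))) {
    vid <- F[f, ]
    dv <- d[vid]
    if (min(dv) >= 0 || max(dv) <= 0) next
    pts <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      if (dv[e[1]] * dv[e[2]] < 0) {
        tt <- dv[e[1]] / (dv[e[1]] - dv[e[2]])
        pts[[length(pts) + 1]] <-
          V[vid[e[1]], 1:2] + tt * (V[vid[e[2]], 1:2] - V[vid[e[1]], 1:2])
      }
    }
    if (length(pts) == 2) segs[[length(segs) + 1]] <- unlist(pts)
  }
  S <- do.call(rbind, segs)  # x1 y1 x2 y2
  ctr <- colMeans(rbind(S[, 1:2], S[, 3:4]))
  p1x <- S[, 1] - ctr[1]; p1y <- S[, 2] - ctr[2]
  ex <- S[, 3] - S[, 1]; ey <- S[, 4] - S[, 2]
  th <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  r <- vapply(th, function(t_) {
    dx <- cos(t_); dy <- sin(t_)
    den <- -dx * ey + dy * ex
    ok <- abs(den) > 1e-14
    tt <- (-p1x * ey + p1y * ex) / den
    ss <- (dx * p1y - dy * p1x) / den
    hit <- ok & tt > 0 & ss >= -1e-12 & ss <= 1 + 1e-12
    if (!any(hit)) 0 else max(tt[hit])
  }, numeric(1))
  sum(r^2) / 2 * (2 * pi / n_rays)
}
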