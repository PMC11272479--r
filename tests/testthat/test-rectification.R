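test_that("deviation map is zero for an identical pair and signed correctly", {
  limb <- test_limb()
  m0 <- compute_deviation_map(limb$mesh, limb$mesh)
  expect_lt(max(abs(unclass(m0)), na.rm = TRUE), 1e-9)

  # shrinking a cylinder by 2 mm radially gives +2 mm carve on the barrel
  cyl <- make_cylinder(30, 150, 120, 40)
  small <- surface_mesh(cbind(cyl$vertices[, 1] * 28 / 30,
                              cyl$vertices[, 2] * 28 / 30,
                              cyl$vertices[, 3]), cyl$faces)
  dev <- unclass(compute_deviation_map(cyl, small))
  barrel <- cyl$vertices[, 3] > 20 & cyl$vertices[, 3] < 130
  expect_equal(median(dev[barrel], na.rm = TRUE), 2, tolerance = 0.01)

  # an outward distal bulge reads as build (negative) at its apex
  limb2 <- test_limb()
  sock <- generate_socket(limb2, rectification_profile(DE = 4))
  dev2 <- unclass(compute_deviation_map(limb2$mesh, sock$mesh))
  apex <- which.max(limb2$mesh$vertices[, 3])
  expect_equal(dev2[apex], -4, tolerance = 0.04)

  # wholly disjoint meshes cannot be mapped
  far <- apply_transform(limb$mesh, rigid_transform(diag(3), c(500, 0, 0)))
  expect_error(compute_deviation_map(limb$mesh, far), "disjoint")
})

test_that("region size is the direction-oriented 98th percentile, floored at 0", {
  limb <- test_limb()
  nv <- nrow(limb$mesh$vertices)
  mask <- limb$masks$MP

  const <- structure(rep(3, nv), class = "deviation_map")
  expect_equal(as.numeric(region_size(const, mask, "carve")), 3)
  # opposite direction floors at 0 but keeps the raw value
  s <- region_size(const, mask, "build")
  expect_equal(as.numeric(s), 0)
  expect_equal(attr(s, "raw"), -3)

  # linear ramp over 1000 vertices: 98th percentile by order statistics
  ramp_vals <- seq(0, 1, length.out = 1000)
  ramp <- structure(c(ramp_vals, rep(NA, nv - 1000)), class = "deviation_map")
  expect_equal(as.numeric(region_size(ramp, 1:1000, "carve")),
               as.numeric(quantile(ramp_vals, 0.98)), tolerance = 1e-12)
  expect_equal(as.numeric(region_size(ramp, 1:1000, "carve")), 0.98,
               tolerance = 2e-3)

  # permutation invariance and the never-exceeds-max property
  set.seed(5)
  perm <- sample(mask)
  noisy <- structure(rnorm(nv, 1, 0.5), class = "deviation_map")
  expect_identical(region_size(noisy, mask, "carve"),
                   region_size(noisy, perm, "carve"))
  expect_lte(as.numeric(region_size(noisy, mask, "carve")),
             max(unclass(noisy)[mask]))

  expect_error(region_size(const, 1:5, "carve", region = "PT"), "PT")
})

test_that("a wide Gaussian carve bump is recovered near its peak size", {
  limb <- test_limb(144, 96)               # finer mesh: several hundred
  mask <- limb$masks$MP                    # vertices inside one bump s.d.
  V <- limb$mesh$vertices
  ctr <- colMeans(V[mask, ])
  d2 <- rowSums(sweep(V, 2, ctr)^2)
  sigma <- sqrt(max(d2[mask])) / 1.5
  field <- 5 * exp(-d2 / (2 * sigma^2))
  expect_gt(sum(field[mask] > 5 * exp(-0.5)), 200)
  map <- structure(field, class = "deviation_map")
  expect_equal(as.numeric(region_size(map, mask, "carve")), 5, tolerance = 0.1)
})

test_that("volume reduction matches closed forms and an independent section oracle", {
  limb <- test_limb()
  expect_equal(as.numeric(volume_reduction(limb$mesh, limb$mesh,
                                           limb$landmarks)), 0,
               tolerance = 1e-9)

  # radial scaling by 0.97 reduces every section by exactly 1 - 0.97^2
  Vs <- limb$mesh$vertices
  scaled <- surface_mesh(cbind(Vs[, 1] * 0.97, Vs[, 2] * 0.97, Vs[, 3]),
                         limb$mesh$faces)
  expect_equal(as.numeric(volume_reduction(limb$mesh, scaled, limb$landmarks)),
               (1 - 0.97^2) * 100, tolerance = 0.1)

  # local-bump-only socket against the independent polar-integration oracle
  sock <- generate_socket(limb, rectification_profile(MP = 4, TC = 3))
  vr <- volume_reduction(limb$mesh, sock$mesh, limb$landmarks)
  per <- attr(vr, "per_section")
  pa <- principal_axis(limb$mesh)
  z_world <- vapply(per$level, function(l) (pa$centroid + l * pa$axis)[3],
                    numeric(1))
  oracle <- mean(vapply(z_world, function(z0) {
    al <- section_area_polar(limb$mesh, z0, n_rays = 720)
    as <- section_area_polar(sock$mesh, z0, n_rays = 720)
    (al - as) / al
  }, numeric(1))) * 100
  expect_equal(as.numeric(vr), oracle, tolerance = 0.05)

  # VR is invariant under a joint rigid motion of the pair
  t1 <- rigid_transform(rotation_about_axis(c(1, 2, 0.5), 40), c(30, -12, 8))
  vr_moved <- volume_reduction(apply_transform(limb$mesh, t1),
                               apply_transform(scaled, t1),
                               landmark_set(rt_apply_points(t1, limb$landmarks)))
  expect_equal(as.numeric(vr_moved), (1 - 0.97^2) * 100, tolerance = 0.1)
})

test_that("extract_profile recovers a known mid-sized design within tolerance", {
  limb <- test_limb()
  expect_true(all(profile_sizes(extract_profile(limb$mesh, limb$mesh,
                                                limb$landmarks, limb$masks))
                  < 1e-6))

  prof <- test_profile()
  sock <- generate_socket(limb, prof)
  got <- extract_profile(limb$mesh, sock$mesh, limb$landmarks, limb$masks)
  truth <- profile_sizes(prof)
  est <- profile_sizes(got)
  expect_true(all(abs(est - truth) / truth < 0.10))
  expect_lt(abs(got$VR - prof$VR), 0.5)

  # a region starved of usable vertices errors with its name
  bad_masks <- unclass(limb$masks)
  bad_masks$FH <- bad_masks$FH[1:4]
  expect_error(extract_profile(limb$mesh, sock$mesh, limb$landmarks,
                               region_mask_set(bad_masks)), "FH")
})

test_that("global socket scaling moves deviations monotonically toward carve", {
  limb <- test_limb()
  meds <- vapply(c(0.95, 1.0, 1.05), function(s) {
    Vs <- limb$mesh$vertices
    sock <- surface_mesh(cbind(Vs[, 1] * s, Vs[, 2] * s, Vs[, 3]),
                         limb$mesh$faces)
    dev <- unclass(compute_deviation_map(limb$mesh, sock))
    barrel <- limb$param$z > 30 & limb$param$z < 120
    median(dev[barrel], na.rm = TRUE)
  }, numeric(1))
  expect_gt(meds[1], meds[2])
  expect_gt(meds[2], meds[3])
  expect_gt(meds[1], 0)  # shrunk socket = carve
  expect_lt(meds[3], 0)  # inflated socket = build
})
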