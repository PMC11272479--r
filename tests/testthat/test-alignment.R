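test_that("coarse alignment recovers a known displacement from landmarks", {
  limb <- test_limb()
  pose <- rigid_transform(rotation_about_axis(c(0.2, 1, 0.4), 8), c(9, -8, 8))
  socket <- apply_transform(limb$mesh, pose)
  lm_s <- landmark_set(rt_apply_points(pose, limb$landmarks))
  tr <- coarse_align(limb$mesh, socket, limb$landmarks, lm_s)
  err <- rt_magnitude(rt_compose(tr, pose))
  expect_lt(err$angle_deg, 0.1)
  expect_lt(err$translation_mm, 0.1)

  # already aligned: identity
  tr0 <- coarse_align(limb$mesh, limb$mesh, limb$landmarks, limb$landmarks)
  expect_lt(rt_magnitude(tr0)$angle_deg, 1e-6)
  expect_lt(rt_magnitude(tr0)$translation_mm, 1e-6)

  lm_partial <- landmark_set(list(mid_patella = lm_s["mid_patella", ]),
                             require = "mid_patella")
  expect_error(coarse_align(limb$mesh, socket, limb$landmarks, lm_partial),
               "missing landmark: distal_tibia")
})

test_that("coarse alignment under landmark noise reports a bounded residual RMS", {
  limb <- test_limb()
  set.seed(11)
  pose <- random_pose(6, 8)
  socket <- apply_transform(limb$mesh, pose)
  noisy <- rt_apply_points(pose, limb$landmarks) +
    matrix(rnorm(9, 0, 2 / sqrt(3)), 3, 3)  # ~2 mm displacement per landmark
  lm_s <- landmark_set(noisy)
  tr <- coarse_align(limb$mesh, socket, limb$landmarks, lm_s)
  expect_gte(attr(tr, "rms"), 0)
  expect_lte(attr(tr, "rms"), 4)
  # residual RMS agrees with an independent numeric rigid fit on the same
  # point pairs (general-purpose optimisation, no SVD closed form)
  pa_l <- principal_axis(limb$mesh)
  pa_s <- principal_axis(socket)
  src <- rbind(lm_s["mid_patella", ], lm_s["distal_tibia", ], pa_s$centroid)
  tgt <- rbind(limb$landmarks["mid_patella", ],
               limb$landmarks["distal_tibia", ], pa_l$centroid)
  obj <- function(par) {
    R <- rotation_about_axis(par[1:3] + 1e-9, sqrt(sum(par[1:3]^2)) * 180 / pi)
    fit <- sweep(src %*% t(R), 2, par[4:6], "+")
    mean(rowSums((fit - tgt)^2))
  }
  opt <- optim(rep(0, 6), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  expect_equal(attr(tr, "rms"), sqrt(opt$value), tolerance = 1e-3)
})

test_that("ICP recovers residual pose error on identical-geometry pairs", {
  # a pure surface of revolution leaves rotation about its own axis
  # unobservable to ICP (that mode is fixed by the landmark stage), so the
  # ICP test deforms the limb with a fixed asymmetric radial modulation
  base <- test_limb()
  V <- base$mesh$vertices
  th <- atan2(V[, 2], V[, 1])
  mod <- 1 + 0.06 * sin(6 * th + 0.7) * sin(2 * pi * V[, 3] / 60)
  mesh <- surface_mesh(cbind(V[, 1] * mod, V[, 2] * mod, V[, 3]),
                       base$mesh$faces)
  pose <- rigid_transform(rotation_about_axis(c(1, 0.6, 0.8), 5),
                          c(2.5, -2.5, 2.9))
  perturbed <- apply_transform(mesh, pose)
  limb <- list(mesh = mesh, anterior = base$anterior)
  res <- icp_align(limb$mesh, perturbed, limb$anterior, max_iter = 400)
  err <- rt_magnitude(rt_compose(res$transform, pose))
  expect_lt(err$angle_deg, 0.5)
  expect_lt(err$translation_mm, 0.5)
  expect_true(res$converged)
  # RMS trace is non-increasing
  expect_true(all(diff(res$rms_trace) <= 1e-9))

  # already registered: immediate convergence to identity
  res0 <- icp_align(limb$mesh, mesh, limb$anterior)
  expect_lte(res0$iterations, 2)
  expect_lt(rt_magnitude(res0$transform)$translation_mm, 1e-4)

  # contract: max_iter = 0 returns the identity, not converged
  resn <- icp_align(limb$mesh, perturbed, limb$anterior, max_iter = 0)
  expect_equal(resn$transform$rotation, diag(3))
  expect_false(resn$converged)
  expect_error(icp_align(limb$mesh, perturbed, integer(0)), "empty")
})

test_that("align_pair composes its stages and honours the override slot", {
  limb <- test_limb()
  sock <- generate_socket(limb, test_profile())
  al0 <- align_pair(limb$mesh, sock$mesh, limb$landmarks, limb$landmarks,
                    limb$anterior)
  al1 <- align_pair(limb$mesh, sock$mesh, limb$landmarks, limb$landmarks,
                    limb$anterior, override = rt_identity())
  expect_equal(al1$transform$rotation, al0$transform$rotation, tolerance = 1e-12)
  expect_equal(al1$transform$translation, al0$transform$translation,
               tolerance = 1e-12)

  # a known correction composes exactly on a deliberately mis-landmarked pair
  bad_lm <- limb$landmarks
  bad_lm["mid_patella", ] <- bad_lm["mid_patella", ] + c(4, 0, -3)
  corr <- rigid_transform(rotation_about_axis(c(0, 0, 1), 2), c(1, -1, 0.5))
  al2 <- align_pair(limb$mesh, sock$mesh, limb$landmarks,
                    landmark_set(bad_lm), limb$anterior)
  al3 <- align_pair(limb$mesh, sock$mesh, limb$landmarks,
                    landmark_set(bad_lm), limb$anterior, override = corr)
  expected <- rt_compose(corr, al2$transform)
  expect_equal(al3$transform$rotation, expected$rotation, tolerance = 1e-12)
  expect_equal(al3$transform$translation, expected$translation,
               tolerance = 1e-12)
})

test_that("align_pair is equivariant under a joint rotation of the scene", {
  limb <- test_limb()
  set.seed(31)
  pose <- random_pose(7, 6)
  sock <- generate_socket(limb, test_profile(), pose = pose)
  lm_s <- landmark_set(rt_apply_points(pose, limb$landmarks))
  al <- align_pair(limb$mesh, sock$mesh, limb$landmarks, lm_s, limb$anterior,
                   max_iter = 12)

  Q <- rigid_transform(rotation_about_axis(c(1, 0.5, -0.2), 23), c(5, 5, -10))
  limb_q <- apply_transform(limb$mesh, Q)
  sock_q <- apply_transform(sock$mesh, Q)
  al_q <- align_pair(limb_q, sock_q,
                     landmark_set(rt_apply_points(Q, limb$landmarks)),
                     landmark_set(rt_apply_points(Q, lm_s)),
                     limb$anterior, max_iter = 12)
  conj <- rt_compose(Q, rt_compose(al$transform, rt_inverse(Q)))
  expect_equal(al_q$transform$rotation, conj$rotation, tolerance = 1e-6)
  expect_equal(al_q$transform$translation, conj$translation, tolerance = 1e-5)
})

test_that("pose recovery holds across random perturbations up to 10 deg / 10 mm", {
  limb <- test_limb()
  sock0 <- generate_socket(limb, rectification_profile())
  for (s in 1:5) {
    set.seed(100 + s)
    pose <- random_pose(10, 10)
    perturbed <- apply_transform(sock0$mesh, pose)
    lm_s <- landmark_set(rt_apply_points(pose, limb$landmarks))
    al <- align_pair(limb$mesh, perturbed, limb$landmarks, lm_s, limb$anterior)
    err <- rt_magnitude(rt_compose(al$transform, pose))
    expect_lt(err$angle_deg, 0.5)
    expect_lt(err$translation_mm, 0.5)
  }
})
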