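#!/usr/bin/env Rscript
# Stage 1: build the synthetic study inputs.
#
# Emits (a) six limb/socket scan pairs with known rectification profiles and
# rigid pose perturbations, laid out as the file set a clinical extraction
# batch would use (STL meshes, landmark/mask JSON, a manifest CSV), and (b) a
# 163-socket design cohort drawn from the published correlation pattern with
# the distal-end/volume-reduction conditional rule imposed.

suppressPackageStartupMessages(library(socketmap))

seed <- 20260101L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

limb <- generate_limb(limb_spec())  # default 180 x 120 resolution
marg <- socketmap:::default_marginals()

rows <- list()
for (i in 1:6) {
  set.seed(seed + i)
  draw <- vapply(marg, function(m) max(0.5, rnorm(1, m[["mean"]], m[["sd"]])),
                 numeric(1))
  prof <- rectification_profile(PT = draw[["PT"]], FH = draw[["FH"]],
                                MP = draw[["MP"]], LP = draw[["LP"]],
                                TC = draw[["TC"]], DE = draw[["DE"]],
                                LMC = draw[["LMC"]], VR = draw[["VR"]],
                                socket_id = sprintf("SYN%02d", i))
  pose <- rigid_transform(rotation_about_axis(rnorm(3), runif(1, 0, 8)),
                          runif(3, -5, 5))
  sock <- generate_socket(limb, prof, pose = pose, seed = seed + i)
  paths <- write_pair_fixture(limb, sock, file.path(out, sprintf("pair%02d", i)))
  rows[[i]] <- data.frame(socket_id = sprintf("SYN%02d", i),
                          limb = paths$limb, socket = paths$socket,
                          landmarks_limb = paths$landmarks_limb,
                          landmarks_socket = paths$landmarks_socket,
                          masks = paths$masks, anterior = paths$anterior,
                          design = sample(c("PTB", "TSB"), 1, prob = c(.85, .15)),
                          truth = paths$truth)
  cat(sprintf("pair %d: VR %.1f%%, local sizes %.1f-%.1f mm, pose %.1f deg\n",
              i, prof$VR, min(unlist(prof[names(region_directions())])),
              max(unlist(prof[names(region_directions())])),
              rt_magnitude(pose)$angle_deg))
}
manifest <- do.call(rbind, rows)
write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)

rules <- list(list(target = "DE", conditioning = "VR", prob = 0.5))
cohort <- generate_cohort_table(163, cohort_structure(rules = rules),
                                seed = seed)
write.csv(cohort, "results/cohort_synthetic.csv", row.names = FALSE)
cat(sprintf("\ncohort: %d sockets (%d PTB / %d TSB / %d PTB-SC), %d flagged oversized\n",
            nrow(cohort), sum(cohort$design == "PTB"),
            sum(cohort$design == "TSB"), sum(cohort$design == "PTB-SC"),
            sum(cohort$vr_oversized)))
cat("wrote", file.path(out, "manifest.csv"), "and results/cohort_synthetic.csv\n")
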