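#!/usr/bin/env Rscript
# Stage 2: align each limb/socket pair and extract its rectification profile.
#
# Runs the full per-socket pipeline (coarse landmark alignment, anterior
# sub-patellar ICP, normal-ray deviation mapping, 98th-percentile region
# sizing, 10-section volume reduction) over the manifest from stage 1, then
# scores the recovered design variables against the generator's ground truth.

suppressPackageStartupMessages(library(socketmap))

manifest <- read.csv("results/sim/manifest.csv", stringsAsFactors = FALSE)
res <- run_extract(manifest, out_csv = "results/extracted_profiles.csv",
                   seed = 20260101L)

cat(sprintf("%d/%d pairs extracted cleanly\n",
            sum(res$status == "ok"), nrow(res)))
cat(sprintf("ICP: %d-%d iterations, final RMS %.2f-%.2f mm\n",
            min(res$icp_iterations, na.rm = TRUE),
            max(res$icp_iterations, na.rm = TRUE),
            min(res$icp_rms, na.rm = TRUE), max(res$icp_rms, na.rm = TRUE)))

regions <- names(region_directions())
score <- lapply(seq_len(nrow(res)), function(i) {
  truth <- jsonlite::read_json(manifest$truth[i], simplifyVector = TRUE)$profile
  err <- vapply(regions, function(v) res[[v]][i] - truth[[v]], numeric(1))
  data.frame(socket_id = res$socket_id[i], t(err),
             VR_err = res$VR[i] - truth$VR)
})
score <- do.call(rbind, score)
write.csv(score, "results/extraction_errors.csv", row.names = FALSE)

cat("\nrecovery error vs ground truth (mm; VR in % points):\n")
print(round(score[, -1], 2))
cat(sprintf("\nmean |error|: local %.2f mm, VR %.2f points\n",
            mean(abs(as.matrix(score[regions]))), mean(abs(score$VR_err))))
cat("note: residual ~1 mm anterior bias is the masked-ICP effect discussed in\n")
cat("the methods vignette; extraction on exactly aligned pairs is unbiased.\n")
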