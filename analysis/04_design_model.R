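#!/usr/bin/env Rscript
# Stage 4: the probabilistic design model.
#
# Fits the KDE size categories (cuts at the 33rd/67th percentiles, exemplars
# at the 10th/50th/90th) for all eight design variables, the pairwise
# Gaussian naive Bayes conditional probabilities, and the most-probable
# template designs following a prior decision of high or low volume
# reduction, rendered onto a synthetic limb as PLY deviation maps.

suppressPackageStartupMessages(library(socketmap))

cohort <- read.csv("results/cohort_synthetic.csv", stringsAsFactors = FALSE)
limb <- generate_limb(limb_spec())

files <- run_analysis(cohort, "results/model",
                      config = list(seed = 20260101L, limb = limb))
cat("wrote", length(files), "files under results/model\n\n")

cats <- read.csv("results/model/categories.csv", comment.char = "#")
cat("size categories (exemplars low / mid / high):\n")
print(data.frame(variable = cats$variable,
                 low = round(cats$exemplar_low, 1),
                 mid = round(cats$exemplar_mid, 1),
                 high = round(cats$exemplar_high, 1)))

pp <- read.csv("results/model/pairwise_probabilities.csv", comment.char = "#")
de_vr <- pp[pp$target == "DE" & pp$conditioning == "VR" &
              pp$conditioning_category == "high", ]
cat(sprintf("\nP(DE category | VR at its high exemplar): low %.0f%%, mid %.0f%%, high %.0f%%\n",
            100 * de_vr$p_low, 100 * de_vr$p_mid, 100 * de_vr$p_high))

for (choice in c("high", "low")) {
  tpl <- jsonlite::read_json(sprintf("results/model/template_VR_%s.json",
                                     choice), simplifyVector = TRUE)$template
  cat(sprintf("\ntemplate after choosing VR = %s:\n", choice))
  print(data.frame(variable = tpl$variable, category = tpl$category,
                   exemplar = round(tpl$exemplar, 1)))
}
cat("\nrendered maps: results/model/template_VR_{high,low}_map.ply\n")
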