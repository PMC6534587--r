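#!/usr/bin/env Rscript
# Step 4: inclination-line analysis.
#
# Fits y = a x + b to every rat apex-to-root profile by vertical least
# squares and summarizes slopes per stage, split into positive and negative
# groups. Control lines should be uniformly shallow-positive; lesion stages
# mix signs with growing spread.

suppressPackageStartupMessages(library(fiquant))

df <- read.csv("results/profiles_rat.csv")
profs <- lapply(split(df, df$sample_id), function(d) {
  d <- d[order(d$position), ]
  measurement_profile(d$gvalue, d$position, d$stage_label[1], d$sample_id[1])
})
fits <- lapply(profs, fit_inclination)

per_sample <- do.call(rbind, lapply(fits, function(f) {
  data.frame(sample_id = f$sample_id, stage_label = f$stage_label,
             slope_a = f$slope_a, intercept_b = f$intercept_b,
             sign = f$sign, residual_rms = f$residual_rms)
}))
write.csv(per_sample, "results/inclination_per_sample.csv", row.names = FALSE)

stages <- vapply(fits, function(f) f$stage_label, character(1))
summary_tab <- do.call(rbind, lapply(unique(stages), function(lab) {
  slope_group_summary(fits[stages == lab], stage_label = lab)
}))
write.csv(summary_tab, "results/inclination_groups.csv", row.names = FALSE)

cat("slope summary per stage (G-value per pixel):\n")
print(cbind(summary_tab[, c("stage_label", "n", "n_positive", "n_negative")],
            round(summary_tab[, c("mean_slope", "mean_positive", "mean_negative")], 3)))
cat(sprintf("\nControl slopes all positive: %s\n",
            summary_tab$n_negative[summary_tab$stage_label == "Control"] == 0))
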