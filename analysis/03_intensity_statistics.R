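#!/usr/bin/env Rscript
# Step 3: intensity statistics.
#
# Per-sample and pooled per-stage summaries of the measured G-values (the
# group-statistics table of the analysis), the per-stage mean within-sample
# SD (the variation table), and the pixel-distribution histogram that shows
# scattering widening with tumor progression.

suppressPackageStartupMessages(library(fiquant))

read_profiles <- function(model) {
  df <- read.csv(file.path("results", paste0("profiles_", model, ".csv")))
  lapply(split(df, df$sample_id), function(d) {
    d <- d[order(d$position), ]
    measurement_profile(d$gvalue, d$position, d$stage_label[1], d$sample_id[1])
  })
}

for (model in c("rat", "human")) {
  profs <- read_profiles(model)
  stages <- vapply(profs, function(p) p$stage_label, character(1))
  by_stage <- split(profs, factor(stages, levels = unique(stages)))

  per_sample <- do.call(rbind, lapply(profs, summarize_sample))
  write.csv(per_sample, sprintf("results/per_sample_%s.csv", model), row.names = FALSE)

  groups <- do.call(rbind, lapply(names(by_stage), function(lab) {
    summarize_group(by_stage[[lab]], stage_label = lab)
  }))
  write.csv(groups, sprintf("results/group_summary_%s.csv", model), row.names = FALSE)

  within <- data.frame(
    stage_label = names(by_stage),
    mean_within_sd = vapply(by_stage, function(ps) {
      mean(vapply(ps, function(p) sample_sd(p$values), numeric(1)))
    }, numeric(1))
  )
  write.csv(within, sprintf("results/within_sd_%s.csv", model), row.names = FALSE)

  dist_tab <- scatter_distribution(by_stage, bin_width = 1)
  jsonlite::write_json(dist_tab, sprintf("results/distribution_%s.json", model),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cat(sprintf("\n== %s group summary (pooled pixels) ==\n", model))
  print(cbind(groups[, c("stage_label", "n_samples")],
              round(groups[, c("mean", "sd", "median", "min", "max", "range")], 1),
              mean_pcc = round(groups$mean_pcc, 2)))
  cat("mean within-sample SD per stage:\n")
  print(transform(within, mean_within_sd = round(mean_within_sd, 2)))
}
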