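#!/usr/bin/env Rscript
# Step 1: generate the synthetic cohorts.
#
# The rat cohort emulates the four-stage carcinogenesis model (Control,
# LGD, HGD/CIS, Cancer; 10/11/15/14 animals, 200-pixel measurement lines);
# the human run is the four single-site measurement lines (50 px) of the
# clinical application. Each run writes 8-bit RGB PNGs (signal in the green
# channel) plus a truth.json with every latent draw.

suppressPackageStartupMessages(library(fiquant))
seed <- 20190524

dir.create("results", showWarnings = FALSE)
rat <- generate_cohort(rat_stage_presets(), seed, "results/cohort_rat", force = TRUE)
hum <- generate_cohort(human_site_presets(), seed + 1, "results/cohort_human", force = TRUE)

cat(sprintf("rat cohort: %d images (%s)\n", nrow(rat),
            paste(table(rat$stage_label)[unique(rat$stage_label)], collapse = "/")))
cat(sprintf("human sites: %d images\n", nrow(hum)))
cat("per-animal mean G-values drawn per stage:\n")
print(aggregate(animal_mean ~ stage_label, rat, function(x) round(mean(x), 1)))
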