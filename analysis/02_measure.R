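#!/usr/bin/env Rscript
# Step 2: measure the cohorts.
#
# Every rendered image is reloaded from disk (so quantization is included),
# the apex-to-root measurement line is sampled at the image mid-height, and
# the long table of per-pixel G-values is written for the downstream
# statistics scripts. One surface plot per stage illustrates the height-map
# view of the fluorescence field.

suppressPackageStartupMessages(library(fiquant))

measure_cohort <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  mid_y <- (truth$height - 1) %/% 2
  line <- line_spec(c(0, mid_y), c(truth$n_points - 1, mid_y), truth$n_points)
  do.call(rbind, lapply(truth$animals, function(rec) {
    img <- load_gvalue_image(file.path(dir, rec$file))
    prof <- extract_line_profile(img, line, stage_label = rec$stage_label,
                                 sample_id = rec$animal_id)
    data.frame(sample_id = rec$animal_id, stage_label = rec$stage_label,
               position = prof$positions, gvalue = prof$values)
  }))
}

for (model in c("rat", "human")) {
  prof <- measure_cohort(file.path("results", paste0("cohort_", model)))
  out <- file.path("results", paste0("profiles_", model, ".csv"))
  write.csv(prof, out, row.names = FALSE)
  cat(sprintf("%s: %d samples x %d pixels -> %s\n", model,
              length(unique(prof$sample_id)), max(table(prof$sample_id)), out))
}

# surface plots of the first rat animal per stage (3x3 box smoothing)
truth <- jsonlite::read_json("results/cohort_rat/truth.json")
seen <- character(0)
for (rec in truth$animals) {
  if (rec$stage_label %in% seen) next
  seen <- c(seen, rec$stage_label)
  img <- load_gvalue_image(file.path("results/cohort_rat", rec$file))
  z <- surface_matrix(img, smooth = 3)
  png(file.path("results", paste0("surface_", rec$stage_label, ".png")), 640, 480)
  persp(z = t(z), theta = 30, phi = 30, expand = 0.4, col = "palegreen3",
        border = NA, shade = 0.6, xlab = "apex -> root", ylab = "",
        zlab = "G-value", main = paste("Fluorescence surface:", rec$stage_label),
        zlim = c(0, 120))
  dev.off()
}
cat("surface plots:", paste(seen, collapse = ", "), "\n")
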