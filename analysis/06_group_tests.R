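#!/usr/bin/env Rscript
# Step 6: omnibus and many-to-one group tests.
#
# One-way ANOVA across the four rat stages and Monte-Carlo Dunnett
# comparisons of every lesion stage against Control, on per-animal mean
# G-values (pixels within an animal are pseudo-replicates and are averaged
# first).

suppressPackageStartupMessages(library(fiquant))
seed <- 20190524

df <- read.csv("results/profiles_rat.csv")
animal_means <- aggregate(gvalue ~ sample_id + stage_label, df, mean)
groups <- split(animal_means$gvalue, animal_means$stage_label)
groups <- groups[c("Control", "LGD", "HGD_CIS", "Cancer")]

aov_res <- anova_oneway(groups)
cat(sprintf("one-way ANOVA: F(%d, %d) = %.2f, p = %.3g\n",
            aov_res$df_between, aov_res$df_within, aov_res$statistic, aov_res$p))

dun <- dunnett_many_to_one(groups, reference_index = 1, n_mc = 1e5, seed = seed)
cat(sprintf("Dunnett vs Control (MC critical value %.3f):\n",
            attr(dun, "critical_value")))
print(as.data.frame(dun), digits = 3)

out <- rbind(
  data.frame(comparison_label = "one-way ANOVA (all stages)",
             statistic = aov_res$statistic, p_adjusted = aov_res$p,
             significant = aov_res$p < 0.05),
  as.data.frame(dun)
)
write.csv(out, "results/group_tests_rat.csv", row.names = FALSE)
cat(sprintf("\nall lesion stages significantly brighter than Control: %s\n",
            all(dun$significant)))
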