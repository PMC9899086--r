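#!/usr/bin/env Rscript
# Stage 6: per-driver significance against both genetic controls
# (normality triage -> ANOVA/Bonferroni or Kruskal-Wallis/Dunn) and the
# power analysis at the study's sample sizes.
# Output: results/tables/screen_stats.csv, power.csv

source("analysis/00_config.R")
suppressMessages(library(data.table))

deltas <- fread(file.path(tables_dir, "per_fly_deltas.csv"))
stats_tbl <- screen_stats(deltas, alpha = 0.05)
fwrite(stats_tbl, file.path(tables_dir, "screen_stats.csv"))

sig <- unique(stats_tbl[significant_overall == TRUE,
                        .(driver, parameter, phase)])
cat(sprintf("%d driver x parameter x phase effects pass the both-controls rule\n",
            nrow(sig)))

# power at the study's n: null at the GAL4 control's delta mean/SD,
# alternative at the experimental delta mean
power_tbl <- sig[, {
  sub <- deltas[driver == .BY$driver & parameter == .BY$parameter &
                  phase == .BY$phase]
  ctrl <- sub[genotype_role == "gal4_control", value]
  expv <- sub[genotype_role == "experimental", value]
  .(n_exp = length(expv), n_ctrl = length(ctrl),
    power = power_ttest(length(expv), length(ctrl),
                        mean(ctrl), sd(ctrl), mean(expv)))
}, by = .(driver, parameter, phase)]
fwrite(power_tbl, file.path(tables_dir, "power.csv"))
cat(sprintf("power > 0.9 for %.0f%% of significant effects\n",
            100 * mean(power_tbl$power > 0.9)))
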