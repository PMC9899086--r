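#!/usr/bin/env Rscript
# Stage 1: simulate the screen and write it in DAM2 format.
# Output: results/screen/Monitor*.txt, channel_map.csv, design.yaml,
#         ground_truth.json

source("analysis/00_config.R")

cfg <- screen_config()
scr <- simulate_screen(cfg, dir = screen_dir)

n_flies <- nrow(scr$channel_map)
cat(sprintf("simulated %d drivers x 3 genotypes x %d flies = %d flies\n",
            length(cfg$drivers), cfg$flies_per_genotype, n_flies))
cat(sprintf("wrote %d monitor files + channel map + design + ground truth to %s\n",
            length(scr$paths$monitors), screen_dir))
cat("planted effects: R4m wake-promoting (DP), R3d fragmenting (DP)\n")
cat("R4m drivers:", paste(cfg$drivers[cfg$subtype_matrix[, "R4m"] == 1],
                          collapse = " "), "\n")
cat("R3d drivers:", paste(cfg$drivers[cfg$subtype_matrix[, "R3d"] == 1],
                          collapse = " "), "\n")
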