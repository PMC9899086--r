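#!/usr/bin/env Rscript
# Stage 2: read the DAM files back through the io path, drop dead flies,
# score sleep bouts (>= 5 min inactivity) and estimate P(wake)/P(doze).
# Output: results/tables/sleep_metrics.csv, transitions.csv, survival.csv

source("analysis/00_config.R")
suppressMessages(library(data.table))
dir.create(tables_dir, recursive = TRUE, showWarnings = FALSE)

design_cfg <- yaml::read_yaml(file.path(screen_dir, "design.yaml"))
design <- experiment_design(design_cfg$baseline, design_cfg$activation,
                            design_cfg$recovery,
                            lights_on = design_cfg$lights_on)
cm <- read_channel_map(file.path(screen_dir, "channel_map.csv"))
monitors <- list.files(screen_dir, pattern = "^Monitor.*\\.txt$",
                       full.names = TRUE)
names(monitors) <- sub("\\.txt$", "", basename(monitors))
activity <- load_dam_screen(monitors, cm, design)

survival <- filter_dead_flies(activity, min_active_minutes_last_day = 1)
activity <- activity[fly_id %in% survival[keep == TRUE, fly_id]]
cat(sprintf("loaded %d flies (%d dropped dead)\n",
            sum(survival$keep), sum(!survival$keep)))

metrics <- sleep_metrics(activity, min_bout = 5)
transitions <- transition_estimates(activity)

fwrite(survival, file.path(tables_dir, "survival.csv"))
fwrite(metrics, file.path(tables_dir, "sleep_metrics.csv"))
fwrite(transitions, file.path(tables_dir, "transitions.csv"))

base <- metrics[day_role == "baseline",
                .(mean_sleep = mean(total_sleep)), by = phase]
cat(sprintf("baseline sleep: LP %.0f min, DP %.0f min (per fly)\n",
            base[phase == "LP", mean_sleep], base[phase == "DP", mean_sleep]))
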