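#!/usr/bin/env Rscript
# Stage 4: Gaussian-mixture clustering of driver points in
# (dP(wake), dP(doze)) space, k chosen from {3,4,5} by mean silhouette.
# Output: results/tables/clustering.csv, gmm_models.json

source("analysis/00_config.R")
suppressMessages(library(data.table))

points <- fread(file.path(tables_dir, "driver_points.csv"))
assignments <- list()
models <- list()
for (ph in c("LP", "DP")) {
  pts <- points[phase == ph & is.finite(d_p_wake) & is.finite(d_p_doze)]
  m <- as.matrix(pts[, .(d_p_wake, d_p_doze)])
  rownames(m) <- pts$driver
  res <- select_k(m, k_candidates = 3:5, seed = screen_seed)
  cat(sprintf("%s: k = %d (mean silhouettes: %s)\n", ph, res$chosen_k,
              paste(sprintf("k=%s %.3f", names(res$mean_silhouette),
                            res$mean_silhouette), collapse = ", ")))
  assignments[[ph]] <- data.table(driver = pts$driver, phase = ph,
                                  cluster = res$assignments)
  best <- res$models[[as.character(res$chosen_k)]]
  models[[ph]] <- list(
    chosen_k = res$chosen_k,
    mean_silhouette = as.list(res$mean_silhouette),
    weights = best$weights, means = best$means,
    covariances = lapply(seq_len(best$k), function(j) best$covariances[, , j]),
    ellipses_1sigma = lapply(seq_len(best$k),
                             function(j) cluster_ellipse(best, j, 1))
  )
}
fwrite(rbindlist(assignments), file.path(tables_dir, "clustering.csv"))
jsonlite::write_json(models, file.path(tables_dir, "gmm_models.json"),
                     auto_unbox = TRUE, digits = NA)
cat("wrote clustering.csv and gmm_models.json\n")
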