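#!/usr/bin/env Rscript
# Stage 5: binary subtype design-matrix model -- which ring-neuron
# subtypes explain each driver's change rate in each sleep parameter?
# Output: results/tables/subtype_glm.csv

source("analysis/00_config.R")
suppressMessages(library(data.table))

truth <- jsonlite::read_json(file.path(screen_dir, "ground_truth.json"),
                             simplifyVector = TRUE)
sm <- truth$subtype_matrix
X <- sapply(intersect(names(sm), RING_SUBTYPES), function(cn) sm[[cn]])
rownames(X) <- sm$driver
rates <- fread(file.path(tables_dir, "change_rates.csv"))

tab <- subtype_glm_table(X, rates, alpha = 0.05)
fwrite(tab, file.path(tables_dir, "subtype_glm.csv"))

sig <- tab[!is.na(effect) & effect != "none"]
cat("significant subtype effects (p < 0.05):\n")
print(sig[, .(parameter, phase, term, weight = round(weight, 3),
              p = signif(p, 3), effect)])
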