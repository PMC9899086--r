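Package: damscreen
Title: Thermogenetic Sleep-Screen Analysis for Drosophila Activity Monitor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis stack for thermogenetic Drosophila sleep screens recorded
    on Trikinetics Drosophila Activity Monitors (DAM2). Reads and validates
    monitor files, bins beam-break counts to one-minute resolution, scores
    sleep bouts (>= 5 min inactivity), and computes per-phase sleep metrics
    (total sleep, episode number, maximum episode length) together with the
    minute-to-minute behavioral transition probabilities P(wake) and P(doze).
    Effect sizes are baseline-subtracted and corrected against both genetic
    controls (GAL4-only and UAS-only); driver lines are clustered in
    (delta-P(wake), delta-P(doze)) space by full-covariance Gaussian mixtures
    with silhouette-based model selection, and ring-neuron subtype
    contributions are estimated by a binary design-matrix linear model.
    Includes a two-state Markov fly simulator that writes DAM2-format files
    with ground-truth annotations for end-to-end validation, and the screen's
    significance machinery (normality triage, ANOVA with planned Bonferroni
    comparisons, Kruskal-Wallis with Dunn's comparisons, the both-controls
    rule, and noncentral-t power analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr
Config/testthat/edition: 3
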