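# Shared configuration for the worked analysis: a 34-driver thermogenetic
# screen with two planted effects --
#   * R4m wake-promoting at night (logit +1.0 on p(wake), DP), and
#   * R3d fragmenting at night (logit +0.9 on p(doze), +0.325 on p(wake),
#     calibrated so scored total sleep stays level),
# 16 flies per genotype, 3 recorded days (baseline 21C / activation 30C /
# recovery 21C), 12h:12h LD.

library(damscreen)

screen_seed <- 2026L
screen_dir <- "results/screen"
tables_dir <- "results/tables"

screen_config <- function() {
  simulation_config(
    n_drivers = 34L,
    flies_per_genotype = 16L,
    weights_wake = list(DP = c(R4m = 1.0, R3d = 0.325)),
    weights_doze = list(DP = c(R3d = 0.9)),
    seed = screen_seed
  )
}
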