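# Baseline subtraction and genetic-control correction.
#
# Thermogenetic activation needs a temperature step (21 -> 30 deg C) that
# itself changes sleep, so raw activation-minus-baseline deltas confound
# neuronal activation with temperature. Both genetic controls (GAL4/+ and
# UAS/+) undergo the same step without activation; subtracting the mean of
# their deltas isolates the activation effect.

.SLEEP_PARAMS <- c("total_sleep", "n_episodes", "max_episode")
.PROB_PARAMS <- c("p_doze", "p_wake")

#' Long parameter table: sleep metrics + transition probabilities
#'
#' Stacks the five screen parameters (total sleep, episode number, maximum
#' episode length, P(doze), P(wake)) into one long table per fly, day and
#' phase.
#'
#' @param metrics Output of [sleep_metrics()].
#' @param transitions Output of [transition_estimates()] (optional).
#' @return `data.table`: id columns, `day_role`, `phase`, `parameter`,
#'   `value`.
#' @export
parameter_table <- function(metrics, transitions = NULL) {
  id <- c("fly_id", "genotype", "driver", "genotype_role", "day_role", "phase")
  long <- melt(as.data.table(metrics)[, c(id, .SLEEP_PARAMS), with = FALSE],
               id.vars = id, variable.name = "parameter", value.name = "value",
               variable.factor = FALSE)
  if (!is.null(transitions)) {
    tlong <- melt(as.data.table(transitions)[, c(id, .PROB_PARAMS), with = FALSE],
                  id.vars = id, variable.name = "parameter",
                  value.name = "value", variable.factor = FALSE)
    long <- rbind(long, tlong)
  }
  long[, value := as.numeric(value)]
  long[]
}

#' Per-fly paired deltas against baseline
#'
#' For each fly, parameter and phase, subtracts the baseline-day value from
#' the activation (or recovery) day. The delta is defined only when both
#' days' values are defined; flies missing a day are skipped and counted.
#'
#' @param params Long table from [parameter_table()].
#' @param contrast `"activation-baseline"` or `"recovery-baseline"`.
#' @return `data.table`: `fly_id`, `genotype`, `driver`, `genotype_role`,
#'   `phase`, `parameter`, `contrast`, `value`. The number of skipped
#'   fly-parameter pairs is in attribute `"n_skipped"`.
#' @export
per_fly_delta <- function(params, contrast = c("activation-baseline",
                                               "recovery-baseline")) {
  contrast <- match.arg(contrast)
  top_day <- sub("-baseline", "", contrast)
  p <- as.data.table(params)
  wide <- dcast(p[day_role %in% c("baseline", top_day)],
                fly_id + genotype + driver + genotype_role + phase + parameter ~ day_role,
                value.var = "value")
  if (!top_day %in% names(wide)) wide[, (top_day) := NA_real_]
  if (!"baseline" %in% names(wide)) wide[, baseline := NA_real_]
  wide[, value := get(top_day) - baseline]
  n_skipped <- sum(is.na(wide$value))
  out <- wide[!is.na(value),
              .(fly_id, genotype, driver, genotype_role, phase, parameter,
                contrast = contrast, value)]
  setattr(out, "n_skipped", n_skipped)
  out[]
}

#' Genetic-control correction
#'
#' `exp - (gal4 + uas) / 2`: the experimental delta minus the mean of the
#' two control deltas. Linear in each argument; a shift common to all
#' three genotypes (the pure temperature effect) cancels exactly.
#'
#' @param exp_delta,gal4_delta,uas_delta Numeric (vectors recycle).
#' @return Corrected delta; `NA` whenever any input is undefined.
#' @export
control_correct <- function(exp_delta, gal4_delta, uas_delta) {
  exp_delta - (gal4_delta + uas_delta) / 2
}

#' Driver points in (delta P(wake), delta P(doze)) space
#'
#' One control-corrected coordinate pair per driver and phase: the input
#' to the Gaussian-mixture clustering. `method = "per_fly_mean"` averages
#' per-fly probability deltas within each genotype before correcting;
#' `method = "pooled"` recomputes each genotype-day probability from
#' pooled transition counts and differences those.
#'
#' @param transitions Output of [transition_estimates()].
#' @param contrast See [per_fly_delta()].
#' @param method Aggregation of flies within genotype.
#' @return `data.table`: `driver`, `phase`, `d_p_wake`, `d_p_doze`.
#' @export
driver_delta_points <- function(transitions,
                                contrast = c("activation-baseline",
                                             "recovery-baseline"),
                                method = c("per_fly_mean", "pooled")) {
  contrast <- match.arg(contrast)
  method <- match.arg(method)
  top_day <- sub("-baseline", "", contrast)
  tr <- as.data.table(transitions)
  if (method == "per_fly_mean") {
    long <- melt(tr[, .(fly_id, driver, genotype_role, day_role, phase,
                        p_doze, p_wake)],
                 id.vars = c("fly_id", "driver", "genotype_role", "day_role",
                             "phase"),
                 variable.name = "parameter", value.name = "value",
                 variable.factor = FALSE)
    d <- per_fly_delta(long[, genotype := NA_character_][],
                       contrast = contrast)
    g <- d[, .(value = mean(value)), by = .(driver, genotype_role, phase, parameter)]
  } else {
    pooled <- pool_transitions(tr, by = c("driver", "genotype_role",
                                          "day_role", "phase"))
    long <- melt(pooled[, .(driver, genotype_role, day_role, phase,
                            p_doze, p_wake)],
                 id.vars = c("driver", "genotype_role", "day_role", "phase"),
                 variable.name = "parameter", value.name = "value",
                 variable.factor = FALSE)
    wide <- dcast(long[day_role %in% c("baseline", top_day)],
                  driver + genotype_role + phase + parameter ~ day_role,
                  value.var = "value")
    g <- wide[, .(driver, genotype_role, phase, parameter,
                  value = get(top_day) - baseline)]
  }
  roles <- dcast(g, driver + phase + parameter ~ genotype_role,
                 value.var = "value")
  for (col in c("experimental", "gal4_control", "uas_control")) {
    if (!col %in% names(roles)) roles[, (col) := NA_real_]
  }
  roles[, value := control_correct(experimental, gal4_control, uas_control)]
  out <- dcast(roles, driver + phase ~ parameter, value.var = "value")
  setnames(out, c("p_wake", "p_doze"), c("d_p_wake", "d_p_doze"))
  out[]
}

#' Relative change rate (activation - baseline) / baseline
#'
#' @param activation,baseline Numeric vectors; a zero baseline yields `NA`.
#' @return Numeric vector of change rates.
#' @export
change_rate <- function(activation, baseline) {
  ifelse(!is.na(baseline) & baseline != 0 & !is.na(activation),
         (activation - baseline) / baseline, NA_real_)
}

#' Mean change rate per driver, sleep parameter and phase
#'
#' The regression response of the subtype model: for each driver's
#' experimental genotype, the mean over flies of
#' (activation - baseline) / baseline. Flies with a zero (or missing)
#' baseline are excluded from the mean and counted.
#'
#' @param params Long table from [parameter_table()] (sleep parameters).
#' @param parameters Which parameters to summarize.
#' @return `data.table`: `driver`, `parameter`, `phase`, `value`
#'   (mean change rate), `n_flies`, `n_excluded`.
#' @export
driver_change_rates <- function(params, parameters = .SLEEP_PARAMS) {
  p <- as.data.table(params)[genotype_role == "experimental" &
                               parameter %in% parameters]
  wide <- dcast(p[day_role %in% c("baseline", "activation")],
                fly_id + driver + phase + parameter ~ day_role,
                value.var = "value")
  wide[, rate := change_rate(activation, baseline)]
  out <- wide[, .(value = mean(rate[!is.na(rate)]),
                  n_flies = sum(!is.na(rate)),
                  n_excluded = sum(is.na(rate))),
              by = .(driver, parameter, phase)]
  out[]
}
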