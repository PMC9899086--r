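# Minute-to-minute behavioral transition probabilities.
#
# P(wake) is the conditional probability that an inactive minute is
# followed by an active one (arousal / sleep-depth proxy); P(doze) the
# reverse (sleep-pressure proxy). Both are defined on raw 1-minute
# activity/inactivity, not on 5-min scored sleep.

#' Estimate P(wake) and P(doze) from a state vector
#'
#' Counts minute pairs (t, t+1). A pair contributes iff minute t lies in
#' the window and both members are observed; the successor may fall
#' outside the window (e.g. the first minute of the next phase).
#' `p_wake` = transitions inactive->active / inactive minutes with an
#' observed successor; `p_doze` analogously with roles reversed. With zero
#' opportunities the probability is undefined (`NA`), never zero.
#'
#' @param states States from [binarize()] (or logical, TRUE = inactive),
#'   one fly-day in time order.
#' @param window Logical vector (same length) marking minutes whose
#'   outgoing transition is counted; default all.
#' @return One-row `data.table`: `p_wake`, `p_doze`,
#'   `n_wake_transitions`, `n_wake_opportunities`, `n_doze_transitions`,
#'   `n_doze_opportunities`.
#' @export
estimate_transitions <- function(states, window = NULL) {
  inact <- .inactive_logical(states)
  n <- length(inact)
  if (is.null(window)) window <- rep(TRUE, n)
  stopifnot(length(window) == n)
  if (n < 2L) {
    return(data.table(p_wake = NA_real_, p_doze = NA_real_,
                      n_wake_transitions = 0L, n_wake_opportunities = 0L,
                      n_doze_transitions = 0L, n_doze_opportunities = 0L))
  }
  cur <- inact[-n]
  nxt <- inact[-1L]
  ok <- window[-n] & !is.na(cur) & !is.na(nxt)
  wake_opp <- sum(ok & cur)
  wake_tr <- sum(ok & cur & !nxt)
  doze_opp <- sum(ok & !cur)
  doze_tr <- sum(ok & !cur & nxt)
  data.table(
    p_wake = if (wake_opp > 0L) wake_tr / wake_opp else NA_real_,
    p_doze = if (doze_opp > 0L) doze_tr / doze_opp else NA_real_,
    n_wake_transitions = wake_tr, n_wake_opportunities = wake_opp,
    n_doze_transitions = doze_tr, n_doze_opportunities = doze_opp
  )
}

#' Pool transition estimates by summing counts
#'
#' Transition and opportunity counts are summed and the probabilities
#' recomputed from the pooled counts (not averaged).
#'
#' @param estimates `data.table` of [estimate_transitions()] rows.
#' @param by Optional character vector of grouping columns.
#' @return Pooled estimate(s), one row per group.
#' @export
pool_transitions <- function(estimates, by = NULL) {
  est <- as.data.table(estimates)
  if (nrow(est) == 0L) stop("no estimates to pool", call. = FALSE)
  out <- est[, .(
    n_wake_transitions = sum(n_wake_transitions),
    n_wake_opportunities = sum(n_wake_opportunities),
    n_doze_transitions = sum(n_doze_transitions),
    n_doze_opportunities = sum(n_doze_opportunities)
  ), by = by]
  out[, p_wake := ifelse(n_wake_opportunities > 0,
                         n_wake_transitions / n_wake_opportunities, NA_real_)]
  out[, p_doze := ifelse(n_doze_opportunities > 0,
                         n_doze_transitions / n_doze_opportunities, NA_real_)]
  setcolorder(out, c(by, "p_wake", "p_doze"))
  out[]
}

#' Per fly x day x phase transition estimates for a screen
#'
#' Applies [estimate_transitions()] within each fly and experiment day,
#' once per phase window. Pairs never straddle an experiment-day boundary
#' (days have distinct roles and temperatures), but a within-day pair may
#' cross the LP/DP boundary; it is attributed to the phase of its first
#' minute.
#'
#' @param activity Annotated per-minute table.
#' @return `data.table`: `fly_id`, `genotype`, `driver`, `genotype_role`,
#'   `day_role`, `phase` plus the [estimate_transitions()] columns.
#' @export
transition_estimates <- function(activity) {
  act <- as.data.table(activity)
  setorder(act, fly_id, minute)
  act[, inact := count == 0L] # NA propagates
  act[, nxt := shift(inact, type = "lead"), by = .(fly_id, date)]
  counts <- act[!is.na(inact) & !is.na(nxt), .(
    n_wake_transitions = sum(inact & !nxt),
    n_wake_opportunities = sum(inact),
    n_doze_transitions = sum(!inact & nxt),
    n_doze_opportunities = sum(!inact)
  ), by = .(fly_id, genotype, driver, genotype_role, day_role, phase)]
  # flies/phases with no observed pairs must still appear, as undefined
  grid <- unique(act[, .(fly_id, genotype, driver, genotype_role, day_role)])
  grid <- grid[CJ(fly_id = unique(fly_id), phase = c("LP", "DP"),
                  sorted = FALSE),
               on = "fly_id", allow.cartesian = TRUE]
  res <- counts[grid, on = c("fly_id", "genotype", "driver", "genotype_role",
                             "day_role", "phase")]
  for (col in c("n_wake_transitions", "n_wake_opportunities",
                "n_doze_transitions", "n_doze_opportunities")) {
    res[is.na(get(col)), (col) := 0L]
  }
  res[, p_wake := ifelse(n_wake_opportunities > 0,
                         n_wake_transitions / n_wake_opportunities, NA_real_)]
  res[, p_doze := ifelse(n_doze_opportunities > 0,
                         n_doze_transitions / n_doze_opportunities, NA_real_)]
  act[, c("inact", "nxt") := NULL]
  setcolorder(res, c("fly_id", "genotype", "driver", "genotype_role",
                     "day_role", "phase", "p_wake", "p_doze"))
  res[]
}
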