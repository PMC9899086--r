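# Sleep scoring: binarize per-minute activity, detect sleep bouts
# (>= min_bout consecutive inactive minutes) and summarize per phase.

#' Binarize per-minute activity counts
#'
#' A minute is `"active"` iff its beam-break count is > 0; missing counts
#' propagate as `NA`.
#'
#' @param counts Integer vector of per-minute counts (`NA` = missing).
#' @return Character vector in `{"active", "inactive", NA}`.
#' @export
binarize <- function(counts) {
  out <- rep(NA_character_, length(counts))
  out[!is.na(counts) & counts > 0] <- "active"
  out[!is.na(counts) & counts == 0] <- "inactive"
  out
}

.inactive_logical <- function(states) {
  if (is.character(states)) {
    bad <- setdiff(unique(states[!is.na(states)]), c("active", "inactive"))
    if (length(bad)) stop("unknown state value(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    states == "inactive"
  } else if (is.logical(states)) {
    states # TRUE = inactive
  } else {
    stop("states must be character ('active'/'inactive') or logical", call. = FALSE)
  }
}

#' Score sleep bouts from a state vector
#'
#' A sleep bout is every maximal run of at least `min_bout` consecutive
#' inactive minutes. Missing minutes break runs: sleep is never inferred
#' through unobserved time. The input must be one fly-day in time order;
#' bouts do not continue across days.
#'
#' @param states Vector from [binarize()] (or logical, TRUE = inactive).
#' @param min_bout Minimum bout length in minutes (fly convention: 5).
#' @return `data.table` with `start` (1-based index into `states`) and
#'   `duration` (minutes), ordered and non-overlapping.
#' @export
score_bouts <- function(states, min_bout = 5L) {
  if (min_bout < 1L) stop("min_bout must be >= 1", call. = FALSE)
  inact <- .inactive_logical(states)
  # NA breaks runs: treat missing as not-inactive for run detection
  r <- rle(!is.na(inact) & inact)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_bout
  data.table(start = starts[keep], duration = r$lengths[keep])
}

# per-minute sleep indicator implied by a bout set
.asleep_vector <- function(bouts, n) {
  asleep <- logical(n)
  if (nrow(bouts)) {
    for (i in seq_len(nrow(bouts))) {
      asleep[bouts$start[i]:(bouts$start[i] + bouts$duration[i] - 1L)] <- TRUE
    }
  }
  asleep
}

#' Summarize sleep per phase for one fly-day
#'
#' Bouts are scored on the whole day, then intersected with each phase
#' window. Sleep minutes are attributed to the phase they occur in; an
#' episode is counted once, in the phase containing its start
#' (`straddle = "start"`), or in every phase it touches
#' (`straddle = "both"`). The maximum episode is the longest within-phase
#' sleeping segment of any bout, so a phase's maximum never exceeds its
#' total.
#'
#' @param states One fly-day of states in time order (see [score_bouts()]).
#' @param phase Character vector, same length: `"LP"` / `"DP"` per minute.
#' @param min_bout Minimum bout length, minutes.
#' @param straddle How phase-straddling bouts are counted as episodes.
#' @return `data.table` with one row per phase: `phase`,
#'   `total_sleep`, `n_episodes`, `max_episode` (all minutes or counts).
#' @export
sleep_summary <- function(states, phase, min_bout = 5L,
                          straddle = c("start", "both")) {
  straddle <- match.arg(straddle)
  stopifnot(length(states) == length(phase))
  s <- .phase_sleep(.inactive_logical(states), phase, min_bout, straddle)
  data.table(phase = s$phase, total_sleep = s$total_sleep,
             n_episodes = s$n_episodes, max_episode = s$max_episode)
}

# shared fast path: one fly-day, logical inactive vector (NA = missing)
.phase_sleep <- function(inact, phase, min_bout, straddle) {
  bouts <- score_bouts(inact, min_bout)
  asleep <- .asleep_vector(bouts, length(inact))
  total <- n_ep <- max_ep <- n_missing <- integer(2L)
  for (j in 1:2) {
    ph <- c("LP", "DP")[j]
    in_ph <- phase == ph
    total[j] <- sum(asleep & in_ph)
    segs <- rle(asleep & in_ph)
    max_ep[j] <- if (any(segs$values)) max(segs$lengths[segs$values]) else 0L
    n_ep[j] <- if (straddle == "start") {
      sum(phase[bouts$start] == ph)
    } else if (nrow(bouts)) {
      sum(vapply(seq_len(nrow(bouts)), function(i) {
        idx <- bouts$start[i]:(bouts$start[i] + bouts$duration[i] - 1L)
        any(phase[idx] == ph)
      }, logical(1L)))
    } else 0L
    n_missing[j] <- sum(is.na(inact[in_ph]))
  }
  list(phase = c("LP", "DP"), total_sleep = total, n_episodes = n_ep,
       max_episode = max_ep, n_missing = n_missing)
}

#' Per-fly sleep metrics for an annotated screen
#'
#' Computes the three sleep-structure metrics of the screen -- total sleep,
#' number of episodes, maximum episode length -- per fly, experiment day
#' and phase. Each day is scored independently.
#'
#' @param activity Annotated per-minute table ([annotate_minutes()] /
#'   [load_dam_screen()]).
#' @param min_bout Minimum bout length, minutes (default 5).
#' @param straddle See [sleep_summary()].
#' @return `data.table`: `fly_id`, `genotype`, `driver`, `genotype_role`,
#'   `day_role`, `phase`, `total_sleep`, `n_episodes`, `max_episode`,
#'   `n_missing` (missing minutes in that phase).
#' @export
sleep_metrics <- function(activity, min_bout = 5L,
                          straddle = c("start", "both")) {
  straddle <- match.arg(straddle)
  act <- as.data.table(activity)
  setorder(act, fly_id, minute)
  res <- act[, .phase_sleep(count == 0L, phase, min_bout, straddle),
             by = .(fly_id, genotype, driver, genotype_role, day_role)]
  res[]
}
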