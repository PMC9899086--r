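# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can serve as ground truth.

# enumerate maximal inactive runs by walking the vector minute by minute
oracle_bouts <- function(inact, min_bout) {
  bouts <- list()
  run_start <- NA_integer_
  for (i in seq_along(inact)) {
    sleeping <- !is.na(inact[i]) && inact[i]
    if (sleeping && is.na(run_start)) run_start <- i
    if (!sleeping && !is.na(run_start)) {
      len <- i - run_start
      if (len >= min_bout) bouts[[length(bouts) + 1L]] <- c(run_start, len)
      run_start <- NA_integer_
    }
  }
  if (!is.na(run_start)) {
    len <- length(inact) - run_start + 1L
    if (len >= min_bout) bouts[[length(bouts) + 1L]] <- c(run_start, len)
  }
  if (!length(bouts)) {
    return(data.frame(start = integer(0), duration = integer(0)))
  }
  m <- do.call(rbind, bouts)
  data.frame(start = m[, 1L], duration = m[, 2L])
}

# per-phase totals/episodes/max directly from the bout list
oracle_phase_summary <- function(inact, phase, min_bout,
                                 straddle = "start") {
  b <- oracle_bouts(inact, min_bout)
  asleep <- rep(FALSE, length(inact))
  for (i in seq_len(nrow(b))) {
    asleep[b$start[i]:(b$start[i] + b$duration[i] - 1L)] <- TRUE
  }
  out <- list()
  for (ph in c("LP", "DP")) {
    total <- sum(asleep & phase == ph)
    # longest contiguous sleeping stretch inside the phase
    best <- 0L; cur <- 0L
    for (i in seq_along(inact)) {
      if (asleep[i] && phase[i] == ph) {
        cur <- cur + 1L
        best <- max(best, cur)
      } else cur <- 0L
    }
    n_ep <- 0L
    for (i in seq_len(nrow(b))) {
      idx <- b$start[i]:(b$start[i] + b$duration[i] - 1L)
      hit <- if (straddle == "start") phase[b$start[i]] == ph else
        any(phase[idx] == ph)
      if (hit) n_ep <- n_ep + 1L
    }
    out[[ph]] <- c(total = total, n_episodes = n_ep, max_episode = best)
  }
  out
}

# pair-by-pair transition counter
oracle_transitions <- function(inact, window = rep(TRUE, length(inact))) {
  wt <- wo <- dt_ <- do_ <- 0L
  for (t in seq_len(length(inact) - 1L)) {
    if (!window[t] || is.na(inact[t]) || is.na(inact[t + 1L])) next
    if (inact[t]) {
      wo <- wo + 1L
      if (!inact[t + 1L]) wt <- wt + 1L
    } else {
      do_ <- do_ + 1L
      if (inact[t + 1L]) dt_ <- dt_ + 1L
    }
  }
  list(p_wake = if (wo > 0) wt / wo else NA_real_,
       p_doze = if (do_ > 0) dt_ / do_ else NA_real_,
       n_wake_transitions = wt, n_wake_opportunities = wo,
       n_doze_transitions = dt_, n_doze_opportunities = do_)
}

# tiny DAM2 file written by hand (independent of write_dam_monitor)
write_toy_monitor <- function(path, counts_by_row, dates, times,
                              status = 1L, n_counts = 32L) {
  lines <- character(length(times))
  for (i in seq_along(times)) {
    row_counts <- rep(0L, n_counts)
    row_counts[seq_along(counts_by_row[[i]])] <- counts_by_row[[i]]
    lines[i] <- paste(c(i, dates[i], times[i], status,
                        rep(0L, 6L), row_counts), collapse = "\t")
  }
  writeLines(lines, path)
  path
}

# quick 2-D Gaussian cluster generator
make_clusters <- function(centers, n_per, sd) {
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(j) {
    cbind(rnorm(n_per, centers[j, 1], sd), rnorm(n_per, centers[j, 2], sd))
  }))
  list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# small annotated activity table for pipeline-level tests
toy_screen <- function(n_drivers = 4, flies = 4, seed = 1, ...) {
  cfg <- simulation_config(n_drivers = n_drivers,
                           flies_per_genotype = flies, seed = seed, ...)
  simulate_screen(cfg)
}
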