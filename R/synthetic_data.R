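# Ground-truth simulator: two-state (active/inactive) Markov flies with
# phase-, day- and genotype-dependent transition probabilities, written
# out in the DAM2 dialect so the whole pipeline can be exercised against
# known truth.
#
# Effects stack additively on the logit scale: a temperature shift on the
# activation day hits every genotype, subtype-driven shifts hit only the
# experimental genotype. Logit stacking keeps probabilities in (0, 1).

#' Simulate a two-state Markov activity chain
#'
#' Minute-to-minute chain over {active, inactive}: an active minute goes
#' inactive with probability `p_doze`, an inactive one goes active with
#' probability `p_wake`. The first minute is drawn from the stationary
#' distribution, whose inactive fraction is
#' `p_doze / (p_doze + p_wake)`.
#'
#' @param n Number of minutes.
#' @param p_doze,p_wake Transition probabilities. Scalars, or vectors of
#'   length `n` for time-varying (e.g. phase-dependent) chains; element t
#'   governs the transition out of minute t. The stationary draw for
#'   minute 1 uses element 1.
#' @return Logical vector, TRUE = active.
#' @export
simulate_markov_states <- function(n, p_doze, p_wake) {
  p_doze <- rep_len(p_doze, n)
  p_wake <- rep_len(p_wake, n)
  stopifnot(all(p_doze >= 0 & p_doze <= 1), all(p_wake >= 0 & p_wake <= 1),
            p_doze[1L] + p_wake[1L] > 0)
  active <- logical(n)
  u <- runif(n)
  active[1L] <- u[1L] < p_wake[1L] / (p_doze[1L] + p_wake[1L])
  for (t in seq_len(n - 1L)) {
    active[t + 1L] <- if (active[t]) u[t + 1L] >= p_doze[t] else
      u[t + 1L] < p_wake[t]
  }
  active
}

#' Simulate one fly-day of minute states and counts
#'
#' One 1440-minute calendar day under a light/dark cycle with
#' phase-specific transition probabilities. Active minutes emit a count
#' of `1 + Poisson(lambda - 1)` beam breaks, inactive minutes emit 0.
#'
#' @param p_doze,p_wake Named numeric, elements `LP` and `DP`.
#' @param lights_on_minute Clock minute of lights-on (default 480 =
#'   08:00).
#' @param photoperiod_minutes Light-phase length.
#' @param lambda Mean count of an active minute (>= 1).
#' @return `data.table`: `clock_minute` (0-1439), `zt_minute`, `phase`,
#'   `active`, `count`.
#' @export
simulate_fly_day <- function(p_doze, p_wake, lights_on_minute = 480L,
                             photoperiod_minutes = 720L, lambda = 2) {
  stopifnot(all(c("LP", "DP") %in% names(p_doze)),
            all(c("LP", "DP") %in% names(p_wake)), lambda >= 1)
  clock <- 0:1439
  zt <- (clock - lights_on_minute) %% 1440L
  phase <- ifelse(zt < photoperiod_minutes, "LP", "DP")
  active <- simulate_markov_states(1440L, p_doze[phase], p_wake[phase])
  count <- integer(1440L)
  count[active] <- 1L + rpois(sum(active), lambda - 1)
  data.table(clock_minute = clock, zt_minute = zt, phase = phase,
             active = active, count = count)
}

#' Build a screen simulation configuration
#'
#' Defines a full thermogenetic screen: `n_drivers` driver lines, each
#' with an experimental genotype (driver > dTrpA1) plus GAL4-only and
#' UAS-only controls, recorded for one baseline, one activation and one
#' recovery day. The activation day applies a temperature logit shift to
#' every genotype, plus the driver's subtype-weighted logit shifts to the
#' experimental genotype only. Defaults give a wild-type-like fly:
#' about 4 h of fragmented day sleep and 9-10 h of consolidated night
#' sleep, and a temperature step that is mildly wake-promoting.
#'
#' @param n_drivers Number of driver lines (default 34, the screen size).
#' @param subtype_matrix Driver x subtype 0/1 matrix, or `NULL` to draw
#'   one from `seed` (each subtype present with probability 0.25, at
#'   least one per driver).
#' @param subtypes Subtype names (columns) when drawing a matrix.
#' @param weights_doze,weights_wake Lists with named numeric elements
#'   `LP`, `DP`: per-subtype logit shifts on p(doze) / p(wake) applied to
#'   experimental genotypes on the activation day. Vectors are matched to
#'   subtypes by name; unnamed subtypes get 0.
#' @param p_doze,p_wake Baseline probabilities, named `LP`/`DP`.
#' @param temperature_effect Named numeric `c(doze = , wake = )`: logit
#'   shift on the activation day for all genotypes.
#' @param flies_per_genotype Flies per genotype (default 16).
#' @param lambda Mean active-minute count.
#' @param death_prob Per-fly probability of dying at a uniformly drawn
#'   minute of the recording (counts 0 afterwards).
#' @param lights_on Clock time "HH:MM".
#' @param start_date Calendar date of the baseline day.
#' @param seed Integer seed; fully determines the simulated screen.
#' @return List of class `damscreen_simconfig`.
#' @export
simulation_config <- function(n_drivers = 34L, subtype_matrix = NULL,
                              subtypes = RING_SUBTYPES,
                              weights_doze = list(), weights_wake = list(),
                              p_doze = c(LP = 0.15, DP = 0.30),
                              p_wake = c(LP = 0.30, DP = 0.10),
                              temperature_effect = c(doze = -0.2, wake = 0.3),
                              flies_per_genotype = 16L, lambda = 2,
                              death_prob = 0, lights_on = "08:00",
                              start_date = as.Date("2021-08-09"),
                              seed = 1L) {
  if (is.null(subtype_matrix)) {
    subtype_matrix <- .with_seed(seed + 1000L, {
      X <- matrix(rbinom(n_drivers * length(subtypes), 1L, 0.25),
                  n_drivers, length(subtypes),
                  dimnames = list(sprintf("driver%02d", seq_len(n_drivers)),
                                  subtypes))
      for (i in which(rowSums(X) == 0)) {
        X[i, sample.int(ncol(X), 1L)] <- 1L
      }
      X
    })
  }
  subtype_matrix <- subtype_design(subtype_matrix)
  n_drivers <- nrow(subtype_matrix)
  subtypes <- colnames(subtype_matrix)
  expand_w <- function(w) {
    lapply(c(LP = "LP", DP = "DP"), function(ph) {
      full <- setNames(numeric(length(subtypes)), subtypes)
      v <- w[[ph]]
      if (!is.null(v)) {
        bad <- setdiff(names(v), subtypes)
        if (length(bad)) stop("weight for unknown subtype: ",
                              paste(bad, collapse = ", "), call. = FALSE)
        full[names(v)] <- v
      }
      full
    })
  }
  cfg <- structure(list(
    drivers = rownames(subtype_matrix),
    subtypes = subtypes,
    subtype_matrix = subtype_matrix,
    weights_doze = expand_w(weights_doze),
    weights_wake = expand_w(weights_wake),
    p_doze = p_doze, p_wake = p_wake,
    temperature_effect = temperature_effect,
    flies_per_genotype = as.integer(flies_per_genotype),
    lambda = lambda, death_prob = death_prob,
    lights_on = lights_on,
    dates = c(baseline = as.Date(start_date),
              activation = as.Date(start_date) + 1L,
              recovery = as.Date(start_date) + 2L),
    seed = as.integer(seed)
  ), class = "damscreen_simconfig")
  tp <- true_probabilities(cfg) # validates range, errors name the genotype
  invisible(tp)
  cfg
}

#' Ground-truth transition probabilities implied by a configuration
#'
#' @param config A [simulation_config()].
#' @return `data.table`: `driver`, `genotype_role`, `day_role`, `phase`,
#'   `p_doze`, `p_wake`.
#' @export
true_probabilities <- function(config) {
  stopifnot(inherits(config, "damscreen_simconfig"))
  grid <- CJ(driver = config$drivers,
             genotype_role = c("experimental", "gal4_control", "uas_control"),
             day_role = c("baseline", "activation", "recovery"),
             phase = c("LP", "DP"), sorted = FALSE)
  lp_doze <- stats::qlogis(config$p_doze[grid$phase])
  lp_wake <- stats::qlogis(config$p_wake[grid$phase])
  on_act <- grid$day_role == "activation"
  lp_doze[on_act] <- lp_doze[on_act] + config$temperature_effect[["doze"]]
  lp_wake[on_act] <- lp_wake[on_act] + config$temperature_effect[["wake"]]
  is_exp_act <- on_act & grid$genotype_role == "experimental"
  if (any(is_exp_act)) {
    idx <- which(is_exp_act)
    X <- config$subtype_matrix[grid$driver[idx], , drop = FALSE]
    wd <- vapply(c("LP", "DP"), function(ph) X %*% config$weights_doze[[ph]],
                 numeric(length(idx)))
    ww <- vapply(c("LP", "DP"), function(ph) X %*% config$weights_wake[[ph]],
                 numeric(length(idx)))
    sel <- cbind(seq_along(idx), match(grid$phase[idx], c("LP", "DP")))
    lp_doze[idx] <- lp_doze[idx] + wd[sel]
    lp_wake[idx] <- lp_wake[idx] + ww[sel]
  }
  grid[, p_doze := stats::plogis(lp_doze)]
  grid[, p_wake := stats::plogis(lp_wake)]
  eps <- 1e-12
  bad <- grid[p_doze <= eps | p_doze >= 1 - eps | p_wake <= eps |
                p_wake >= 1 - eps]
  if (nrow(bad)) {
    stop("transition probability out of (0,1) after logit shifts for ",
         bad$driver[1L], " (", bad$genotype_role[1L], ", ", bad$day_role[1L],
         " ", bad$phase[1L], ")", call. = FALSE)
  }
  grid[]
}

.screen_fly_table <- function(config) {
  flies <- CJ(driver = config$drivers,
              genotype_role = c("experimental", "gal4_control", "uas_control"),
              rep = seq_len(config$flies_per_genotype), sorted = FALSE)
  flies[, genotype := fcase(
    genotype_role == "experimental", paste0(driver, ">dTrpA1"),
    genotype_role == "gal4_control", paste0(driver, "/+"),
    genotype_role == "uas_control", "UAS-dTrpA1/+"
  )]
  flies[, fly_id := sprintf("%s_%s_%02d", driver,
                            c(experimental = "exp", gal4_control = "g4",
                              uas_control = "uas")[genotype_role], rep)]
  flies[]
}

#' Simulate a full screen
#'
#' Generates every fly of every genotype triplet for the 3-day protocol
#' and returns the annotated per-minute activity table plus the ground
#' truth. With `dir` set, also writes DAM2 monitor files (32 channels
#' each; unmapped channels all-zero), a channel-map CSV, a design YAML
#' and a ground-truth JSON manifest; files are byte-deterministic in the
#' seed.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory, or `NULL` for in-memory only.
#' @return List of class `damscreen_screen`: `activity` (annotated
#'   per-minute table in the [annotate_minutes()] layout), `truth`
#'   (`probabilities`, `weights_doze`, `weights_wake`, `subtype_matrix`,
#'   `deaths`), `design`, `channel_map`, `paths` (when written).
#' @export
simulate_screen <- function(config, dir = NULL) {
  stopifnot(inherits(config, "damscreen_simconfig"))
  truth_p <- true_probabilities(config)
  flies <- .screen_fly_table(config)
  n_flies <- nrow(flies)
  design <- experiment_design(config$dates[["baseline"]],
                              config$dates[["activation"]],
                              config$dates[["recovery"]],
                              lights_on = config$lights_on)
  lights_on_minute <- design$lights_on_minute
  clock <- 0:1439
  zt <- (clock - lights_on_minute) %% 1440L
  phase_day <- ifelse(zt < design$photoperiod_minutes, "LP", "DP")
  nT <- 3L * 1440L
  states <- matrix(FALSE, n_flies, nT) # TRUE = active; fly-major columns
  counts <- NULL
  deaths <- NULL
  key <- paste(flies$driver, flies$genotype_role)
  .with_seed(config$seed, {
    for (d in 1:3) {
      role <- names(config$dates)[d]
      tp <- truth_p[day_role == role]
      tkey_lp <- tp[phase == "LP"][match(key, paste(driver, genotype_role))]
      tkey_dp <- tp[phase == "DP"][match(key, paste(driver, genotype_role))]
      pd <- rbind(LP = tkey_lp$p_doze, DP = tkey_dp$p_doze)
      pw <- rbind(LP = tkey_lp$p_wake, DP = tkey_dp$p_wake)
      ph1 <- phase_day[1L]
      u <- runif(n_flies)
      active <- u < pw[ph1, ] / (pd[ph1, ] + pw[ph1, ])
      states[, (d - 1L) * 1440L + 1L] <- active
      for (t in 1:1439) {
        pht <- phase_day[t]
        u <- runif(n_flies)
        active <- (active & u >= pd[pht, ]) | (!active & u < pw[pht, ])
        states[, (d - 1L) * 1440L + t + 1L] <- active
      }
    }
    counts <- matrix(0L, n_flies, nT)
    counts[states] <- 1L + rpois(sum(states), config$lambda - 1)
    deaths <- data.table(fly_id = flies$fly_id, death_minute = NA_integer_)
    if (config$death_prob > 0) {
      dies <- runif(n_flies) < config$death_prob
      dmin <- sample.int(nT, n_flies, replace = TRUE)
      deaths[dies, death_minute := dmin[dies]]
      for (i in which(dies)) counts[i, dmin[i]:nT] <- 0L
    }
  })
  minutes <- rep(as.POSIXct(paste(config$dates, "00:00:00"), tz = "UTC"),
                 each = 1440L) + rep(clock * 60, 3L)
  activity <- data.table(
    fly_id = rep(flies$fly_id, each = 3L * 1440L),
    genotype = rep(flies$genotype, each = 3L * 1440L),
    driver = rep(flies$driver, each = 3L * 1440L),
    genotype_role = rep(flies$genotype_role, each = 3L * 1440L),
    minute = rep(minutes, n_flies),
    date = rep(rep(config$dates, each = 1440L), n_flies),
    day_role = rep(rep(names(config$dates), each = 1440L), n_flies),
    zt_minute = rep(zt, 3L * n_flies),
    phase = rep(phase_day, 3L * n_flies),
    count = as.integer(t(counts))
  )
  n_monitors <- ceiling(n_flies / 32L)
  channel_map <- copy(flies)
  channel_map[, monitor := sprintf("Monitor%02d", (seq_len(n_flies) - 1L) %/% 32L + 1L)]
  channel_map[, channel := (seq_len(n_flies) - 1L) %% 32L + 1L]
  channel_map <- channel_map[, .(monitor, channel, fly_id, genotype, driver,
                                 genotype_role)]
  out <- structure(list(
    activity = activity,
    truth = list(probabilities = truth_p,
                 weights_doze = config$weights_doze,
                 weights_wake = config$weights_wake,
                 subtype_matrix = config$subtype_matrix,
                 deaths = deaths),
    design = design, channel_map = channel_map, config = config,
    paths = NULL
  ), class = "damscreen_screen")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(monitors = character(0))
    datetimes <- minutes
    for (m in seq_len(n_monitors)) {
      cols <- ((m - 1L) * 32L + 1L):min(m * 32L, n_flies)
      cm <- matrix(0L, nrow = 3L * 1440L, ncol = 32L)
      cm[, seq_along(cols)] <- t(counts[cols, , drop = FALSE])
      colnames(cm) <- sprintf("ch%02d", 1:32)
      readings <- cbind(data.table(datetime = datetimes, status = 1L),
                        as.data.table(cm))
      p <- file.path(dir, sprintf("Monitor%02d.txt", m))
      write_dam_monitor(readings, p)
      paths$monitors[sprintf("Monitor%02d", m)] <- p
    }
    paths$channel_map <- file.path(dir, "channel_map.csv")
    write.csv(channel_map, paths$channel_map, row.names = FALSE)
    paths$design <- file.path(dir, "design.yaml")
    yaml::write_yaml(list(
      baseline = as.character(config$dates[["baseline"]]),
      activation = as.character(config$dates[["activation"]]),
      recovery = as.character(config$dates[["recovery"]]),
      lights_on = config$lights_on, photoperiod_minutes = 720L
    ), paths$design)
    paths$truth <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(list(
      probabilities = truth_p,
      weights_doze = config$weights_doze,
      weights_wake = config$weights_wake,
      subtype_matrix = data.frame(driver = rownames(config$subtype_matrix),
                                  as.data.frame(config$subtype_matrix),
                                  check.names = FALSE),
      deaths = deaths[!is.na(death_minute)],
      seed = config$seed
    ), paths$truth, auto_unbox = TRUE, digits = NA, dataframe = "columns")
    out$paths <- paths
  }
  out
}
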