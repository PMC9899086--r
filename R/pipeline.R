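# End-to-end orchestration: one call from annotated per-minute activity
# (or monitor files on disk) to metrics, deltas, clustering, the subtype
# model and the significance table, with deterministic outputs.

#' Analyze a screen in memory
#'
#' Runs every analysis stage on an annotated activity table: dead-fly
#' filtering, sleep metrics, transition probabilities, baseline deltas,
#' control-corrected driver points, change rates, per-driver statistics,
#' Gaussian-mixture clustering per phase and (when a subtype matrix is
#' given) the subtype model.
#'
#' @param activity Annotated per-minute table ([load_dam_screen()] or
#'   [simulate_screen()]`$activity`).
#' @param subtype_matrix Optional driver x subtype 0/1 matrix for the
#'   subtype model.
#' @param cluster_drivers Optional character vector restricting which
#'   drivers enter the clustering (the screen clusters only drivers with
#'   significant effects; membership is an input, not inferred). Default:
#'   all drivers with finite delta-P coordinates.
#' @param min_bout Sleep-bout threshold, minutes.
#' @param alpha Significance level used throughout.
#' @param k_candidates Mixture component counts tried per phase.
#' @param transition_method `"per_fly_mean"` or `"pooled"`, see
#'   [driver_delta_points()].
#' @param straddle Episode attribution for phase-straddling bouts.
#' @param min_active_minutes_last_day Dead-fly threshold.
#' @param gmm_n_init,gmm_reg EM restarts / covariance ridge.
#' @param seed Seed for the (seeded, deterministic) mixture fits.
#' @param stats_test `"auto"`, `"anova"` or `"kruskal_wallis"`.
#' @return List of class `damscreen_result` with one element per stage.
#' @export
analyze_screen <- function(activity, subtype_matrix = NULL,
                           cluster_drivers = NULL, min_bout = 5L,
                           alpha = 0.05, k_candidates = 3:5,
                           transition_method = c("per_fly_mean", "pooled"),
                           straddle = c("start", "both"),
                           min_active_minutes_last_day = 1L,
                           gmm_n_init = 20L, gmm_reg = 1e-6, seed = 1L,
                           stats_test = "auto") {
  transition_method <- match.arg(transition_method)
  straddle <- match.arg(straddle)
  stopifnot(alpha > 0, alpha < 1, length(k_candidates) >= 1L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  act <- as.data.table(activity)
  survival <- stage("filter_dead_flies",
                    filter_dead_flies(act, min_active_minutes_last_day))
  act <- act[fly_id %in% survival[keep == TRUE, fly_id]]
  metrics <- stage("sleep_metrics",
                   sleep_metrics(act, min_bout = min_bout, straddle = straddle))
  transitions <- stage("transition_prob", transition_estimates(act))
  params <- stage("parameter_table", parameter_table(metrics, transitions))
  deltas <- stage("per_fly_delta", per_fly_delta(params, "activation-baseline"))
  points <- stage("driver_delta_points",
                  driver_delta_points(transitions, "activation-baseline",
                                      method = transition_method))
  rates <- stage("driver_change_rates", driver_change_rates(params))
  stats_tbl <- stage("screen_stats", screen_stats(deltas, alpha = alpha,
                                                  test = stats_test))
  clustering <- stage("gmm_cluster", {
    out <- list()
    for (ph in c("LP", "DP")) {
      pts <- points[phase == ph & is.finite(d_p_wake) & is.finite(d_p_doze)]
      if (!is.null(cluster_drivers)) pts <- pts[driver %in% cluster_drivers]
      if (nrow(pts) <= min(k_candidates)) {
        warning("too few driver points to cluster phase ", ph, call. = FALSE)
        next
      }
      m <- as.matrix(pts[, .(d_p_wake, d_p_doze)])
      rownames(m) <- pts$driver
      out[[ph]] <- select_k(m, k_candidates = k_candidates, seed = seed,
                            n_init = gmm_n_init, reg = gmm_reg)
    }
    out
  })
  glm_tbl <- NULL
  if (!is.null(subtype_matrix)) {
    glm_tbl <- stage("subtype_glm",
                     subtype_glm_table(subtype_design(subtype_matrix), rates,
                                       alpha = alpha))
  }
  structure(list(
    survival = survival, metrics = metrics, transitions = transitions,
    parameters = params, deltas = deltas, driver_points = points,
    change_rates = rates, stats = stats_tbl, clustering = clustering,
    glm = glm_tbl,
    options = list(min_bout = min_bout, alpha = alpha,
                   k_candidates = k_candidates,
                   transition_method = transition_method,
                   straddle = straddle, seed = seed,
                   min_active_minutes_last_day = min_active_minutes_last_day)
  ), class = "damscreen_result")
}

#' Read and validate a run configuration YAML
#'
#' Fields: `monitors` (map label -> path), `channel_map`, `design`
#' (paths), optional `subtype_matrix` (CSV path, first column = driver),
#' optional `cluster_drivers`, plus analysis options (`min_bout`,
#' `alpha`, `k_candidates`, `transition_method`, `straddle`, `seed`,
#' `out_dir`). Referenced files must exist and subtype columns must be
#' known ring subtypes; validation happens before any computation.
#'
#' @param path YAML file path.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c(unlist(cfg$monitors), cfg$channel_map, cfg$design,
              cfg$subtype_matrix)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("config references missing file: ", f, call. = FALSE)
    }
  }
  cfg$alpha <- cfg$alpha %||% 0.05
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0,1)",
                                             call. = FALSE)
  cfg$k_candidates <- cfg$k_candidates %||% 3:5
  if (length(cfg$k_candidates) == 0L) stop("k_candidates must be non-empty",
                                           call. = FALSE)
  cfg$min_bout <- cfg$min_bout %||% 5L
  cfg$transition_method <- cfg$transition_method %||% "per_fly_mean"
  cfg$straddle <- cfg$straddle %||% "start"
  cfg$seed <- cfg$seed %||% 1L
  if (!is.null(cfg$subtype_matrix)) {
    sm <- read.csv(cfg$subtype_matrix, row.names = 1L, check.names = FALSE)
    unknown <- setdiff(colnames(sm), RING_SUBTYPES)
    if (length(unknown)) {
      stop("unknown subtype column(s) in subtype matrix: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cfg$subtype_matrix_data <- subtype_design(as.matrix(sm))
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline from a configuration
#'
#' Loads monitors, channel map and design, calls [analyze_screen()] and,
#' when `out_dir` is set, writes the report bundle
#' ([write_screen_outputs()]). Identical config + inputs give identical
#' outputs.
#'
#' @param config Path to a YAML config or a list from
#'   [read_run_config()].
#' @return The `damscreen_result`, invisibly when written to disk.
#' @export
run_screen_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  design_cfg <- yaml::read_yaml(config$design)
  design <- experiment_design(design_cfg$baseline, design_cfg$activation,
                              design_cfg$recovery,
                              lights_on = design_cfg$lights_on %||% "08:00",
                              photoperiod_minutes =
                                design_cfg$photoperiod_minutes %||% 720L)
  channel_map <- read_channel_map(config$channel_map)
  activity <- load_dam_screen(unlist(config$monitors), channel_map, design)
  res <- analyze_screen(
    activity,
    subtype_matrix = config$subtype_matrix_data,
    cluster_drivers = config$cluster_drivers,
    min_bout = config$min_bout, alpha = config$alpha,
    k_candidates = config$k_candidates,
    transition_method = config$transition_method,
    straddle = config$straddle, seed = config$seed
  )
  if (!is.null(config$out_dir)) {
    write_screen_outputs(res, config$out_dir)
    return(invisible(res))
  }
  res
}

#' Write the report bundle of an analysis
#'
#' CSV per tabular stage, a JSON model file for the clustering (weights,
#' means, covariances, silhouettes per candidate k) and a manifest JSON
#' (package version, seed, options, md5 of every written file). Output
#' is deterministic: re-running the same analysis writes byte-identical
#' files.
#'
#' @param result A `damscreen_result`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_screen_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "damscreen_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wr <- function(dt, name) {
    p <- file.path(out_dir, name)
    write.csv(dt, p, row.names = FALSE)
    paths[name] <<- p
  }
  wr(result$survival, "survival.csv")
  wr(result$metrics, "sleep_metrics.csv")
  wr(result$transitions, "transitions.csv")
  wr(result$deltas, "per_fly_deltas.csv")
  wr(result$driver_points, "driver_points.csv")
  wr(result$change_rates, "change_rates.csv")
  wr(result$stats, "screen_stats.csv")
  if (!is.null(result$glm)) wr(result$glm, "subtype_glm.csv")
  if (length(result$clustering)) {
    assign_tbl <- rbindlist(lapply(names(result$clustering), function(ph) {
      cl <- result$clustering[[ph]]
      data.table(driver = rownames(cl$points), phase = ph,
                 cluster = cl$assignments)
    }))
    wr(assign_tbl, "clustering.csv")
    model_json <- lapply(result$clustering, function(cl) {
      list(chosen_k = cl$chosen_k,
           mean_silhouette = as.list(cl$mean_silhouette),
           models = lapply(cl$models, function(m) {
             if (is.null(m)) return(NULL)
             list(k = m$k, weights = m$weights, means = m$means,
                  covariances = lapply(seq_len(m$k),
                                       function(j) m$covariances[, , j]),
                  log_likelihood = m$log_likelihood,
                  converged = m$converged, seed = m$seed)
           }))
    })
    p <- file.path(out_dir, "gmm_models.json")
    jsonlite::write_json(model_json, p, auto_unbox = TRUE, digits = NA)
    paths["gmm_models.json"] <- p
  }
  manifest <- list(
    package = "damscreen",
    version = as.character(utils::packageVersion("damscreen")),
    options = result$options,
    files = as.list(tools::md5sum(unname(paths)))
  )
  names(manifest$files) <- names(paths)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  paths["manifest.json"] <- mp
  invisible(paths)
}
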