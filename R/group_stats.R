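# Significance machinery of the screen: per driver, the experimental
# group is compared against BOTH genetic controls; a change counts only
# when both planned comparisons are significant. Normally distributed
# groups go through one-way ANOVA + Bonferroni planned comparisons,
# otherwise Kruskal-Wallis + Dunn. Power analysis uses the noncentral t.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino) and kurtosis
#' (Anscombe-Glynn) into K2 = Z1^2 + Z2^2, chi-squared with 2 df under
#' normality. Requires n >= 8.
#'
#' @param x Numeric sample.
#' @return List: `statistic` (K2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) stop("dagostino_test needs n >= 8", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance sample", call. = FALSE)
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2
  # skewness: D'Agostino (1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xx * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = 1 - pchisq(k2, 2L),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Choose the omnibus test family for a set of groups
#'
#' ANOVA iff every group passes the omnibus skewness-kurtosis normality
#' test at `alpha`; any failure, any group smaller than `min_n` (the test
#' is unreliable below that), or any zero-variance group routes to the
#' rank-based family.
#'
#' @param groups List of numeric samples (each non-empty).
#' @param alpha Normality-test level.
#' @param min_n Minimum per-group n for the omnibus test.
#' @return `"anova"` or `"kruskal_wallis"`.
#' @export
normality_triage <- function(groups, alpha = 0.05, min_n = 8L) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  if (any(lengths(groups) < min_n)) return("kruskal_wallis")
  if (any(vapply(groups, function(g) var(g) == 0, logical(1L)))) {
    return("kruskal_wallis")
  }
  ps <- vapply(groups, function(g) dagostino_test(g)$p_value, numeric(1L))
  if (all(ps > alpha)) "anova" else "kruskal_wallis"
}

.comparison_result <- function(parameter, phase, test_used, statistic,
                               p_global, comparisons, alpha) {
  structure(list(
    parameter = parameter, phase = phase, test_used = test_used,
    statistic = statistic, p_global = p_global,
    comparisons = comparisons,
    significant_overall = nrow(comparisons) == 2L &&
      all(comparisons$p_adj < alpha),
    alpha = alpha
  ), class = "damscreen_comparison")
}

#' One-way ANOVA with planned Bonferroni comparisons vs both controls
#'
#' Global F over the three groups, then the two planned comparisons
#' (experimental vs each control) as t tests on the pooled within-group
#' variance, Bonferroni-adjusted for the 2 comparisons
#' (`p_adj = min(1, 2 p)`). The control-vs-control contrast is not
#' tested. `significant_overall` is TRUE iff both adjusted p fall below
#' `alpha` -- the screen's both-controls rule.
#'
#' @param exp,gal4,uas Numeric samples (n >= 2 each).
#' @param alpha Significance level.
#' @param parameter,phase Optional labels.
#' @return `damscreen_comparison`: `test_used = "anova"`, `statistic`
#'   (F), `p_global`, `comparisons` table (`comparison`, `effect` = mean
#'   difference, `statistic`, `p_raw`, `p_adj`), `significant_overall`.
#' @export
anova_with_planned <- function(exp, gal4, uas, alpha = 0.05,
                               parameter = NA_character_,
                               phase = NA_character_) {
  groups <- list(exp = exp[!is.na(exp)], gal4 = gal4[!is.na(gal4)],
                 uas = uas[!is.na(uas)])
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1L)))
  df_res <- length(y) - 3L
  if (ssw == 0) { # degenerate: no within-group variance, aov would warn
    ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - mean(y))^2,
                      numeric(1L)))
    Fstat <- if (ssb == 0) 0 else Inf
    p_global <- if (ssb == 0) 1 else 0
    mse <- 0
  } else {
    av <- anova(aov(y ~ g))
    Fstat <- av$`F value`[1L]
    p_global <- av$`Pr(>F)`[1L]
    mse <- av$`Mean Sq`[2L]
  }
  cmp <- rbindlist(lapply(c("gal4", "uas"), function(ctrl) {
    diff <- mean(groups$exp) - mean(groups[[ctrl]])
    se <- sqrt(mse * (1 / length(groups$exp) + 1 / length(groups[[ctrl]])))
    if (se == 0) { # zero within-group variance: p = 0 iff means differ
      t <- if (diff == 0) 0 else Inf * sign(diff)
      p_raw <- if (diff == 0) 1 else 0
    } else {
      t <- diff / se
      p_raw <- 2 * pt(-abs(t), df_res)
    }
    data.table(comparison = paste0("exp_vs_", ctrl, "_control"),
               effect = diff, statistic = t, p_raw = p_raw,
               p_adj = pmin(1, 2 * p_raw))
  }))
  .comparison_result(parameter, phase, "anova",
                     if (is.na(Fstat)) 0 else Fstat,
                     if (is.na(p_global)) 1 else p_global, cmp, alpha)
}

#' Kruskal-Wallis with Dunn's planned comparisons vs both controls
#'
#' Tie-corrected Kruskal-Wallis H over the three groups, then Dunn z
#' statistics on mean ranks for the two experimental-vs-control
#' contrasts, with tie-corrected variance and Bonferroni factor 2.
#' Because the tables' "mean difference" unit is ambiguous for rank
#' tests, both the raw mean difference (`effect`) and the mean-rank
#' difference (`rank_effect`) are reported.
#'
#' @inheritParams anova_with_planned
#' @return `damscreen_comparison` with `test_used = "kruskal_wallis"`.
#' @export
kruskal_dunn <- function(exp, gal4, uas, alpha = 0.05,
                         parameter = NA_character_, phase = NA_character_) {
  groups <- list(exp = exp[!is.na(exp)], gal4 = gal4[!is.na(gal4)],
                 uas = uas[!is.na(uas)])
  if (any(lengths(groups) < 1L)) stop("empty group", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  N <- length(y)
  if (length(unique(y)) == 1L) { # everything tied
    H <- 0; p_global <- 1
  } else {
    kw <- kruskal.test(y, g)
    H <- unname(kw$statistic)
    p_global <- kw$p.value
  }
  rk <- rank(y)
  ties <- table(y)
  tie_sum <- sum(ties^3 - ties)
  mean_rank <- tapply(rk, g, mean)
  var_base <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))
  cmp <- rbindlist(lapply(c("gal4", "uas"), function(ctrl) {
    rdiff <- mean_rank[["exp"]] - mean_rank[[ctrl]]
    se <- sqrt(var_base * (1 / length(groups$exp) + 1 / length(groups[[ctrl]])))
    if (se == 0) {
      z <- 0; p_raw <- 1
    } else {
      z <- rdiff / se
      p_raw <- 2 * pnorm(-abs(z))
    }
    data.table(comparison = paste0("exp_vs_", ctrl, "_control"),
               effect = mean(groups$exp) - mean(groups[[ctrl]]),
               rank_effect = rdiff, statistic = z, p_raw = p_raw,
               p_adj = pmin(1, 2 * p_raw))
  }))
  .comparison_result(parameter, phase, "kruskal_wallis", H, p_global, cmp,
                     alpha)
}

#' Compare an experimental group with both genetic controls
#'
#' Normality triage ([normality_triage()]) followed by the matching test
#' family; `test` can force a family.
#'
#' @inheritParams anova_with_planned
#' @param test `"auto"` (triage), `"anova"`, or `"kruskal_wallis"`.
#' @return `damscreen_comparison`.
#' @export
compare_to_controls <- function(exp, gal4, uas, alpha = 0.05,
                                test = c("auto", "anova", "kruskal_wallis"),
                                parameter = NA_character_,
                                phase = NA_character_) {
  test <- match.arg(test)
  if (test == "auto") test <- normality_triage(list(exp, gal4, uas))
  if (test == "anova") {
    anova_with_planned(exp, gal4, uas, alpha, parameter, phase)
  } else {
    kruskal_dunn(exp, gal4, uas, alpha, parameter, phase)
  }
}

#' Two-sample t-test power via the noncentral t distribution
#'
#' Power of the two-sided two-sample t test, with the null group's SD as
#' the common SD (the screen's recipe: null at the control group's
#' mean/SD, alternative at the experimental mean). At zero effect the
#' power equals `alpha`.
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param mean0,sd0 Null (control) mean and SD (`sd0 > 0`).
#' @param mean1 Alternative (experimental) mean.
#' @param alpha Two-sided level.
#' @return Power in `[alpha, 1]`.
#' @export
power_ttest <- function(n1, n2, mean0, sd0, mean1, alpha = 0.05) {
  stopifnot(sd0 > 0, n1 >= 2L, n2 >= 2L)
  df <- n1 + n2 - 2
  ncp <- (mean1 - mean0) / (sd0 * sqrt(1 / n1 + 1 / n2))
  crit <- qt(1 - alpha / 2, df)
  # pt() warns about its last-digit precision at extreme noncentrality
  suppressWarnings(pt(-crit, df, ncp = ncp) + 1 - pt(crit, df, ncp = ncp))
}

#' Screen-wide per-driver significance table
#'
#' Runs [compare_to_controls()] for every driver, parameter and phase of
#' a per-fly delta table, giving the screen's statistical table: test
#' used, global statistic and p, both planned comparisons, and the
#' both-controls significance flag.
#'
#' @param deltas Output of [per_fly_delta()].
#' @param alpha Significance level.
#' @param test Passed to [compare_to_controls()].
#' @return `data.table`, one row per driver x parameter x phase x
#'   comparison.
#' @export
screen_stats <- function(deltas, alpha = 0.05, test = "auto") {
  d <- as.data.table(deltas)
  combos <- unique(d[, .(driver, parameter, phase)])
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sub <- d[driver == combos$driver[i] & parameter == combos$parameter[i] &
               phase == combos$phase[i]]
    res <- compare_to_controls(
      sub[genotype_role == "experimental", value],
      sub[genotype_role == "gal4_control", value],
      sub[genotype_role == "uas_control", value],
      alpha = alpha, test = test,
      parameter = combos$parameter[i], phase = combos$phase[i]
    )
    cmp <- copy(res$comparisons)
    cmp[, `:=`(driver = combos$driver[i], parameter = combos$parameter[i],
               phase = combos$phase[i], test_used = res$test_used,
               global_statistic = res$statistic, p_global = res$p_global,
               significant_overall = res$significant_overall)]
    out[[i]] <- cmp
  }
  res <- rbindlist(out, fill = TRUE)
  setcolorder(res, c("driver", "parameter", "phase", "test_used"))
  res[]
}
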