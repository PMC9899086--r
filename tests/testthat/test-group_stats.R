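test_that("omnibus K2 statistic matches the reference values on frozen samples", {
  set.seed(42)
  x <- round(rnorm(30, 10, 2), 6)
  r <- dagostino_test(x)
  expect_equal(r$statistic, 0.6151803225429289, tolerance = 1e-10)
  expect_equal(r$p_value, 0.735216576498064, tolerance = 1e-10)
  set.seed(43)
  y <- round(rexp(25, 1), 6)
  r2 <- dagostino_test(y)
  expect_equal(r2$statistic, 9.865631054208446, tolerance = 1e-10)
  expect_equal(r2$p_value, 0.0072061854815989, tolerance = 1e-10)
  expect_error(dagostino_test(rnorm(5)), "n >= 8")
})

test_that("triage routes clean Gaussians to ANOVA and skewed data to ranks", {
  set.seed(9)
  pass <- 0
  for (i in 1:50) {
    g <- replicate(3, rnorm(40), simplify = FALSE)
    if (normality_triage(g) == "anova") pass <- pass + 1
  }
  expect_gt(pass / 50, 0.7) # 0.95^3 ~ 0.86 expected all-pass rate
  detect <- 0
  for (i in 1:50) {
    g <- list(rexp(30), rnorm(30), rnorm(30))
    if (normality_triage(g) == "kruskal_wallis") detect <- detect + 1
  }
  expect_gt(detect / 50, 0.7) # true K2 power vs exponential n=30 is ~0.79
  # small-n rule is unconditional
  expect_equal(normality_triage(list(rnorm(5), rnorm(40), rnorm(40))),
               "kruskal_wallis")
  expect_error(normality_triage(list(numeric(0), rnorm(10))), "empty")
})

test_that("identical groups are never significant under either family", {
  g <- rep(5, 12)
  a <- anova_with_planned(g, g, g)
  expect_equal(a$statistic, 0)
  expect_false(a$significant_overall)
  expect_true(all(a$comparisons$p_adj == 1))
  k <- kruskal_dunn(g, g, g)
  expect_equal(k$statistic, 0)
  expect_equal(k$p_global, 1)
  expect_false(k$significant_overall)
})

test_that("the F decomposition matches a hand-computed sums-of-squares oracle", {
  exp <- c(6, 8, 4, 5, 3, 4)
  gal4 <- c(8, 12, 9, 11, 5, 8, 12, 9)
  uas <- c(13, 9, 11, 8, 12)
  res <- anova_with_planned(exp, gal4, uas)
  y <- c(exp, gal4, uas)
  groups <- list(exp, gal4, uas)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - mean(y))^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  Fo <- (ssb / 2) / (ssw / (length(y) - 3))
  expect_equal(res$statistic, Fo)
  expect_equal(res$p_global, 1 - pf(Fo, 2, length(y) - 3))
  # planned comparison against the pooled-variance t by hand
  mse <- ssw / (length(y) - 3)
  t1 <- (mean(exp) - mean(gal4)) / sqrt(mse * (1 / 6 + 1 / 8))
  expect_equal(res$comparisons$statistic[1], t1)
  expect_equal(res$comparisons$p_adj[1],
               min(1, 2 * 2 * pt(-abs(t1), length(y) - 3)))
})

test_that("zero within-group variance with distinct means hits the explicit p = 0 path", {
  res <- anova_with_planned(rep(1, 5), rep(2, 5), rep(3, 5))
  expect_equal(res$comparisons$p_raw, c(0, 0))
  expect_true(res$significant_overall)
})

test_that("a 5-sd shifted experimental group is flagged against both controls", {
  set.seed(14)
  exp <- rnorm(30, 5, 1)
  res <- anova_with_planned(exp, rnorm(30), rnorm(30))
  expect_true(res$significant_overall)
  res2 <- kruskal_dunn(exp, rnorm(30), rnorm(30))
  expect_true(res2$significant_overall)
})

test_that("the KW statistic matches the tie-corrected brute-force formula", {
  exp <- c(1, 2, 2, 3)
  gal4 <- c(2, 3, 3, 4, 4)
  uas <- c(1, 1, 4, 5)
  res <- kruskal_dunn(exp, gal4, uas)
  y <- c(exp, gal4, uas)
  g <- rep(1:3, c(4, 5, 4))
  N <- length(y)
  r <- rank(y)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (N + 1)
  ties <- table(y)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  expect_equal(res$statistic, H)
  expect_equal(res$p_global, 1 - pchisq(H, 2))
  # Dunn z by hand for exp vs gal4
  sig2 <- (N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))) *
    (1 / 4 + 1 / 5)
  z <- (mean(r[g == 1]) - mean(r[g == 2])) / sqrt(sig2)
  expect_equal(res$comparisons$statistic[1], z)
  expect_equal(res$comparisons$p_adj[1], min(1, 2 * 2 * pnorm(-abs(z))))
  expect_true(all(res$comparisons$p_adj >= res$comparisons$p_raw))
})

test_that("KW is invariant under strictly monotone transforms", {
  set.seed(3)
  e <- rexp(12); g4 <- rexp(12); u <- rexp(12)
  h1 <- kruskal_dunn(e, g4, u)$statistic
  h2 <- kruskal_dunn(exp(e), exp(g4), exp(u))$statistic
  expect_equal(h1, h2)
})

test_that("power calculation hits its closed-form anchors", {
  expect_equal(power_ttest(30, 30, 0, 1, 0), 0.05, tolerance = 1e-12)
  # equal-n case agrees with stats::power.t.test
  ref <- stats::power.t.test(n = 30, delta = 1, sd = 1, sig.level = 0.05)$power
  expect_equal(power_ttest(30, 30, 0, 1, 1), ref, tolerance = 1e-6)
  # monotone in n and |effect|
  expect_gt(power_ttest(60, 60, 0, 1, 0.5), power_ttest(30, 30, 0, 1, 0.5))
  expect_gt(power_ttest(30, 30, 0, 1, 1.2), power_ttest(30, 30, 0, 1, 0.8))
})

test_that("screen-level statistics carry the both-controls rule per driver", {
  cfg <- simulation_config(n_drivers = 2, flies_per_genotype = 10, seed = 44,
                           weights_wake = list(DP = c(R4m = 1.5)))
  scr <- simulate_screen(cfg)
  m <- sleep_metrics(scr$activity)
  p <- parameter_table(m)
  d <- per_fly_delta(p, "activation-baseline")
  s <- screen_stats(d)
  expect_true(all(c("driver", "parameter", "phase", "test_used", "p_adj",
                    "significant_overall") %in% names(s)))
  expect_true(all(s$test_used %in% c("anova", "kruskal_wallis")))
  # drivers carrying R4m lose night sleep -> flagged; others not, typically
  r4m <- rownames(cfg$subtype_matrix)[cfg$subtype_matrix[, "R4m"] == 1]
  if (length(r4m) > 0 && length(r4m) < 2) {
    flag <- unique(s[driver %in% r4m & parameter == "total_sleep" &
                       phase == "DP", significant_overall])
    expect_true(flag)
  }
})
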