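make_params <- function() {
  # two flies x two days x one phase, three parameters
  data.table::CJ(fly_id = c("f1", "f2"), day_role = c("baseline", "activation"),
                 parameter = c("total_sleep", "n_episodes", "max_episode"),
                 phase = "LP", sorted = FALSE)[
    , `:=`(genotype = "g", driver = "d", genotype_role = "experimental")][
    , value := c(400, 10, 100, 550, 8, 120,   300, 12, 80, 300, 12, 80)][]
}

test_that("per-fly deltas are paired day differences", {
  d <- per_fly_delta(make_params(), "activation-baseline")
  f1 <- d[fly_id == "f1"]
  expect_equal(f1[parameter == "total_sleep", value], 150)
  expect_equal(f1[parameter == "n_episodes", value], -2)
  expect_equal(f1[parameter == "max_episode", value], 20)
  # identical days give zero for every parameter
  expect_true(all(d[fly_id == "f2", value] == 0))
})

test_that("flies missing a day are skipped and counted", {
  p <- make_params()[!(fly_id == "f2" & day_role == "activation")]
  d <- per_fly_delta(p, "activation-baseline")
  expect_equal(sort(unique(d$fly_id)), "f1")
  expect_equal(attr(d, "n_skipped"), 3L)
})

test_that("control correction arithmetic and linearity", {
  expect_equal(control_correct(0.03, 0.04, 0.02), 0) # exp = control mean
  expect_equal(control_correct(0.10, 0.04, 0.02), 0.07)
  # shared shift (pure temperature effect) cancels
  set.seed(2)
  e <- rnorm(20); g <- rnorm(20); u <- rnorm(20); c0 <- rnorm(1)
  expect_equal(control_correct(e + c0, g + c0, u + c0),
               control_correct(e, g, u))
  # linear in each argument
  expect_equal(control_correct(2 * e, g, u) - control_correct(e, g, u),
               e)
  expect_true(is.na(control_correct(0.1, NA, 0.2)))
})

test_that("change rate handles zero baselines by exclusion", {
  expect_equal(change_rate(550, 500), 0.10)
  expect_equal(change_rate(500, 500), 0)
  expect_true(is.na(change_rate(10, 0)))
  p <- data.table::CJ(fly_id = sprintf("f%d", 1:5),
                      day_role = c("baseline", "activation"),
                      parameter = "total_sleep", phase = "LP", sorted = FALSE)
  p[, `:=`(genotype = "g", driver = "d", genotype_role = "experimental")]
  p[, value := c(100, 110, 0, 50, 200, 100, 0, 30, 100, 150)]
  r <- driver_change_rates(p)
  # two zero-baseline flies excluded; mean over the rest
  expect_equal(r$n_excluded, 2L)
  expect_equal(r$n_flies, 3L)
  base <- p[day_role == "baseline", value]
  act <- p[day_role == "activation", value]
  keep <- base != 0
  expect_equal(r$value, mean((act[keep] - base[keep]) / base[keep]))
})

test_that("driver delta points match a spreadsheet-style recomputation", {
  set.seed(9)
  tr <- data.table::CJ(fly_id = sprintf("f%02d", 1:12),
                       day_role = c("baseline", "activation"),
                       phase = c("LP", "DP"), sorted = FALSE)
  tr[, driver := "drv"]
  tr[, genotype := rep(c("exp", "g4", "uas"), each = 16)]
  tr[, genotype_role := rep(c("experimental", "gal4_control", "uas_control"),
                            each = 16)]
  tr[, `:=`(p_doze = runif(.N, 0.1, 0.4), p_wake = runif(.N, 0.05, 0.3))]
  tr[, `:=`(n_wake_transitions = 10L, n_wake_opportunities = 100L,
            n_doze_transitions = 10L, n_doze_opportunities = 100L)]
  pts <- driver_delta_points(tr, method = "per_fly_mean")
  # direct recomputation for DP / p_wake
  man <- tr[phase == "DP", .(fly_id, genotype_role, day_role, p_wake)]
  wide <- data.table::dcast(man, fly_id + genotype_role ~ day_role,
                            value.var = "p_wake")
  d <- wide[, .(m = mean(activation - baseline)), by = genotype_role]
  want <- d[genotype_role == "experimental", m] -
    (d[genotype_role == "gal4_control", m] +
       d[genotype_role == "uas_control", m]) / 2
  expect_equal(pts[phase == "DP", d_p_wake], want)
  expect_equal(nrow(pts), 2L) # one point per driver per phase
})

test_that("pooled and per-fly aggregation agree for balanced complete counts", {
  scr <- toy_screen(n_drivers = 2, flies = 3, seed = 17)
  tr <- transition_estimates(scr$activity)
  a <- driver_delta_points(tr, method = "per_fly_mean")
  b <- driver_delta_points(tr, method = "pooled")
  expect_equal(a$driver, b$driver)
  # same sign structure and similar magnitude (not identical estimators)
  expect_lt(max(abs(a$d_p_wake - b$d_p_wake), na.rm = TRUE), 0.05)
})

test_that("temperature-only screens are biased raw but centered after correction", {
  cfg <- simulation_config(n_drivers = 8, flies_per_genotype = 6, seed = 23,
                           temperature_effect = c(doze = -0.5, wake = 0.6))
  scr <- simulate_screen(cfg)
  tr <- transition_estimates(scr$activity)
  long <- data.table::melt(
    tr[, .(fly_id, genotype, driver, genotype_role, day_role, phase,
           p_doze, p_wake)],
    id.vars = c("fly_id", "genotype", "driver", "genotype_role", "day_role",
                "phase"),
    variable.name = "parameter", value.name = "value", variable.factor = FALSE)
  raw <- per_fly_delta(long, "activation-baseline")
  raw_mean <- raw[parameter == "p_wake" & phase == "DP" &
                    genotype_role == "experimental", mean(value)]
  expect_gt(raw_mean, 0.01) # temperature bias visible in raw deltas
  pts <- driver_delta_points(tr)
  corrected <- pts[phase == "DP", d_p_wake]
  se <- sd(corrected) / sqrt(length(corrected))
  expect_lt(abs(mean(corrected)), 3 * se + 1e-12)
})
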