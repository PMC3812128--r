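test_that("rmse does the arithmetic and rejects empty pairings", {
  obs <- c(1.3, 0.6, 2.0, 3.5)
  fit <- obs - c(0.3, -0.4, 0.0, 0.5)
  expect_equal(rmse(obs, fit), sqrt(0.125), tolerance = 1e-12)
  expect_equal(rmse(obs, obs), 0)
  expect_error(rmse(c(NA, 1), c(1, NA)), "no complete")
  expect_error(rmse(1:3, 1:4), "same length")
  # dual-accumulation cross-check on many random pairs
  set.seed(14)
  a <- rnorm(1000); b <- rnorm(1000)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_equal(rmse(a, b), sqrt(acc / 1000), tolerance = 1e-12)
})

test_that("a model matching the truth has zero rolling prediction error", {
  s <- line_series(a = 2, b = 0.1, m = 30)
  for (k in c(1L, 5L)) {
    r <- rolling_rmsep(s, "L", k)
    expect_equal(r$rmsep, 0, tolerance = 1e-9)
    expect_equal(nrow(r$points), 20L)
  }
})

test_that("two-origin linear refits match a hand-computed oracle", {
  y <- as.numeric(1:12)
  s <- yield_series("h", 2000L + (1:12), y)
  r <- rolling_rmsep(s, "L", k = 1, target_years = c(2011L, 2012L))
  expect_equal(r$rmsep, 0, tolerance = 1e-12)
  # same series with an outlier at the final year: the 2012 forecast is
  # trained on 2001..2011 (still the exact line), so its error is exactly
  # the outlier; the 2011 forecast is unaffected.
  y2 <- y; y2[12] <- y[12] + 1.0
  s2 <- yield_series("h", 2000L + (1:12), y2)
  r2 <- rolling_rmsep(s2, "L", k = 1, target_years = c(2011L, 2012L))
  expect_equal(r2$rmsep, sqrt((0^2 + 1^2) / 2), tolerance = 1e-9)
})

test_that("every forecast is trained only on data preceding target - k", {
  set.seed(44)
  sim <- simulate_scenario_panel(
    simulation_config("plateau", n_units = 3, seed = 8))
  for (model in c("L", "HW0", "DLM0")) {
    for (k in c(1L, 4L)) {
      r <- rolling_rmsep(sim$panel$series[[1L]], model, k)
      expect_equal(nrow(r$points), 20L)
      expect_true(all(r$points$train_end_year <= r$points$target_year - k))
    }
  }
})

test_that("a too-small training window is a protocol error naming the year", {
  s <- line_series(m = 12)
  expect_error(rolling_rmsep(s, "C", k = 9, target_years = 1971:1972),
               "1971")
  expect_error(rolling_rmsep(s, "LP", k = 1), "plateau")
})

test_that("panel averages, exclusions and percent differences are right", {
  # two units whose per-unit linear RMSEPs are hand-checkable
  s1 <- line_series(a = 2, b = 0.1, m = 25, unit = "u1")
  set.seed(3)
  s2 <- noisy_line_series(a = 2, b = 0.1, m = 25, sd = 0.2, seed = 3,
                          unit = "u2")
  panel <- yield_panel(list(s1, s2), label = "toy")
  tab <- panel_evaluate(panel, models = c("L", "Q"), horizons = 1L)
  r1 <- rolling_rmsep(s1, "L", 1)$rmsep
  r2 <- rolling_rmsep(s2, "L", 1)$rmsep
  row <- tab[tab$model == "L" & tab$statistic == "RMSEP", ]
  expect_equal(row$value, mean(c(r1, r2)), tolerance = 1e-12)
  expect_equal(row$n_units, 2L)
  # percent difference against the group minimum
  grp <- tab[tab$statistic == "RMSEP" & tab$horizon == 1L, ]
  mn <- min(grp$value)
  expect_equal(grp$pct_difference_vs_min, 100 * (grp$value - mn) / mn,
               tolerance = 1e-12)
  expect_equal(sum(grp$pct_difference_vs_min == 0), 1L)
  # worked percent-difference example: (0.42, 0.52) -> (0, 23.81)
  expect_equal(100 * (0.52 - 0.42) / 0.42, 23.8095, tolerance = 1e-4)
})

test_that("units a model cannot fit are excluded and counted", {
  s1 <- noisy_line_series(m = 30, seed = 1, unit = "ok1")
  s2 <- noisy_line_series(m = 30, seed = 2, unit = "ok2")
  s3 <- line_series(m = 4, unit = "short")  # too short for cubic RMSE
  panel <- yield_panel(list(s1, s2, s3), label = "mix")
  tab <- panel_evaluate(panel, models = c("L", "C"), horizons = integer(0))
  expect_equal(tab$n_units[tab$model == "C"], 2L)
  expect_equal(tab$n_units[tab$model == "L"], 3L)
})

test_that("the in-sample linear RMSE equals the closed-form OLS value per unit", {
  set.seed(9)
  s <- noisy_line_series(m = 40, sd = 0.35, seed = 9)
  panel <- yield_panel(list(s), label = "one")
  tab <- panel_evaluate(panel, models = "L", horizons = integer(0))
  beta <- poly_oracle(s$t_index, s$yields, 1)
  res <- s$yields - (beta[1] + beta[2] * s$t_index)
  expect_equal(tab$value[tab$statistic == "RMSE"], sqrt(mean(res^2)),
               tolerance = 1e-10)
})

test_that("panel statistics are invariant to unit ordering", {
  sim <- simulate_scenario_panel(
    simulation_config("plateau", n_units = 3, seed = 21))
  p1 <- sim$panel
  p2 <- yield_panel(rev(p1$series), label = p1$label)
  t1 <- panel_evaluate(p1, models = c("L", "HW0"), horizons = 1L)
  t2 <- panel_evaluate(p2, models = c("L", "HW0"), horizons = 1L)
  key <- function(t) t[order(t$model, t$statistic, t$horizon), ]
  expect_equal(key(t1)$value, key(t2)$value, tolerance = 1e-12)
})

test_that("win-rate counting and stratification behave on simple panels", {
  sim <- simulate_scenario_panel(
    simulation_config("dlm_draw", n_units = 4, seed = 5))
  w <- dlms_vs_dlm0_winrate(sim$panel, k = 1)
  expect_equal(w$overall, 100 * mean(w$per_unit$wins))
  expect_equal(sum(w$per_unit$stratum == "low"), 2L)  # even split at median
  expect_equal(sum(w$per_unit$stratum == "high"), 2L)
  expect_equal(w$overall,
               mean(c(w$low_stratum, w$high_stratum)), tolerance = 1e-9)
  expect_error(dlms_vs_dlm0_winrate(
    yield_panel(list(sim$panel$series[[1L]])), 1), "at least 2")
})

test_that("identical units give a degenerate, uniform win rate", {
  s <- noisy_line_series(m = 35, sd = 0.25, seed = 10)
  panel <- yield_panel(list(
    yield_series("a", s$years, s$yields),
    yield_series("b", s$years, s$yields),
    yield_series("c", s$years, s$yields)), label = "same")
  w <- dlms_vs_dlm0_winrate(panel, k = 1)
  expect_true(w$overall %in% c(0, 100))
  expect_equal(w$low_stratum, w$overall)
})
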