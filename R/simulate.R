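#' Configure a synthetic yield-panel simulation
#'
#' Four scenarios cover the trend shapes national wheat panels exhibit:
#'
#' * `"dlm_draw"` — exact draws from the local linear trend state-space
#'   model with known variances; the latent level and slope paths are
#'   returned so recovery tests can compare against the truth.
#' * `"plateau"` — a deterministic broken line plus Gaussian noise:
#'   yields rise at `rise_rate` from `start_level`, then flatten at the
#'   break year. Defaults mirror a France-like national series: 2.5 t/ha
#'   in 1961 rising at 0.13 t/ha/yr until 1992, plateauing near 6.5 t/ha.
#' * `"accelerating"` — a smooth convex trend whose slope grows linearly
#'   in time (Brazil-like: about 0.5 t/ha in 1961 reaching about 3 t/ha
#'   by 2010).
#' * `"linear"` — a straight line plus noise (no plateau, constant rate).
#'
#' Unit-level parameters are jittered around the configured values so
#' panels are heterogeneous. Identical config and seed give bit-identical
#' panels (R's Mersenne-Twister generator, recorded in the config).
#'
#' @param scenario One of `"dlm_draw"`, `"plateau"`, `"accelerating"`,
#'   `"linear"`.
#' @param n_units Number of geographical units.
#' @param years Calendar years (default 1961:2010, M = 50).
#' @param seed Integer seed.
#' @param start_level Trend level in the first year (t/ha).
#' @param start_slope Initial yearly increase rate (t/ha/yr).
#' @param var_obs,var_level,var_slope Disturbance variances for
#'   `"dlm_draw"`; defaults 0.09, 0.01, 1e-4.
#' @param noise_sd Observation noise sd for the deterministic scenarios
#'   (t/ha).
#' @param break_year Plateau start (calendar year, `"plateau"` only).
#' @param accel Yearly growth of the slope (`"accelerating"` only,
#'   t/ha/yr^2).
#' @param jitter Relative sd of the unit-to-unit lognormal jitter applied
#'   to shape parameters (0 disables heterogeneity).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(scenario = c("dlm_draw", "plateau",
                                           "accelerating", "linear"),
                              n_units = 1L, years = 1961:2010, seed = 1L,
                              start_level = NULL, start_slope = NULL,
                              var_obs = 0.09, var_level = 0.01,
                              var_slope = 1e-4, noise_sd = NULL,
                              break_year = 1992L, accel = 0.00127,
                              jitter = 0.1) {
  scenario <- match.arg(scenario)
  n_units <- as.integer(n_units)
  years <- as.integer(years)
  stopifnot(n_units >= 1L, length(years) >= 10L, all(diff(years) == 1L))
  stopifnot(var_obs >= 0, var_level >= 0, var_slope >= 0, jitter >= 0)
  defaults <- switch(scenario,
    dlm_draw     = list(start_level = 2.5, start_slope = 0.13, noise_sd = NA),
    plateau      = list(start_level = 2.5, start_slope = 0.13, noise_sd = 0.3),
    accelerating = list(start_level = 0.5, start_slope = 0.02, noise_sd = 0.2),
    linear       = list(start_level = 2.5, start_slope = 0.05, noise_sd = 0.25))
  if (is.null(start_level)) start_level <- defaults$start_level
  if (is.null(start_slope)) start_slope <- defaults$start_slope
  if (is.null(noise_sd)) noise_sd <- defaults$noise_sd
  structure(
    list(scenario = scenario, n_units = n_units, years = years,
         seed = as.integer(seed), start_level = start_level,
         start_slope = start_slope, var_obs = var_obs,
         var_level = var_level, var_slope = var_slope, noise_sd = noise_sd,
         break_year = as.integer(break_year), accel = accel,
         jitter = jitter, rng = "Mersenne-Twister"),
    class = "simulation_config")
}

# Yields are floored at 0.05 t/ha (series invariant: positive yields); a
# config whose noise floors more than 1% of draws is rejected rather than
# silently truncated, because truncation would bias recovery tests.
.YIELD_FLOOR <- 0.05

#' Simulate one series from the local linear trend model
#'
#' Draws the slope and level random walks of the state-space model, adds
#' observation noise, and returns the observations alongside the latent
#' truth.
#'
#' @param config A [simulation_config()] with `scenario = "dlm_draw"`.
#' @param unit_id Unit label.
#' @return A list with `series` (a [yield_series()]) and `truth` (data
#'   frame `year`, `true_level`, `true_slope`).
#' @export
simulate_dlm_series <- function(config, unit_id = "sim1") {
  stopifnot(inherits(config, "simulation_config"))
  if (config$scenario != "dlm_draw")
    stop("simulate_dlm_series requires scenario 'dlm_draw'", call. = FALSE)
  set.seed(config$seed)
  out <- draw_dlm_unit(config, unit_id)
  n_floor <- sum(out$series$yields < .YIELD_FLOOR + 1e-12 &
                   out$raw < .YIELD_FLOOR)
  if (n_floor > 0.01 * length(config$years))
    stop("more than 1% of draws hit the positivity floor; ",
         "reduce the noise or raise the start level", call. = FALSE)
  out[c("series", "truth")]
}

draw_dlm_unit <- function(config, unit_id) {
  m <- length(config$years)
  level <- numeric(m); slope <- numeric(m)
  level[1L] <- config$start_level
  slope[1L] <- config$start_slope
  w_l <- rnorm(m, 0, sqrt(config$var_level))
  w_b <- rnorm(m, 0, sqrt(config$var_slope))
  for (t in 2:m) {
    level[t] <- level[t - 1L] + slope[t - 1L] + w_l[t]
    slope[t] <- slope[t - 1L] + w_b[t]
  }
  raw <- level + rnorm(m, 0, sqrt(config$var_obs))
  y <- pmax(raw, .YIELD_FLOOR)
  list(series = yield_series(unit_id, config$years, y),
       truth = data.frame(unit_id = unit_id, year = config$years,
                          true_level = level, true_slope = slope,
                          stringsAsFactors = FALSE),
       raw = raw)
}

jittered <- function(value, rel_sd) {
  if (rel_sd <= 0 || value == 0) return(value)
  value * exp(rnorm(1L, 0, rel_sd))
}

draw_scenario_unit <- function(config, unit_id) {
  yrs <- config$years
  m <- length(yrs)
  tt <- seq_len(m)
  lvl0 <- jittered(config$start_level, config$jitter)
  s0 <- jittered(config$start_slope, config$jitter)
  truth_level <- switch(config$scenario,
    plateau = {
      br <- config$break_year +
        if (config$jitter > 0) round(rnorm(1L, 0, 5 * config$jitter / 0.1)) else 0L
      br <- min(max(br, yrs[3L]), yrs[m - 2L])
      tb <- match(br, yrs)
      lvl0 + s0 * (pmin(tt, tb) - 1)
    },
    accelerating = {
      g <- jittered(config$accel, config$jitter)
      lvl0 + s0 * (tt - 1) + 0.5 * g * (tt - 1)^2
    },
    linear = lvl0 + s0 * (tt - 1),
    stop("unknown scenario '", config$scenario, "'", call. = FALSE))
  truth_slope <- c(diff(truth_level), truth_level[m] - truth_level[m - 1L])
  raw <- truth_level + rnorm(m, 0, config$noise_sd)
  y <- pmax(raw, .YIELD_FLOOR)
  list(series = yield_series(unit_id, yrs, y),
       truth = data.frame(unit_id = unit_id, year = yrs,
                          true_level = truth_level, true_slope = truth_slope,
                          stringsAsFactors = FALSE),
       raw = raw)
}

#' Simulate a panel of yield series under a scenario
#'
#' Generates `n_units` series under the configured scenario (any of the
#' four, including `"dlm_draw"`), with unit-level heterogeneity, and
#' returns the observed panel alongside the per-unit truth.
#'
#' @param config A [simulation_config()].
#' @param unit_prefix Prefix for generated unit ids.
#' @return A list with `panel` (a [yield_panel()]), `truth` (row-bound
#'   truth data frame) and `n_floored` (count of draws raised to the
#'   positivity floor).
#' @export
simulate_scenario_panel <- function(config, unit_prefix = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(unit_prefix))
    unit_prefix <- switch(config$scenario, dlm_draw = "D", plateau = "P",
                          accelerating = "A", linear = "L")
  set.seed(config$seed)
  units <- vector("list", config$n_units)
  n_raw_floor <- 0L; n_total <- 0L
  for (i in seq_len(config$n_units)) {
    uid <- sprintf("%s%03d", unit_prefix, i)
    u <- if (config$scenario == "dlm_draw") draw_dlm_unit(config, uid)
         else draw_scenario_unit(config, uid)
    n_raw_floor <- n_raw_floor + sum(u$raw < .YIELD_FLOOR)
    n_total <- n_total + length(u$raw)
    units[[i]] <- u
  }
  if (n_raw_floor > 0.01 * n_total)
    stop("more than 1% of simulated yields hit the positivity floor (",
         n_raw_floor, "/", n_total, "); the configuration is rejected ",
         "because truncation would distort the panel", call. = FALSE)
  list(panel = yield_panel(lapply(units, `[[`, "series"),
                           label = paste0(config$scenario, "_panel")),
       truth = do.call(rbind, c(lapply(units, `[[`, "truth"),
                                list(make.row.names = FALSE))),
       n_floored = n_raw_floor)
}

#' Write a simulated panel and its truth to disk
#'
#' The panel is written in the default FAOSTAT-like dialect readable by
#' [read_yield_panel()]; the latent truth goes to a sibling
#' `*_truth.csv` so no pipeline stage can confuse data with truth.
#'
#' @param sim Result of [simulate_scenario_panel()].
#' @param path Output path for the panel CSV.
#' @return Invisibly, c(panel_path, truth_path).
#' @export
write_simulation <- function(sim, path) {
  write_yield_panel(sim$panel, path)
  truth_path <- if (grepl("\\.csv$", path))
    sub("\\.csv$", "_truth.csv", path) else paste0(path, "_truth.csv")
  write_result_table(sim$truth, truth_path)
  invisible(c(panel = path, truth = truth_path))
}
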