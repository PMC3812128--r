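#' Run one stage of the yield-trend pipeline
#'
#' Programmatic entry point behind the command-line wrapper shipped in
#' `inst/cli/yieldtrends.R`. Five commands cover the full analysis:
#'
#' * `simulate` — write a synthetic panel (+ truth) under a scenario.
#' * `fit` — per-unit parameter table for the requested models.
#' * `rates` — smoothed yearly yield-increase-rate trajectories with
#'   uncertainty bands and final-year coefficients of variation.
#' * `evaluate` — RMSE / rolling-origin RMSEP comparison table.
#' * `compare` — win-rate table of the local linear trend model versus
#'   the local level model, stratified by final increase rate.
#'
#' Every run writes a `manifest.txt` (resolved configuration, seed,
#' package version, input checksum) into the output directory so it can
#' be replayed exactly. Units on which a model fails to fit produce a
#' warning and are tabulated, never a hard failure, so large panel runs
#' always complete.
#'
#' @param command One of `"simulate"`, `"fit"`, `"rates"`, `"evaluate"`,
#'   `"compare"`.
#' @param input Input panel CSV (all commands except `simulate`).
#' @param output_dir Directory for result tables (created if needed).
#' @param models Character vector of model ids (fit/evaluate).
#' @param horizons Integer horizons for RMSEP (evaluate/compare).
#' @param target_years Evaluation window (evaluate/compare); `NULL` means
#'   the last 20 years of each series.
#' @param scenario,n_units,years Simulation settings (`simulate`).
#' @param seed Integer seed (simulate).
#' @param dialect Input dialect for [read_yield_panel()].
#' @param digits Decimals in written tables.
#' @param verbose Log one line per unit x model.
#' @return Invisibly, a list with the written file paths and the main
#'   result object.
#' @export
run_yield_pipeline <- function(command = c("simulate", "fit", "rates",
                                           "evaluate", "compare"),
                               input = NULL, output_dir = ".",
                               models = c("L", "Q", "C", "DLM0", "DLMs"),
                               horizons = 1:10, target_years = NULL,
                               scenario = "plateau", n_units = 10L,
                               years = 1961:2010, seed = 1L,
                               dialect = "faostat", digits = 6,
                               verbose = FALSE) {
  command <- match.arg(command)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) if (verbose) message(sprintf(...))
  warnings_seen <- character(0)

  load_panel <- function() {
    if (is.null(input) || !file.exists(input))
      stop("command '", command, "' needs an existing --input panel file",
           call. = FALSE)
    read_yield_panel(input, dialect = dialect)
  }

  paths <- character(0)
  result <- NULL

  if (command == "simulate") {
    config <- simulation_config(scenario = scenario, n_units = n_units,
                                years = years, seed = seed)
    sim <- simulate_scenario_panel(config)
    out <- file.path(output_dir, "panel.csv")
    paths <- write_simulation(sim, out)
    result <- sim
    log_line("simulated %d '%s' units -> %s", n_units, scenario, out)
  } else if (command == "fit") {
    panel <- load_panel()
    rows <- list()
    for (s in panel$series) {
      for (model in models) {
        t0 <- proc.time()[["elapsed"]]
        fit <- tryCatch(fit_trend_model(s, model), error = function(e) e)
        if (inherits(fit, "error")) {
          warnings_seen <- c(warnings_seen,
                             sprintf("%s/%s: %s", s$unit_id, model,
                                     conditionMessage(fit)))
          next
        }
        rows[[length(rows) + 1L]] <- fit_parameter_rows(fit, model)
        log_line("fit %s x %s [%.2fs]", s$unit_id, model,
                 proc.time()[["elapsed"]] - t0)
      }
    }
    result <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    out <- file.path(output_dir, "fits.csv")
    write_result_table(result, out, digits = digits)
    paths <- out
  } else if (command == "rates") {
    panel <- load_panel()
    rows <- list(); cvs <- list()
    for (s in panel$series) {
      tr <- tryCatch(increase_rate_trajectory(s), error = function(e) e)
      if (inherits(tr, "error")) {
        warnings_seen <- c(warnings_seen,
                           sprintf("%s: %s", s$unit_id, conditionMessage(tr)))
        next
      }
      rows[[length(rows) + 1L]] <- as.data.frame(tr)
      cvs[[length(cvs) + 1L]] <- data.frame(
        unit_id = s$unit_id,
        final_slope = tr$slope[nrow(tr)],
        final_sd = tr$sd[nrow(tr)],
        cv_pct = attr(tr, "cv_final"),
        cv_category = attr(tr, "cv_category"), stringsAsFactors = FALSE)
      log_line("rates %s", s$unit_id)
    }
    result <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    out1 <- file.path(output_dir, "rates.csv")
    out2 <- file.path(output_dir, "rates_final_cv.csv")
    write_result_table(result, out1, digits = digits)
    write_result_table(do.call(rbind, c(cvs, list(make.row.names = FALSE))),
                       out2, digits = digits)
    paths <- c(out1, out2)
  } else if (command == "evaluate") {
    panel <- load_panel()
    result <- panel_evaluate(panel, models = models, horizons = horizons,
                             target_years = target_years)
    out <- file.path(output_dir, "evaluation.csv")
    write_result_table(as.data.frame(result), out, digits = digits)
    paths <- out
  } else if (command == "compare") {
    panel <- load_panel()
    cache <- new_fit_cache()
    rows <- lapply(horizons, function(k) {
      w <- dlms_vs_dlm0_winrate(panel, k, target_years, cache)
      data.frame(horizon = k, overall_pct = w$overall,
                 low_stratum_pct = w$low_stratum,
                 high_stratum_pct = w$high_stratum,
                 median_slope = w$median_slope, stringsAsFactors = FALSE)
    })
    result <- do.call(rbind, rows)
    out <- file.path(output_dir, "winrates.csv")
    write_result_table(result, out, digits = digits)
    paths <- out
  }

  manifest <- c(
    sprintf("command: %s", command),
    sprintf("package: yieldtrends %s", as.character(packageVersion("yieldtrends"))),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("models: %s", paste(models, collapse = ",")),
    sprintf("horizons: %s", paste(horizons, collapse = ",")),
    sprintf("scenario: %s", scenario),
    sprintf("input: %s", if (is.null(input)) "-" else input),
    sprintf("input_md5: %s",
            if (is.null(input) || !file.exists(input)) "-"
            else unname(tools::md5sum(input))),
    sprintf("outputs: %s", paste(paths, collapse = ",")),
    sprintf("warnings: %d", length(warnings_seen)),
    if (length(warnings_seen)) paste("  -", warnings_seen) else character(0))
  writeLines(manifest, file.path(output_dir, "manifest.txt"))
  if (length(warnings_seen))
    warning(length(warnings_seen), " unit x model combination(s) failed; ",
            "see manifest.txt", call. = FALSE)
  invisible(list(paths = paths, result = result,
                 manifest = file.path(output_dir, "manifest.txt"),
                 warnings = warnings_seen))
}

# Long-format parameter rows for the fit table.
fit_parameter_rows <- function(fit, model) {
  param_row <- function(parameter, estimate) {
    data.frame(unit_id = fit$unit_id, model = model, parameter = parameter,
               estimate = estimate,
               converged = isTRUE(fit$converged), stringsAsFactors = FALSE)
  }
  if (model %in% c("L", "Q", "C")) {
    nm <- c("a", "b", "c", "d")[seq_len(fit$degree + 1L)]
    do.call(rbind, Map(param_row, nm, fit$coefficients))
  } else if (model == "LP") {
    if (!isTRUE(fit$converged)) return(param_row("Ymax", NA_real_))
    rbind(param_row("Ymax", fit$Ymax), param_row("T_break", fit$T_break),
          param_row("R", fit$R))
  } else if (model %in% c("HW0", "HWs")) {
    out <- rbind(param_row("alpha", fit$alpha), param_row("sse", fit$sse))
    if (!is.null(fit$beta)) out <- rbind(out, param_row("beta", fit$beta))
    out
  } else {
    out <- rbind(param_row("var_obs", fit$spec$var_obs),
                 param_row("var_level", fit$spec$var_level),
                 param_row("loglik", fit$loglik))
    if (fit$order == 1L)
      out <- rbind(out, param_row("var_slope", fit$spec$var_slope))
    out
  }
}
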