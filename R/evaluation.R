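#' Model identifiers
#'
#' The eight models compared by the package: polynomial trends `L`, `Q`,
#' `C`; the segmented `LP` trend; Holt-Winters `HW0` / `HWs`; dynamic
#' linear models `DLM0` / `DLMs`.
#'
#' @return Character vector of identifiers.
#' @export
model_ids <- function() c("L", "Q", "C", "LP", "HW0", "HWs", "DLM0", "DLMs")

# Minimum observed yields each model needs before it may be fitted.
.model_min_obs <- c(L = 3L, Q = 4L, C = 5L, LP = 6L,
                    HW0 = 4L, HWs = 4L, DLM0 = 5L, DLMs = 8L)

#' Fit any of the eight models by its identifier
#'
#' Thin dispatcher used by the evaluation protocol and the pipeline
#' driver.
#'
#' @param series A [yield_series()].
#' @param model One of [model_ids()].
#' @return The model-specific fit object.
#' @export
fit_trend_model <- function(series, model) {
  switch(model,
         L = fit_polynomial(series, 1L),
         Q = fit_polynomial(series, 2L),
         C = fit_polynomial(series, 3L),
         LP = fit_linear_plateau(series),
         HW0 = fit_holt_winters(series, "HW0"),
         HWs = fit_holt_winters(series, "HWs"),
         DLM0 = fit_dlm(series, 0L),
         DLMs = fit_dlm(series, 1L),
         stop("unknown model '", model, "'", call. = FALSE))
}

# Forecast the yield at absolute time index target_t from a fit whose
# training data ended at index last_t. Regression models extrapolate the
# curve; HW and DLM forecast k = target_t - last_t steps ahead.
forecast_trend_model <- function(fit, model, target_t, last_t) {
  if (model %in% c("L", "Q", "C", "LP")) {
    predict(fit, target_t)
  } else if (model %in% c("HW0", "HWs")) {
    hw_forecast(fit$state, target_t - last_t)
  } else {
    dlm_forecast(fit, target_t - last_t)$mean
  }
}

#' Create a fit cache for rolling-origin evaluation
#'
#' Within one evaluation run, the model refitted on data up to a given
#' origin year is identical across all (target year, horizon) pairs that
#' share that origin, so fits are cached by (unit, model, origin year).
#' Every origin still gets its own fresh fit; no state leaks between
#' origins.
#'
#' @return An environment usable as the `cache` argument of
#'   [rolling_rmsep()] and [panel_evaluate()].
#' @export
new_fit_cache <- function() new.env(parent = emptyenv())

cached_fit <- function(series, model, train_end_year, cache) {
  train <- truncate_series(series, train_end_year)
  if (n_observed(train) < .model_min_obs[[model]])
    stop("training data up to ", train_end_year, " has only ",
         n_observed(train), " observations; model ", model, " needs ",
         .model_min_obs[[model]], call. = FALSE)
  if (is.null(cache))
    return(list(fit = fit_trend_model(train, model), train = train))
  key <- paste(series$unit_id, model, train_end_year, sep = "\r")
  if (!exists(key, envir = cache, inherits = FALSE)) {
    assign(key, list(fit = fit_trend_model(train, model), train = train),
           envir = cache)
  }
  get(key, envir = cache, inherits = FALSE)
}

#' Root mean square error
#'
#' @param observed,fitted Paired numeric vectors; pairs with a missing
#'   member are dropped.
#' @return RMSE over the remaining pairs (t/ha).
#' @export
rmse <- function(observed, fitted) {
  if (length(observed) != length(fitted))
    stop("observed and fitted must have the same length", call. = FALSE)
  keep <- !is.na(observed) & !is.na(fitted)
  if (!any(keep)) stop("no complete (observed, fitted) pairs", call. = FALSE)
  sqrt(mean((observed[keep] - fitted[keep])^2))
}

#' Rolling-origin k-year-ahead prediction error (RMSEP)
#'
#' For each target year `t` in the evaluation window the model is refitted
#' from scratch on all data up to year `t - k` and used to predict the
#' yield in year `t`; RMSEP is the root mean square of those out-of-sample
#' errors. The segmented `LP` model is excluded: its break date is not
#' reliably identifiable on truncated series.
#'
#' @param series A [yield_series()].
#' @param model One of [model_ids()] except `"LP"`.
#' @param k Horizon in years, >= 1.
#' @param target_years Calendar years to predict. Default: the last 20
#'   years of the series.
#' @param cache Optional [new_fit_cache()] shared across calls.
#' @return An `rmsep_result`: list with `rmsep`, `model`, `k` and
#'   `points`, a data frame of forecast points recording for each target
#'   year the training-set end used (for protocol audit).
#' @export
rolling_rmsep <- function(series, model, k, target_years = NULL,
                          cache = NULL) {
  stopifnot(inherits(series, "yield_series"))
  model <- match.arg(model, model_ids())
  if (model == "LP")
    stop("RMSEP is not defined for the linear-plus-plateau model ",
         "(unidentifiable break date on truncated series)", call. = FALSE)
  k <- as.integer(k)
  stopifnot(length(k) == 1L, k >= 1L)
  if (is.null(target_years)) {
    last <- series$years[length(series$years)]
    target_years <- seq(max(series$years[1L] + 1L, last - 19L), last)
  }
  target_years <- as.integer(sort(target_years))
  pts <- vector("list", length(target_years))
  for (i in seq_along(target_years)) {
    ty <- target_years[i]
    entry <- tryCatch(cached_fit(series, model, ty - k, cache),
                      error = function(e) e)
    if (inherits(entry, "error"))
      stop("target year ", ty, " (horizon ", k, "): ",
           conditionMessage(entry), call. = FALSE)
    train <- entry$train
    target_t <- series$t_index[match(ty, series$years)]
    if (is.na(target_t))
      stop("target year ", ty, " is outside the series", call. = FALSE)
    last_t <- train$t_index[length(train$t_index)]
    pred <- forecast_trend_model(entry$fit, model, target_t, last_t)
    obs <- series$yields[match(ty, series$years)]
    pts[[i]] <- data.frame(
      unit_id = series$unit_id, model = model, target_year = ty,
      horizon = k, predicted = pred, observed = obs,
      train_end_year = train$years[length(train$years)],
      n_train = n_observed(train), stringsAsFactors = FALSE)
  }
  points <- do.call(rbind, pts)
  structure(
    list(rmsep = rmse(points$observed, points$predicted),
         model = model, k = k, unit_id = series$unit_id, points = points),
    class = "rmsep_result")
}

# In-sample fitted values used for RMSE: regression fits report their own,
# DLMs report the smoothed level (the retrospective trend), HW models are
# forecast-only and have no goodness-of-fit RMSE.
fit_rmse_for_model <- function(series, model) {
  if (model %in% c("HW0", "HWs")) return(NA_real_)
  fit <- fit_trend_model(series, model)
  if (model == "LP") {
    if (!isTRUE(fit$converged)) return(NA_real_)
    return(fit_rmse(fit))
  }
  if (model %in% c("DLM0", "DLMs")) {
    sm <- fit$smoother
    return(rmse(series$yields, sm$level))
  }
  fit_rmse(fit)
}

#' Evaluate a panel of series with several models
#'
#' Computes, per model: the in-sample RMSE (fit on the full series;
#' reported with horizon 0) and the rolling-origin RMSEP at each requested
#' horizon. Statistics are computed per unit and then averaged
#' arithmetically over units (set `aggregate = "pooled"` to pool squared
#' errors across units instead). Units where a model cannot be fitted are
#' excluded from that model's average and reflected in `n_units`. Percent
#' differences are relative to the best model within each
#' (statistic, horizon) group. Holt-Winters models are forecast-only and
#' get no RMSE row; the segmented `LP` model gets no RMSEP rows.
#'
#' @param panel A [yield_panel()].
#' @param models Subset of [model_ids()].
#' @param horizons Integer vector of horizons (default `1:10`); use
#'   `integer(0)` to skip RMSEP.
#' @param target_years Evaluation window passed to [rolling_rmsep()].
#' @param aggregate `"mean"` (per-unit statistics averaged) or `"pooled"`.
#' @param cache Optional shared [new_fit_cache()].
#' @param rmse_models Models for which in-sample RMSE is computed;
#'   defaults to all requested models that support it.
#' @return An `evaluation_table` data frame with columns `dataset_label`,
#'   `model`, `statistic`, `horizon`, `value`, `pct_difference_vs_min`,
#'   `n_units`.
#' @export
panel_evaluate <- function(panel, models = model_ids(), horizons = 1:10,
                           target_years = NULL,
                           aggregate = c("mean", "pooled"),
                           cache = new_fit_cache(), rmse_models = NULL) {
  stopifnot(inherits(panel, "yield_panel"), length(panel$series) > 0L)
  aggregate <- match.arg(aggregate)
  models <- match.arg(models, model_ids(), several.ok = TRUE)
  if (is.null(rmse_models))
    rmse_models <- setdiff(models, c("HW0", "HWs"))
  rows <- list()

  for (model in rmse_models) {
    vals <- vapply(panel$series, function(s)
      tryCatch(fit_rmse_for_model(s, model), error = function(e) NA_real_),
      numeric(1L))
    ok <- !is.na(vals)
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- data.frame(
      dataset_label = panel$label, model = model, statistic = "RMSE",
      horizon = 0L, value = mean(vals[ok]), pct_difference_vs_min = NA_real_,
      n_units = sum(ok), stringsAsFactors = FALSE)
  }

  rmsep_models <- setdiff(models, "LP")
  for (model in rmsep_models) {
    for (k in horizons) {
      res <- lapply(panel$series, function(s)
        tryCatch(rolling_rmsep(s, model, k, target_years, cache),
                 error = function(e) NULL))
      if (aggregate == "mean") {
        vals <- vapply(res, function(r)
          if (is.null(r)) NA_real_ else r$rmsep, numeric(1L))
        ok <- !is.na(vals)
        if (!any(ok)) next
        value <- mean(vals[ok]); n_units <- sum(ok)
      } else {
        pts <- do.call(rbind, lapply(res, function(r) if (is.null(r)) NULL else r$points))
        if (is.null(pts) || nrow(pts) == 0L) next
        value <- rmse(pts$observed, pts$predicted)
        n_units <- length(unique(pts$unit_id))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        dataset_label = panel$label, model = model, statistic = "RMSEP",
        horizon = as.integer(k), value = value,
        pct_difference_vs_min = NA_real_, n_units = n_units,
        stringsAsFactors = FALSE)
    }
  }

  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no statistic could be computed", call. = FALSE)
  for (grp in split(seq_len(nrow(tab)),
                    paste(tab$statistic, tab$horizon, sep = "\r"))) {
    mn <- min(tab$value[grp])
    tab$pct_difference_vs_min[grp] <- 100 * (tab$value[grp] - mn) / mn
  }
  rownames(tab) <- NULL
  class(tab) <- c("evaluation_table", "data.frame")
  tab
}

#' Where does the local linear trend model beat the local level model?
#'
#' For each unit, compares the rolling-origin RMSEP of the local linear
#' trend model ("DLMs") with that of the local level model ("DLM0") at
#' horizon `k`, and reports the percentage of units where DLMs wins,
#' overall and stratified by the unit's estimated final yield-increase
#' rate. Strata are split at the across-unit median of the DLMs smoothed
#' slope in the last year common to all units; units at or below the
#' median (the median itself is the lower central order statistic for an
#' even unit count) form the low-rate stratum.
#'
#' @param panel A [yield_panel()] with at least 2 units.
#' @param k Horizon in years.
#' @param target_years Evaluation window passed to [rolling_rmsep()].
#' @param cache Optional shared [new_fit_cache()].
#' @return A `winrate_result`: list with `overall`, `low_stratum`,
#'   `high_stratum` (percentages), `k`, `median_slope` and the `per_unit`
#'   data frame.
#' @export
dlms_vs_dlm0_winrate <- function(panel, k, target_years = NULL,
                                 cache = new_fit_cache()) {
  stopifnot(inherits(panel, "yield_panel"))
  if (length(panel$series) < 2L)
    stop("need at least 2 units to stratify win rates", call. = FALSE)
  common_last <- min(vapply(panel$series, function(s)
    max(s$years[!is.na(s$yields)]), numeric(1L)))
  per_unit <- lapply(panel$series, function(s) {
    r1 <- rolling_rmsep(s, "DLMs", k, target_years, cache)
    r0 <- rolling_rmsep(s, "DLM0", k, target_years, cache)
    fit <- cached_fit(s, "DLMs", max(s$years), cache)$fit
    sm <- fit$smoother
    idx <- match(common_last, sm$years)
    if (is.na(idx)) idx <- length(sm$years)
    data.frame(unit_id = s$unit_id, rmsep_dlms = r1$rmsep,
               rmsep_dlm0 = r0$rmsep, final_slope = sm$slope[idx],
               stringsAsFactors = FALSE)
  })
  per_unit <- do.call(rbind, c(per_unit, list(make.row.names = FALSE)))
  per_unit$wins <- per_unit$rmsep_dlms < per_unit$rmsep_dlm0
  n <- nrow(per_unit)
  sorted <- sort(per_unit$final_slope)
  med <- sorted[floor((n + 1L) / 2L)]  # lower central value for even n
  per_unit$stratum <- ifelse(per_unit$final_slope > med, "high", "low")
  pct <- function(x) if (length(x) == 0L) NA_real_ else 100 * mean(x)
  structure(
    list(overall = pct(per_unit$wins),
         low_stratum = pct(per_unit$wins[per_unit$stratum == "low"]),
         high_stratum = pct(per_unit$wins[per_unit$stratum == "high"]),
         k = k, median_slope = med, per_unit = per_unit),
    class = "winrate_result")
}

#' @export
print.winrate_result <- function(x, ...) {
  cat(sprintf(paste0("<winrate_result> k=%d: DLMs beats DLM0 in %.1f%% of ",
                     "units (low-rate stratum %.1f%%, high-rate %.1f%%)\n"),
              x$k, x$overall, x$low_stratum, x$high_stratum))
  invisible(x)
}
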