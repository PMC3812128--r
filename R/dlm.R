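#' Specify a dynamic linear model for yearly yield series
#'
#' Two univariate structural models are supported. `order = 0` is the
#' local level (random walk) model: the yield level follows a random walk
#' and observations are the level plus noise; forecasts are flat. `order
#' = 1` is the local linear trend model: the level is driven by a
#' time-varying slope that itself follows a random walk, so the yearly
#' yield-increase rate is a latent state that can rise, stagnate or turn
#' negative over the course of a series.
#'
#' @param order 0 (local level) or 1 (local linear trend).
#' @param var_obs Observation-noise variance (t^2/ha^2); must be > 0.
#' @param var_level Level disturbance variance; >= 0.
#' @param var_slope Slope disturbance variance (order 1 only); >= 0.
#' @param init_mean Prior mean of the state (length 1 or 2); default 0.
#' @param init_var Prior variance put on each state component. The default
#'   `1e7` is an effectively diffuse prior; the first `order + 1` one-step
#'   prediction errors are excluded from the likelihood to neutralise it.
#' @return A `dlm_spec` object.
#' @export
dlm_spec <- function(order, var_obs, var_level, var_slope = NULL,
                     init_mean = NULL, init_var = 1e7) {
  order <- as.integer(order)
  if (!order %in% c(0L, 1L)) stop("order must be 0 or 1", call. = FALSE)
  stopifnot(is.numeric(var_obs), var_obs > 0, is.finite(var_obs))
  stopifnot(is.numeric(var_level), var_level >= 0, is.finite(var_level))
  if (order == 0L) {
    if (!is.null(var_slope))
      stop("var_slope has no meaning for the local level model", call. = FALSE)
  } else {
    stopifnot(is.numeric(var_slope), var_slope >= 0, is.finite(var_slope))
  }
  d <- order + 1L
  if (is.null(init_mean)) init_mean <- rep(0, d)
  init_mean <- rep_len(as.numeric(init_mean), d)
  stopifnot(is.numeric(init_var), init_var >= 0)
  structure(
    list(order = order, var_obs = var_obs, var_level = var_level,
         var_slope = if (order == 1L) var_slope else NULL,
         init_mean = init_mean, init_var = init_var),
    class = "dlm_spec")
}

#' @export
print.dlm_spec <- function(x, ...) {
  cat(sprintf("<dlm_spec> %s: var_obs=%.4g var_level=%.4g%s\n",
              if (x$order == 0L) "local level (DLM0)" else "local linear trend (DLMs)",
              x$var_obs, x$var_level,
              if (x$order == 1L) sprintf(" var_slope=%.4g", x$var_slope) else ""))
  invisible(x)
}

check_series_for_dlm <- function(series) {
  stopifnot(inherits(series, "yield_series"))
  if (n_observed(series) < 2L)
    stop("need at least 2 observed yields for state-space filtering (unit ",
         series$unit_id, ")", call. = FALSE)
}

#' Kalman filter for a yield series
#'
#' Forward recursion giving, for each year, the one-step-ahead (predicted)
#' and filtered state mean and covariance, the one-step forecast of the
#' observation with its variance, and the prediction-error-decomposition
#' log-likelihood. Missing years skip the measurement update.
#'
#' @param series A [yield_series()].
#' @param spec A [dlm_spec()].
#' @return A `kalman_filter` object; state covariances are stored as
#'   columns `(c11, c12, c22)` of the level/slope covariance matrix.
#' @export
kalman_filter <- function(series, spec) {
  check_series_for_dlm(series)
  stopifnot(inherits(spec, "dlm_spec"))
  out <- .dlm_filter_cpp(series$yields, spec$order, spec$var_obs,
                         spec$var_level,
                         if (spec$order == 1L) spec$var_slope else 0,
                         spec$init_mean[1L],
                         if (spec$order == 1L) spec$init_mean[2L] else 0,
                         spec$init_var)
  out$years <- series$years
  out$t_index <- series$t_index
  out$observed <- !is.na(series$yields)
  out$spec <- spec
  out$unit_id <- series$unit_id
  class(out) <- "kalman_filter"
  out
}

#' Kalman smoother for a yield series
#'
#' Backward (Rauch-Tung-Striebel) recursion giving the mean and variance of
#' the level and slope in each year conditional on the full series. These
#' smoothed quantities are what all retrospective trend reporting uses.
#' Posterior quantiles are Gaussian: quartiles at mean +/- 0.67448975 sd
#' and the 95% interval at mean +/- 1.959964 sd.
#'
#' @param series A [yield_series()].
#' @param spec A [dlm_spec()].
#' @return A `smoother_output` with per-year smoothed level/slope means
#'   and variances, slope quartiles and 95% bounds, the underlying filter
#'   and the log-likelihood.
#' @export
kalman_smoother <- function(series, spec) {
  kf <- kalman_filter(series, spec)
  sm <- .dlm_smoother_cpp(spec$order, kf$pred_mean, kf$pred_cov,
                          kf$filt_mean, kf$filt_cov)
  lvl_var <- pmax(sm$smooth_cov[, 1L], 0)
  slp_var <- pmax(sm$smooth_cov[, 3L], 0)
  # Smoothing conditions on more data than filtering; allow only
  # floating-point slack in the information inequality.
  tol <- 1e-6 * (1 + max(kf$filt_cov[, 1L]))
  if (any(sm$smooth_cov[, 1L] > kf$filt_cov[, 1L] + tol))
    stop("smoothed level variance exceeds filtered variance; ",
         "numerical failure in the backward pass", call. = FALSE)
  slope_mean <- if (spec$order == 1L) sm$smooth_mean[, 2L] else rep(0, length(lvl_var))
  slope_sd <- sqrt(slp_var)
  structure(
    list(years = kf$years,
         t_index = kf$t_index,
         level = sm$smooth_mean[, 1L],
         level_var = lvl_var,
         slope = slope_mean,
         slope_var = slp_var,
         slope_q1 = slope_mean - .QUARTILE_Z * slope_sd,
         slope_q3 = slope_mean + .QUARTILE_Z * slope_sd,
         slope_lo95 = slope_mean - .CI95_Z * slope_sd,
         slope_hi95 = slope_mean + .CI95_Z * slope_sd,
         log_likelihood = kf$loglik,
         filter = kf,
         spec = spec,
         unit_id = kf$unit_id),
    class = "smoother_output")
}

# Gaussian quantile constants, fixed so results are bit-stable.
.QUARTILE_Z <- 0.67448975
.CI95_Z <- 1.959964

#' @export
print.smoother_output <- function(x, ...) {
  n <- length(x$years)
  cat(sprintf("<smoother_output> %s, %d years, logLik %.3f\n",
              x$unit_id, n, x$log_likelihood))
  cat(sprintf("  final level %.3f (sd %.3f), final slope %.4f (sd %.4f)\n",
              x$level[n], sqrt(x$level_var[n]), x$slope[n], sqrt(x$slope_var[n])))
  invisible(x)
}

#' @export
as.data.frame.smoother_output <- function(x, ...) {
  data.frame(unit_id = x$unit_id, year = x$years, level = x$level,
             level_sd = sqrt(x$level_var), slope = x$slope,
             slope_sd = sqrt(x$slope_var), q1 = x$slope_q1, q3 = x$slope_q3,
             lo95 = x$slope_lo95, hi95 = x$slope_hi95,
             stringsAsFactors = FALSE)
}

# Method-of-moments heuristics on first/second differences give the
# multi-start points for the variance MLE; likelihood surfaces of
# structural models are flat near zero variances, so several starts are
# cheap insurance.
dlm_start_points <- function(y, order) {
  y <- y[!is.na(y)]
  vd <- var(diff(y))
  if (!is.finite(vd) || vd <= 0) vd <- max(var(y), 1e-4)
  if (order == 0L) {
    props <- list(c(0.5, 0.5), c(0.9, 0.1), c(0.1, 0.9),
                  c(0.7, 0.3), c(0.3, 0.7))
    lapply(props, function(p) log(pmax(vd * p, 1e-10)))
  } else {
    vd2 <- var(diff(diff(y)))
    if (!is.finite(vd2) || vd2 <= 0) vd2 <- vd
    list(log(pmax(c(vd * 0.5, vd * 0.5, vd2 * 0.01), 1e-10)),
         log(pmax(c(vd * 0.9, vd * 0.1, vd2 * 0.001), 1e-10)),
         log(pmax(c(vd * 0.1, vd * 0.9, vd2 * 0.01), 1e-10)),
         log(pmax(c(vd * 0.45, vd * 0.45, vd2 * 0.1), 1e-10)),
         log(pmax(c(vd * 0.8, vd * 0.15, vd2 * 1e-4), 1e-10)))
  }
}

#' Maximum-likelihood fit of a dynamic linear model
#'
#' Estimates the disturbance variances by maximising the
#' prediction-error-decomposition log-likelihood. The optimisation runs in
#' log-variance coordinates (so variances stay positive, floored at
#' 1e-12), with Nelder-Mead refinement from five method-of-moments
#' starting points.
#'
#' @param series A [yield_series()]; at least 5 (order 0) or 8 (order 1)
#'   observed yields.
#' @param order 0 (local level, "DLM0") or 1 (local linear trend, "DLMs").
#' @param init_var Prior variance scale (diffuse by default).
#' @return A `dlm_fit` with the maximising `spec`, the `smoother`
#'   output at the optimum, `loglik` and `converged`.
#' @export
fit_dlm <- function(series, order, init_var = 1e7) {
  stopifnot(inherits(series, "yield_series"))
  order <- as.integer(order)
  need <- if (order == 1L) 8L else 5L
  if (n_observed(series) < need)
    stop("need at least ", need, " observed yields for order ", order,
         " (unit ", series$unit_id, ")", call. = FALSE)
  y <- series$yields
  nll <- function(lv) {
    v <- pmax(exp(lv), 1e-12)
    .dlm_negloglik_cpp(y, order, v[1L], v[2L],
                       if (order == 1L) v[3L] else 0, 0, 0, init_var)
  }
  best <- NULL
  for (start in dlm_start_points(y, order)) {
    opt <- tryCatch(
      optim(start, nll, method = "Nelder-Mead",
            control = list(maxit = 1000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("maximum-likelihood estimation failed from all starting points ",
         "(unit ", series$unit_id, ", order ", order, ")", call. = FALSE)
  v <- pmax(exp(best$par), 1e-12)
  spec <- if (order == 0L) {
    dlm_spec(0L, var_obs = v[1L], var_level = v[2L], init_var = init_var)
  } else {
    dlm_spec(1L, var_obs = v[1L], var_level = v[2L], var_slope = v[3L],
             init_var = init_var)
  }
  sm <- kalman_smoother(series, spec)
  structure(
    list(model = if (order == 0L) "DLM0" else "DLMs",
         order = order, spec = spec, smoother = sm,
         loglik = -best$value, converged = TRUE,
         optim_convergence = best$convergence,
         unit_id = series$unit_id),
    class = "dlm_fit")
}

#' @export
print.dlm_fit <- function(x, ...) {
  cat(sprintf("<dlm_fit> %s for %s: logLik %.3f\n", x$model, x$unit_id, x$loglik))
  print(x$spec)
  invisible(x)
}

#' k-step-ahead forecast from the end of a filtered series
#'
#' The local linear trend model extrapolates `level + k * slope`; the
#' local level model forecasts its current level for every horizon. The
#' forecast variance propagates the state covariance through `k` system
#' steps and adds the observation noise.
#'
#' @param filter A [kalman_filter()] result (or the `filter` component of
#'   a smoother / `dlm_fit`).
#' @param k Forecast horizon in years, >= 1 (vectorised).
#' @return A data frame with columns `k`, `mean`, `var`.
#' @export
dlm_forecast <- function(filter, k) {
  if (inherits(filter, "dlm_fit")) filter <- filter$smoother$filter
  if (inherits(filter, "smoother_output")) filter <- filter$filter
  stopifnot(inherits(filter, "kalman_filter"))
  k <- as.integer(k)
  if (any(k < 1L)) stop("forecast horizon k must be >= 1", call. = FALSE)
  spec <- filter$spec
  M <- length(filter$years)
  ml <- filter$filt_mean[M, 1L]
  mb <- filter$filt_mean[M, 2L]
  c11 <- filter$filt_cov[M, 1L]
  c12 <- filter$filt_cov[M, 2L]
  c22 <- filter$filt_cov[M, 3L]
  kmax <- max(k)
  vars <- numeric(kmax)
  for (j in seq_len(kmax)) {
    if (spec$order == 1L) {
      n11 <- c11 + 2 * c12 + c22 + spec$var_level
      n12 <- c12 + c22
      n22 <- c22 + spec$var_slope
      c11 <- n11; c12 <- n12; c22 <- n22
    } else {
      c11 <- c11 + spec$var_level
    }
    vars[j] <- c11 + spec$var_obs
  }
  mean <- if (spec$order == 1L) ml + k * mb else rep(ml, length(k))
  data.frame(k = k, mean = mean, var = vars[k])
}

#' Smoothed yearly yield-increase-rate trajectory
#'
#' Fits the local linear trend model by maximum likelihood and returns the
#' smoothed slope path (the yearly yield-increase rate, t/ha per year)
#' with quartiles and 95% bands, plus the coefficient of variation of the
#' final-year rate: `CV = 100 * sd / |estimate|`, reported as `NA` when
#' the estimate is exactly zero. The CV is categorised as `"high"`
#' (|CV| > 100%), `"low"` (< 25%) or `"intermediate"`.
#'
#' @param series A [yield_series()].
#' @return A `rate_trajectory`: data frame with columns `unit_id`, `year`,
#'   `slope`, `sd`, `q1`, `q3`, `lo95`, `hi95`, with attributes
#'   `cv_final` and `cv_category`, and the `dlm_fit` in attribute `fit`.
#' @export
increase_rate_trajectory <- function(series) {
  fit <- fit_dlm(series, order = 1L)
  sm <- fit$smoother
  out <- data.frame(unit_id = sm$unit_id, year = sm$years,
                    slope = sm$slope, sd = sqrt(sm$slope_var),
                    q1 = sm$slope_q1, q3 = sm$slope_q3,
                    lo95 = sm$slope_lo95, hi95 = sm$slope_hi95,
                    stringsAsFactors = FALSE)
  n <- nrow(out)
  cv <- if (out$slope[n] == 0) NA_real_ else 100 * out$sd[n] / abs(out$slope[n])
  attr(out, "cv_final") <- cv
  attr(out, "cv_category") <-
    if (is.na(cv)) NA_character_
    else if (abs(cv) > 100) "high"
    else if (abs(cv) < 25) "low"
    else "intermediate"
  attr(out, "fit") <- fit
  class(out) <- c("rate_trajectory", "data.frame")
  out
}

#' Steady-state smoothing constant equivalent to the local level model
#'
#' For fixed variances, the local level filter's gain converges to a
#' constant; one-step forecasts then coincide with simple exponential
#' smoothing whose constant solves `alpha^2 = q (1 - alpha)` with
#' signal-to-noise ratio `q = var_level / var_obs`. This is why the
#' random-walk model and simple exponential smoothing give nearly
#' identical rolling forecasts on long series.
#'
#' @param var_level Level disturbance variance.
#' @param var_obs Observation-noise variance.
#' @return The steady-state smoothing constant in (0, 1).
#' @export
steady_state_alpha <- function(var_level, var_obs) {
  stopifnot(var_level >= 0, var_obs > 0)
  q <- var_level / var_obs
  (sqrt(q^2 + 4 * q) - q) / 2
}
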