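#' Initialise a non-seasonal Holt-Winters state
#'
#' The trend variant ("HWs") keeps a recursively updated level and slope;
#' the no-trend variant ("HW0", simple exponential smoothing) keeps only
#' the level. Initialisation follows the textbook convention: the level
#' starts at the first observation and, for the trend variant, the slope
#' at the difference between the second and first observations.
#'
#' @param y1 First observed yield.
#' @param y2 Second observed yield (trend variant only).
#' @param alpha Level smoothing constant in \[0, 1\].
#' @param beta Slope smoothing constant in \[0, 1\] (trend variant only).
#' @param trend `TRUE` for the trend variant (HWs), `FALSE` for simple
#'   exponential smoothing (HW0).
#' @return An `hw_state` with fields `alpha`, `beta`, `trend`, `level`,
#'   `slope`, `n_seen` and a `history` of per-update (level, slope).
#' @export
hw_init <- function(y1, y2 = NULL, alpha, beta = 0, trend = TRUE) {
  stopifnot(is.finite(y1), alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  slope <- 0
  if (trend) {
    if (is.null(y2) || !is.finite(y2))
      stop("the trend variant needs the first two observations to initialise",
           call. = FALSE)
    slope <- y2 - y1
  }
  structure(
    list(alpha = alpha, beta = if (trend) beta else NULL, trend = trend,
         level = y1, slope = slope, n_seen = 1L,
         history = list(c(level = y1, slope = slope))),
    class = "hw_state")
}

#' Advance a Holt-Winters state by one observation
#'
#' Trend variant: `level <- alpha y + (1 - alpha)(level + slope)`, then
#' `slope <- beta (level - level_old) + (1 - beta) slope`. No-trend
#' variant: `level <- alpha y + (1 - alpha) level`, slope stays 0. A
#' missing observation (`NA`) carries the state forward along its trend
#' with no update.
#'
#' @param state An [hw_init()] state.
#' @param y New yield observation (may be `NA`).
#' @return The updated `hw_state`.
#' @export
hw_update <- function(state, y) {
  stopifnot(inherits(state, "hw_state"))
  if (!is.na(y) && !is.finite(y))
    stop("non-finite yield observation", call. = FALSE)
  if (is.na(y)) {
    state$level <- state$level + state$slope
  } else {
    old_level <- state$level
    new_level <- state$alpha * y + (1 - state$alpha) * (state$level + state$slope)
    new_slope <- if (state$trend)
      state$beta * (new_level - old_level) + (1 - state$beta) * state$slope
    else 0
    state$level <- new_level
    state$slope <- new_slope
    state$n_seen <- state$n_seen + 1L
  }
  state$history[[length(state$history) + 1L]] <-
    c(level = state$level, slope = state$slope)
  state
}

#' k-step-ahead Holt-Winters forecast
#'
#' Trend variant: `level + k * slope`. No-trend variant: `level`,
#' independent of the horizon.
#'
#' @param state An `hw_state` that has processed at least two observations
#'   (one for the no-trend variant).
#' @param k Horizon in years, >= 1 (vectorised).
#' @return Numeric vector of forecast yields (t/ha).
#' @export
hw_forecast <- function(state, k) {
  stopifnot(inherits(state, "hw_state"))
  k <- as.numeric(k)
  if (any(k < 1)) stop("forecast horizon k must be >= 1", call. = FALSE)
  need <- if (state$trend) 2L else 1L
  if (state$n_seen < need)
    stop("state has processed too few observations to forecast", call. = FALSE)
  if (state$trend) state$level + k * state$slope else rep(state$level, length(k))
}

# One-step-ahead SSE for a series (leading NAs stripped); shared by the
# optimizer and by tests that cross-check the R-level recursion.
hw_objective <- function(y, alpha, beta, trend) {
  .hw_sse_cpp(y, alpha, beta, trend)$sse
}

#' Fit a Holt-Winters model by one-step prediction-error minimisation
#'
#' The smoothing constants minimise the in-sample sum of squared one-step
#' forecast errors, accumulated from the third observation onward (the
#' first two are consumed by initialisation). Optimisation is bounded on
#' \[0, 1\] (or \[0, 1\]^2), with a 9-point multi-start to escape the flat
#' region near `alpha -> 0`.
#'
#' @param series A [yield_series()] with at least 4 observed yields.
#' @param variant `"HW0"` (simple exponential smoothing) or `"HWs"`
#'   (level + trend).
#' @return An `hw_fit` with fields `alpha`, `beta`, `sse`, and `state`
#'   (the `hw_state` after processing the full series, ready for
#'   forecasting).
#' @export
fit_holt_winters <- function(series, variant = c("HWs", "HW0")) {
  stopifnot(inherits(series, "yield_series"))
  variant <- match.arg(variant)
  trend <- variant == "HWs"
  y <- series$yields
  first_obs <- which(!is.na(y))[1L]
  y <- y[first_obs:length(y)]  # leading gaps carry no information
  if (sum(!is.na(y)) < 4L)
    stop("need at least 4 observed yields to fit ", variant,
         " (unit ", series$unit_id, ")", call. = FALSE)
  if (trend) {
    grid <- seq(0.1, 0.9, by = 0.4)
    starts <- expand.grid(alpha = grid, beta = grid)
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      opt <- optim(c(starts$alpha[i], starts$beta[i]),
                   function(p) hw_objective(y, p[1L], p[2L], TRUE),
                   method = "L-BFGS-B", lower = 0, upper = 1)
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    alpha <- best$par[1L]; beta <- best$par[2L]; sse <- best$value
  } else {
    # 1-D problem: golden-section from several brackets, then take the best
    # of the bracket optima and the endpoints.
    cands <- lapply(list(c(0, 0.5), c(0.25, 0.75), c(0.5, 1)), function(b)
      optimise(function(a) hw_objective(y, a, 0, FALSE),
               interval = b, tol = 1e-9))
    vals <- vapply(cands, `[[`, numeric(1L), "objective")
    ends <- c(hw_objective(y, 0, 0, FALSE), hw_objective(y, 1, 0, FALSE))
    if (min(ends) < min(vals)) {
      alpha <- c(0, 1)[which.min(ends)]; sse <- min(ends)
    } else {
      alpha <- cands[[which.min(vals)]]$minimum; sse <- min(vals)
    }
    beta <- NULL
  }
  # Replay the recursion at the optimum to expose the final state.
  obs_idx <- which(!is.na(y))
  state <- hw_init(y[obs_idx[1L]],
                   if (trend) y[obs_idx[2L]] else NULL,
                   alpha = alpha, beta = if (trend) beta else 0,
                   trend = trend)
  if (trend && obs_idx[2L] > obs_idx[1L] + 1L)
    state$slope <- state$slope / (obs_idx[2L] - obs_idx[1L])
  for (t in seq.int(2L, length(y))) state <- hw_update(state, y[t])
  structure(
    list(model = variant, alpha = alpha, beta = beta, sse = sse,
         state = state, unit_id = series$unit_id, converged = TRUE),
    class = "hw_fit")
}

#' @export
print.hw_fit <- function(x, ...) {
  cat(sprintf("<hw_fit> %s for %s: alpha=%.4f%s, one-step SSE=%.4f\n",
              x$model, x$unit_id, x$alpha,
              if (!is.null(x$beta)) sprintf(" beta=%.4f", x$beta) else "",
              x$sse))
  invisible(x)
}
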