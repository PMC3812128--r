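#' Fit a polynomial trend (linear, quadratic or cubic) to a yield series
#'
#' Ordinary least squares on the internal time index `T` (1 at the first
#' year of the series). Degree 1 is the constant-rate linear trend
#' `Y_t = a + b T`, degree 2 adds curvature, degree 3 is the cubic. Missing
#' years are dropped from the fit; fitted values and residuals are reported
#' for every observed year.
#'
#' @param series A [yield_series()].
#' @param degree Polynomial degree: 1, 2 or 3.
#' @return A `polynomial_fit` with fields `degree`, `coefficients`
#'   (intercept first), `fitted`, `residuals`, `sigma` (residual sd),
#'   `years`, `t_index` and `converged` (always `TRUE` for OLS).
#' @export
#' @examples
#' s <- yield_series("X", 1961:1970, 2 + 0.1 * (1:10))
#' fit_polynomial(s, 1)$coefficients
fit_polynomial <- function(series, degree) {
  stopifnot(inherits(series, "yield_series"))
  degree <- as.integer(degree)
  if (!degree %in% 1:3) stop("degree must be 1, 2 or 3", call. = FALSE)
  obs <- !is.na(series$yields)
  if (sum(obs) < degree + 2L)
    stop("need at least ", degree + 2L, " observations for degree ", degree,
         " (unit ", series$unit_id, " has ", sum(obs), ")", call. = FALSE)
  tt <- series$t_index[obs]
  y <- series$yields[obs]
  X <- outer(tt, 0:degree, `^`)
  fit <- lm.fit(X, y)
  beta <- unname(fit$coefficients)
  if (anyNA(beta))
    stop("singular design for unit ", series$unit_id, call. = FALSE)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  structure(
    list(model = c("L", "Q", "C")[degree],
         degree = degree,
         coefficients = beta,
         fitted = fitted,
         residuals = res,
         sigma = sqrt(sum(res^2) / max(1L, length(y) - degree - 1L)),
         years = series$years[obs],
         t_index = tt,
         unit_id = series$unit_id,
         converged = TRUE),
    class = c("polynomial_fit", "trend_fit"))
}

#' Fit the linear-plus-plateau (segmented) trend
#'
#' The trend rises at constant rate `R` until the break date `T*` and is
#' flat at `Ymax = a + R T*` thereafter; continuity at the break is built
#' into the parameterisation. The break date is profiled over a grid of
#' candidate integer dates (every observed index from the 3rd to the
#' (M-2)th point, so the break always has support on both sides), the
#' conditionally linear parameters are solved exactly at each candidate,
#' and the break date is then refined continuously around the best
#' candidate by one-dimensional profile-RSS optimisation.
#'
#' Non-convergence is a reported status, not an error: the fit is flagged
#' `converged = FALSE` when the refined break date (or its 95% confidence
#' interval) leaves the identifiable window spanned by the grid, or when
#' the Jacobian at the optimum is numerically rank-deficient -- the
#' classic symptoms of a series with no plateau, where the break date is
#' unidentifiable. Numeric fields are `NA` in that case.
#'
#' @param series A [yield_series()].
#' @param init_grid Optional integer vector of candidate break indexes
#'   (values of `T`). Defaults to the observed indexes from the 3rd to the
#'   (M-2)th point.
#' @return A `plateau_fit` with fields `Ymax`, `T_break`, `R`, `converged`,
#'   `fitted`, `residuals`, `sigma`.
#' @export
fit_linear_plateau <- function(series, init_grid = NULL) {
  stopifnot(inherits(series, "yield_series"))
  obs <- !is.na(series$yields)
  if (sum(obs) < 6L)
    stop("need at least 6 observations for the linear-plus-plateau model",
         call. = FALSE)
  tt <- series$t_index[obs]
  y <- series$yields[obs]
  m <- length(tt)
  if (is.null(init_grid)) init_grid <- tt[3:(m - 2L)]
  t_lo <- min(init_grid)
  t_hi <- max(init_grid)

  unconverged <- function(reason) {
    structure(
      list(model = "LP", Ymax = NA_real_, T_break = NA_real_, R = NA_real_,
           intercept = NA_real_, fitted = NULL, residuals = NULL,
           sigma = NA_real_, years = series$years[obs], t_index = tt,
           unit_id = series$unit_id, converged = FALSE, reason = reason),
      class = c("plateau_fit", "trend_fit"))
  }

  # Profile RSS over integer candidate breaks: conditional on T*, the model
  # is linear in (a, R) with regressor pmin(T, T*).
  profile_rss <- vapply(init_grid, function(tb) {
    X <- cbind(1, pmin(tt, tb))
    f <- lm.fit(X, y)
    sum(f$residuals^2)
  }, numeric(1L))
  tb0 <- init_grid[which.min(profile_rss)]
  cf0 <- lm.fit(cbind(1, pmin(tt, tb0)), y)$coefficients
  start <- list(a = unname(cf0[1L]), R = unname(cf0[2L]), tb = as.numeric(tb0))

  if (min(profile_rss) <= 1e-12 * sum(y^2)) {
    # the grid candidate already fits perfectly; nothing to refine
    a <- start$a; R <- start$R; tb <- start$tb
  } else {
    # Continuous refinement of the break date around the best candidate,
    # still profiling the conditionally linear parameters exactly. The
    # search interval extends one step past the candidate window so a
    # break being pushed out of the data is observable rather than
    # masked by a boundary.
    prof <- function(tb) {
      f <- lm.fit(cbind(1, pmin(tt, tb)), y)
      sum(f$residuals^2)
    }
    opt <- optimise(prof, interval = c(max(tb0 - 2, t_lo - 1),
                                       min(tb0 + 2, t_hi + 1)), tol = 1e-7)
    tb <- opt$minimum
    cf <- lm.fit(cbind(1, pmin(tt, tb)), y)$coefficients
    a <- unname(cf[1L]); R <- unname(cf[2L])
  }
  if (!all(is.finite(c(a, R, tb)))) return(unconverged("non-finite estimates"))
  if (tb < t_lo || tb > t_hi)
    return(unconverged("break date outside identifiable window"))
  # Identifiability checks: a plateau-free series leaves the break-date
  # column of the Jacobian numerically null, or its standard error so
  # large that the 95% interval for the break escapes the data window --
  # the break date is then not identified.
  J <- cbind(1, pmin(tt, tb), R * (tt < tb))
  sv <- svd(J, nu = 0, nv = 0)$d
  if (sv[1L] <= 0 || sv[length(sv)] / sv[1L] < 1e-8)
    return(unconverged("degenerate Jacobian at optimum"))
  fitted <- a + R * pmin(tt, tb)
  res <- y - fitted
  sigma_hat <- sqrt(sum(res^2) / max(1L, m - 3L))
  se_tb <- sqrt(chol2inv(chol(crossprod(J)))[3L, 3L]) * sigma_hat
  if (tb - 1.96 * se_tb < t_lo || tb + 1.96 * se_tb > t_hi)
    return(unconverged("break date not identified within the data window"))
  structure(
    list(model = "LP",
         Ymax = a + R * tb,
         T_break = tb,
         R = R,
         intercept = a,
         fitted = fitted,
         residuals = res,
         sigma = sigma_hat,
         years = series$years[obs],
         t_index = tt,
         unit_id = series$unit_id,
         converged = TRUE,
         reason = "ok"),
    class = c("plateau_fit", "trend_fit"))
}

#' Evaluate a fitted regression trend at arbitrary time indexes
#'
#' Extrapolation is allowed; the plateau model returns `Ymax` for all
#' `T >= T*`.
#'
#' @param object A `polynomial_fit` or `plateau_fit`.
#' @param t_index Numeric vector of time indexes `T` at which to evaluate.
#' @param ... Unused.
#' @return Numeric vector of trend yields (t/ha).
#' @export
predict.polynomial_fit <- function(object, t_index, ...) {
  drop(outer(as.numeric(t_index), 0:object$degree, `^`) %*% object$coefficients)
}

#' @rdname predict.polynomial_fit
#' @export
predict.plateau_fit <- function(object, t_index, ...) {
  if (!isTRUE(object$converged))
    stop("cannot predict from an unconverged linear-plus-plateau fit",
         call. = FALSE)
  object$intercept + object$R * pmin(as.numeric(t_index), object$T_break)
}

#' In-sample RMSE of a trend fit
#'
#' @param fit Any fit with `residuals`.
#' @return Root mean square residual (t/ha).
#' @export
fit_rmse <- function(fit) {
  if (is.null(fit$residuals)) return(NA_real_)
  sqrt(mean(fit$residuals^2))
}

#' Residual autocorrelation with white-noise bounds
#'
#' Sample autocorrelations of a fit's residual sequence at lags
#' `1..max_lag`, together with the +/- 1.96/sqrt(M) band under the
#' white-noise null, used to check the independence assumption of the
#' regression error term.
#'
#' @param fit A fit with a `residuals` field, or a plain numeric vector.
#' @param max_lag Largest lag to report.
#' @return A data frame with columns `lag`, `acf`, `lower`, `upper`.
#' @export
residual_autocorrelation <- function(fit, max_lag = 10) {
  res <- if (is.numeric(fit)) fit else fit$residuals
  if (is.null(res)) stop("fit has no residuals", call. = FALSE)
  res <- res[!is.na(res)]
  m <- length(res)
  if (m < max_lag + 5L)
    stop("need at least max_lag + 5 residuals (have ", m, ")", call. = FALSE)
  if (sd(res) == 0)
    stop("residuals have zero variance; autocorrelation undefined",
         call. = FALSE)
  r <- drop(acf(res, lag.max = max_lag, plot = FALSE)$acf)[-1L]
  band <- 1.96 / sqrt(m)
  data.frame(lag = seq_len(max_lag), acf = r, lower = -band, upper = band)
}
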