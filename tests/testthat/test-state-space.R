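random_spec <- function(order) {
  if (order == 0L) {
    dlm_spec(0L, var_obs = runif(1, 0.02, 0.5),
             var_level = runif(1, 0.001, 0.3),
             init_mean = rnorm(1, 3, 1), init_var = runif(1, 0.5, 50))
  } else {
    dlm_spec(1L, var_obs = runif(1, 0.02, 0.5),
             var_level = runif(1, 0.001, 0.3),
             var_slope = runif(1, 1e-5, 0.02),
             init_mean = c(rnorm(1, 3, 1), rnorm(1, 0.1, 0.05)),
             init_var = runif(1, 0.5, 50))
  }
}

random_series <- function(m, with_gap = FALSE) {
  y <- pmax(2.5 + 0.1 * (1:m) + rnorm(m, 0, 0.4), 0.05)
  if (with_gap) y[sample(2:(m - 1L), 1L)] <- NA
  yield_series("r", 1960L + (1:m), y)
}

test_that("a single observation under a diffuse prior is reproduced exactly", {
  s <- yield_series("one", c(2000L, 2001L), c(6.2, 6.3))
  kf <- kalman_filter(s, dlm_spec(0L, var_obs = 0.1, var_level = 0.05,
                                  init_var = 1e7))
  expect_equal(kf$filt_mean[1L, 1L], 6.2, tolerance = 1e-5)
})

test_that("zero level disturbance reduces to the precision-weighted running mean", {
  y <- c(5.1, 5.4, 4.9, 5.2, 5.0)
  s <- yield_series("cm", 2000L + seq_along(y), y)
  kf <- kalman_filter(s, dlm_spec(0L, var_obs = 0.2, var_level = 0,
                                  init_var = 1e9))
  running <- cumsum(y) / seq_along(y)
  expect_equal(kf$filt_mean[, 1L], running, tolerance = 1e-6)
})

test_that("filter and smoother match the joint-Gaussian conditioning oracle", {
  set.seed(301)
  for (i in 1:12) {
    order <- i %% 2L
    m <- sample(4:8, 1L)
    s <- random_series(m, with_gap = i > 9)
    spec <- random_spec(order)
    wl <- spec$var_level
    wb <- if (order == 1L) spec$var_slope else 0
    sm <- kalman_smoother(s, spec)
    orc <- oracle_condition(s$yields, order, spec$var_obs, wl, wb,
                            m0 = spec$init_mean, c0 = spec$init_var)
    expect_lt(max(abs(sm$level - orc$level)), 1e-8)
    expect_lt(max(abs(sm$level_var - orc$level_var)), 1e-8)
    if (order == 1L) {
      expect_lt(max(abs(sm$slope - orc$slope)), 1e-8)
      expect_lt(max(abs(sm$slope_var - orc$slope_var)), 1e-8)
    }
    # filtered quantities: condition only on y_1..t
    kf <- sm$filter
    for (t in c(1L, m)) {
      orct <- oracle_condition(s$yields, order, spec$var_obs, wl, wb,
                               m0 = spec$init_mean, c0 = spec$init_var,
                               upto = t)
      expect_lt(abs(kf$filt_mean[t, 1L] - orct$level[t]), 1e-8)
      expect_lt(abs(kf$filt_cov[t, 1L] - orct$level_var[t]), 1e-8)
    }
  }
})

test_that("the smoother equals the filter at the final time point", {
  set.seed(17)
  s <- random_series(12)
  for (order in 0:1) {
    spec <- random_spec(order)
    sm <- kalman_smoother(s, spec)
    m <- length(s$years)
    expect_identical(sm$level[m], sm$filter$filt_mean[m, 1L])
    expect_identical(sm$level_var[m], sm$filter$filt_cov[m, 1L])
  }
})

test_that("smoothing never inflates the filtered variance", {
  set.seed(23)
  for (i in 1:10) {
    s <- random_series(sample(10:40, 1L))
    spec <- random_spec(i %% 2L)
    sm <- kalman_smoother(s, spec)
    expect_true(all(sm$level_var <= sm$filter$filt_cov[, 1L] + 1e-9))
    if (spec$order == 1L)
      expect_true(all(sm$slope_var <= sm$filter$filt_cov[, 3L] + 1e-9))
  }
})

test_that("posterior slope bands collapse in the noiseless linear limit", {
  s <- line_series(a = 2, b = 0.13, m = 25)
  spec <- dlm_spec(1L, var_obs = 1e-10, var_level = 0, var_slope = 0,
                   init_var = 1e7)
  sm <- kalman_smoother(s, spec)
  expect_equal(sm$slope, rep(0.13, 25), tolerance = 1e-4)
  expect_lt(max(sm$slope_q3 - sm$slope_q1), 1e-4)
  expect_lt(max(sm$slope_hi95 - sm$slope_lo95), 1e-4)
  # quartiles bracket the mean symmetrically and sit inside the 95% band
  expect_equal(sm$slope_q3 - sm$slope, sm$slope - sm$slope_q1,
               tolerance = 1e-12)
  expect_true(all(sm$slope_lo95 <= sm$slope_q1 & sm$slope_q3 <= sm$slope_hi95))
})

test_that("maximum likelihood dominates random variance candidates", {
  set.seed(77)
  sim <- simulate_dlm_series(simulation_config("dlm_draw", seed = 99))
  s <- sim$series
  fit <- fit_dlm(s, order = 1L)
  for (i in 1:50) {
    v <- exp(runif(3, log(1e-6), log(1)))
    ll <- kalman_smoother(s, dlm_spec(1L, v[1], v[2], v[3]))$log_likelihood
    expect_lte(ll, fit$loglik + 1e-6)
  }
  fit0 <- fit_dlm(s, order = 0L)
  for (i in 1:20) {
    v <- exp(runif(2, log(1e-6), log(1)))
    ll <- kalman_smoother(s, dlm_spec(0L, v[1], v[2]))$log_likelihood
    expect_lte(ll, fit0$loglik + 1e-6)
  }
})

test_that("an exact linear series drives the disturbance variances to the floor", {
  s <- line_series(a = 2.5, b = 0.13, m = 40)
  fit <- fit_dlm(s, order = 1L)
  expect_lt(fit$spec$var_level, 1e-4)
  expect_lt(fit$spec$var_slope, 1e-4)
  expect_equal(fit$smoother$slope, rep(0.13, 40), tolerance = 1e-3)
})

test_that("forecasts are flat for the local level and affine for the trend model", {
  set.seed(31)
  s <- random_series(30)
  kf0 <- kalman_filter(s, random_spec(0L))
  f0 <- dlm_forecast(kf0, 1:10)
  expect_equal(f0$mean, rep(f0$mean[1L], 10))
  kf1 <- kalman_filter(s, random_spec(1L))
  f1 <- dlm_forecast(kf1, 1:10)
  expect_equal(diff(f1$mean), rep(kf1$filt_mean[30, 2L], 9), tolerance = 1e-12)
  expect_error(dlm_forecast(kf1, 0), "k must be")
})

test_that("forecast variance grows with the horizon and matches simulation", {
  set.seed(57)
  s <- random_series(25)
  spec <- dlm_spec(1L, var_obs = 0.09, var_level = 0.01, var_slope = 1e-4)
  kf <- kalman_filter(s, spec)
  fc <- dlm_forecast(kf, 1:10)
  expect_true(all(diff(fc$var) > 0))
  # Monte-Carlo check of the k-step predictive variance from the filtered state
  m <- length(s$years)
  ml <- kf$filt_mean[m, 1L]; mb <- kf$filt_mean[m, 2L]
  C <- matrix(c(kf$filt_cov[m, 1L], kf$filt_cov[m, 2L],
                kf$filt_cov[m, 2L], kf$filt_cov[m, 3L]), 2, 2)
  n_mc <- 1e5
  ev <- eigen(C, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  x <- cbind(ml, mb) [rep(1, n_mc), ] + matrix(rnorm(2 * n_mc), n_mc) %*% rt
  k <- 5L
  lvl <- x[, 1L]; slp <- x[, 2L]
  for (j in 1:k) {
    lvl <- lvl + slp + rnorm(n_mc, 0, sqrt(spec$var_level))
    slp <- slp + rnorm(n_mc, 0, sqrt(spec$var_slope))
  }
  ysim <- lvl + rnorm(n_mc, 0, sqrt(spec$var_obs))
  expect_equal(var(ysim), fc$var[k], tolerance = 0.05)
  expect_equal(mean(ysim), fc$mean[k], tolerance = 0.05)
})

test_that("the likelihood is location-invariant under a diffuse prior", {
  set.seed(71)
  s <- random_series(30)
  for (order in 0:1) {
    spec <- if (order == 0L) dlm_spec(0L, 0.1, 0.02)
            else dlm_spec(1L, 0.1, 0.02, 1e-4)
    ll1 <- kalman_filter(s, spec)$loglik
    s2 <- yield_series(s$unit_id, s$years, s$yields + 50)
    ll2 <- kalman_filter(s2, spec)$loglik
    expect_equal(ll1, ll2, tolerance = 1e-3)
  }
})

test_that("local level one-step forecasts converge to exponential smoothing", {
  # With fixed variances the filter gain tends to a constant; one-step
  # forecasts then match simple exponential smoothing with the
  # steady-state constant. This is why the random-walk state-space model
  # and simple exponential smoothing produce near-identical RMSEPs.
  set.seed(83)
  m <- 500L
  lvl <- cumsum(c(5, rnorm(m - 1L, 0, sqrt(0.01))))
  y <- pmax(lvl + rnorm(m, 0, sqrt(0.09)), 0.05)
  s <- yield_series("long", 1500L + (1:m), y)
  spec <- dlm_spec(0L, var_obs = 0.09, var_level = 0.01)
  kf <- kalman_filter(s, spec)
  alpha <- steady_state_alpha(0.01, 0.09)
  expect_gt(alpha, 0); expect_lt(alpha, 1)
  expect_equal(alpha^2, (0.01 / 0.09) * (1 - alpha), tolerance = 1e-12)
  st <- hw_init(y[1], alpha = alpha, trend = FALSE)
  ses_forecast <- numeric(m)
  for (t in 2:m) {
    ses_forecast[t] <- hw_forecast(st, 1)
    st <- hw_update(st, y[t])
  }
  burn <- 101:m
  expect_lt(max(abs(kf$forecast[burn] - ses_forecast[burn])), 1e-3)
})

test_that("rate trajectories summarise the smoothed slope with uncertainty", {
  s <- line_series(a = 2.5, b = 0.13, m = 40)
  tr <- increase_rate_trajectory(s)
  expect_equal(tr$slope, rep(0.13, 40), tolerance = 1e-3)
  expect_lt(attr(tr, "cv_final"), 1)
  expect_identical(attr(tr, "cv_category"), "low")
  sim <- simulate_scenario_panel(
    simulation_config("plateau", n_units = 1, noise_sd = 0.2, seed = 13,
                      jitter = 0))
  tr2 <- increase_rate_trajectory(sim$panel$series[[1L]])
  n <- nrow(tr2)
  expect_lt(tr2$slope[n], tr2$slope[n - 20L])  # plateauing: rate declines
  expect_true(all(tr2$q1 <= tr2$slope & tr2$slope <= tr2$q3))
})

test_that("spec validation catches impossible configurations", {
  expect_error(dlm_spec(2L, 0.1, 0.1), "order")
  expect_error(dlm_spec(0L, 0, 0.1), "var_obs")
  expect_error(dlm_spec(0L, 0.1, 0.1, var_slope = 0.1), "no meaning")
  expect_error(dlm_spec(1L, 0.1, -0.1, 1e-4))
  s <- yield_series("gap", 2000:2003, c(NA, NA, NA, 2))
  expect_error(kalman_filter(s, dlm_spec(0L, 0.1, 0.1)), "at least 2")
})
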