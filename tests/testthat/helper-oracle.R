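# Independent oracles used to validate the package's recursions.
# These deliberately take brute-force routes (joint multivariate-Gaussian
# conditioning, explicit normal equations, profiled grid search) that share
# no code with the implementations they check.

# Joint-Gaussian conditioning oracle for the structural state-space models.
# Writes down the joint Gaussian of the stacked states x_1..x_M implied by
#   x_t = G x_{t-1} + w_t,  x_0 ~ N(m0, c0 I),
# in information (precision) form -- the precision matrix of a Markov chain
# is block tridiagonal -- adds the observations as rank-one information
# updates, and solves once for the conditional mean and covariance of
# every state. `upto = t` conditions only on y_1..y_t (the filtered
# distribution); the default conditions on everything (the smoothed
# distribution). Requires all disturbance variances > 0.
oracle_condition <- function(y, order, v, wl, wb = 0,
                             m0 = NULL, c0 = 1, upto = NULL) {
  M <- length(y)
  d <- order + 1L
  if (is.null(m0)) m0 <- rep(0, d)
  G <- if (order == 1L) matrix(c(1, 0, 1, 1), 2, 2) else matrix(1, 1, 1)
  W <- diag(c(wl, wb)[seq_len(d)], d)
  Q1 <- G %*% (c0 * diag(d)) %*% t(G) + W  # marginal covariance of x_1
  P <- matrix(0, M * d, M * d)
  eta <- numeric(M * d)
  blk <- function(t) ((t - 1L) * d + 1L):(t * d)
  Q1i <- solve(Q1)
  Wi <- solve(W)
  mu1 <- drop(G %*% m0)
  P[blk(1L), blk(1L)] <- Q1i
  eta[blk(1L)] <- Q1i %*% mu1
  if (M > 1L) {
    GtWiG <- t(G) %*% Wi %*% G
    WiG <- Wi %*% G
    for (t in 2:M) {
      P[blk(t), blk(t)] <- P[blk(t), blk(t)] + Wi
      P[blk(t - 1L), blk(t - 1L)] <- P[blk(t - 1L), blk(t - 1L)] + GtWiG
      P[blk(t), blk(t - 1L)] <- P[blk(t), blk(t - 1L)] - WiG
      P[blk(t - 1L), blk(t)] <- P[blk(t - 1L), blk(t)] - t(WiG)
    }
  }
  obs <- which(!is.na(y))
  if (!is.null(upto)) obs <- obs[obs <= upto]
  lvl_idx <- (seq_len(M) - 1L) * d + 1L
  for (t in obs) {
    i <- lvl_idx[t]
    P[i, i] <- P[i, i] + 1 / v
    eta[i] <- eta[i] + y[t] / v
  }
  cS <- chol2inv(chol(P))
  cm <- drop(cS %*% eta)
  list(
    level = cm[lvl_idx],
    level_var = diag(cS)[lvl_idx],
    slope = if (d == 2L) cm[lvl_idx + 1L] else rep(0, M),
    slope_var = if (d == 2L) diag(cS)[lvl_idx + 1L] else rep(0, M))
}

# Explicit normal-equations solve for polynomial least squares.
poly_oracle <- function(t_index, y, degree) {
  X <- outer(t_index, 0:degree, `^`)
  solve(crossprod(X), crossprod(X, y))[, 1L]
}

# Profile RSS of the broken-line model over a fine grid of break dates:
# conditional on the break, the model is linear and solved exactly.
lp_profile_grid <- function(t_index, y, grid) {
  rss <- vapply(grid, function(tb) {
    X <- cbind(1, pmin(t_index, tb))
    b <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% b)^2)
  }, numeric(1L))
  list(grid = grid, rss = rss, best = grid[which.min(rss)],
       min_rss = min(rss))
}

# Reference one-step Holt-Winters SSE built on the exported R-level
# recursion (hw_init / hw_update), used to cross-check the optimizer's
# internal objective.
hw_sse_reference <- function(y, alpha, beta, trend) {
  y <- y[which(!is.na(y))[1L]:length(y)]
  obs <- which(!is.na(y))
  st <- hw_init(y[obs[1L]], if (trend) y[obs[2L]] else NULL,
                alpha = alpha, beta = beta, trend = trend)
  if (trend && obs[2L] > obs[1L] + 1L)
    st$slope <- st$slope / (obs[2L] - obs[1L])
  sse <- 0; seen <- 1L
  for (t in 2:length(y)) {
    f <- st$level + st$slope
    if (!is.na(y[t])) {
      seen <- seen + 1L
      if (seen >= 3L) sse <- sse + (y[t] - f)^2
    }
    st <- hw_update(st, y[t])
  }
  sse
}
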