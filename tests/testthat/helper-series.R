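# Small series constructors shared across test files.

line_series <- function(a = 2, b = 0.1, m = 10, first_year = 1961,
                        unit = "line") {
  yield_series(unit, first_year + seq_len(m) - 1L, a + b * seq_len(m))
}

broken_series <- function(rate = 0.1, t_break = 10, m = 20,
                          first_year = 1961, unit = "broken",
                          noise_sd = 0, seed = NULL, base = 0) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq_len(m)
  y <- base + rate * pmin(tt, t_break)
  if (noise_sd > 0) y <- y + rnorm(m, 0, noise_sd)
  yield_series(unit, first_year + tt - 1L, pmax(y, 0.05))
}

noisy_line_series <- function(a = 2, b = 0.1, m = 30, sd = 0.3, seed = 1,
                              unit = "noisy") {
  set.seed(seed)
  yield_series(unit, 1961L + seq_len(m) - 1L,
               pmax(a + b * seq_len(m) + rnorm(m, 0, sd), 0.05))
}
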