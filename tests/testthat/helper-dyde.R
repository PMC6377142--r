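# shared fixtures and independent oracles for the test suite

# the standard sampling design: 12 points at 4 h (44 h span)
t12 <- seq(0, 44, by = 4)

# fast configuration for tests that loop over many series: coarser period
# grid (0.5 h step still contains every integer/half-integer test period)
fast_cfg <- function(...) dyde_config(grid_step_hours = 0.5, ...)

# independent fixed-step RK4 integrator of dy/dt = a*u(t) - b*y + c with
# linear interpolation of u between samples; oracle for the closed-form
# first-order-hold solver
rk4_first_order <- function(a, b, c_, x0, u, times, h = 0.005) {
  uf <- approxfun(times, u, rule = 2)
  f <- function(t, y) a * uf(t) - b * y + c_
  y <- numeric(length(times))
  y[1] <- x0
  for (k in seq_len(length(times) - 1)) {
    t0 <- times[k]; y0 <- y[k]
    nst <- ceiling((times[k + 1] - t0) / h)
    hh <- (times[k + 1] - t0) / nst
    for (s in seq_len(nst)) {
      k1 <- f(t0, y0)
      k2 <- f(t0 + hh / 2, y0 + hh / 2 * k1)
      k3 <- f(t0 + hh / 2, y0 + hh / 2 * k2)
      k4 <- f(t0 + hh, y0 + hh * k3)
      y0 <- y0 + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t0 <- t0 + hh
    }
    y[k + 1] <- y0
  }
  y
}

# small two-condition dataset fixture built from the synthetic generator
small_sim <- function(seed = 1, noise_sd = 0.05) {
  simulate_pair(synthetic_spec(seed = seed, noise_sd = noise_sd))
}

# write a wide-format expression TSV and return its path
write_tmp_expression <- function(ds) {
  path <- tempfile(fileext = ".tsv")
  write_expression(ds, path)
  path
}
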