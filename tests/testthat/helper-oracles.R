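# Independent oracles used across the suite.

# Classical RK4 integration of the three-element Windkessel ODE
#   dP/dt = ((R1 + R2) Q - P) / (R2 C) + R1 dQ/dt
# written directly from the continuous model, independent of the package's
# backward-Euler stepper.
rk4_windkessel <- function(params, Qfun, dQfun, P0, t_end, dt) {
  R1 <- params$R1; R2 <- params$R2; C <- params$C
  f <- function(t, P) ((R1 + R2) * Qfun(t) - P) / (R2 * C) + R1 * dQfun(t)
  n <- ceiling(t_end / dt)
  tt <- seq(0, by = dt, length.out = n + 1)
  P <- numeric(n + 1); P[1] <- P0
  for (i in seq_len(n)) {
    t <- tt[i]; p <- P[i]
    k1 <- f(t, p)
    k2 <- f(t + dt / 2, p + dt / 2 * k1)
    k3 <- f(t + dt / 2, p + dt / 2 * k2)
    k4 <- f(t + dt, p + dt * k3)
    P[i + 1] <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  data.frame(t = tt, P = P)
}

# textbook paired t statistic
t_stat_oracle <- function(x, y) {
  d <- y - x
  mean(d) / (sd(d) / sqrt(length(d)))
}

# Wilcoxon signed-rank V: sum of ranks of |d| over positive d (no ties/zeros)
wilcoxon_V_oracle <- function(x, y) {
  d <- y - x
  d <- d[d != 0]
  sum(rank(abs(d))[d > 0])
}

# Lilliefors/KS statistic against the fitted normal
ks_stat_oracle <- function(d) {
  n <- length(d)
  z <- sort((d - mean(d)) / sd(d))
  Fh <- pnorm(z)
  max(max(seq_len(n) / n - Fh), max(Fh - (seq_len(n) - 1) / n))
}

# standard four-outlet Windkessel set
default_outlets <- function() {
  out <- lapply(c("BA", "LCCA", "LSA", "DAo"), wk_params)
  names(out) <- c("BA", "LCCA", "LSA", "DAo")
  out
}

# small steady-tube simulation reused by solver tests
steady_tube_sim <- function(D = 10, L = 24, h = 1, Q = 0.2, n_cycles = 4,
                            label = "BA") {
  geom <- build_aorta(tube_spec(D, L))
  dom <- suppressWarnings(voxelize(geom, h))
  wf <- flow_waveform(function(t) rep(Q, length(t)), period = 1)
  ctl <- solver_controls(n_cycles = n_cycles, dt_max_frac = 1 / 40,
                         periodicity_tol = 1)
  list(dom = dom,
       sim = simulate_case(dom, wf, list(outlet = wk_params(label)),
                           controls = ctl),
       Q = Q, geom = geom)
}
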