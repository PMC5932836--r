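test_that("reference parameter table is retrievable bit-exactly by label", {
  ba <- wk_params("BA")
  expect_identical(c(ba$R1, ba$R2, ba$C), c(0.100, 2.480, 0.466))
  dao <- wk_params("DAo")
  expect_identical(c(dao$R1, dao$R2, dao$C), c(0.120, 2.118, 0.421))
  lcca <- wk_params("LCCA")
  expect_identical(c(lcca$R1, lcca$R2, lcca$C), c(0.110, 2.510, 0.443))
  lsa <- wk_params("LSA")
  expect_identical(c(lsa$R1, lsa$R2, lsa$C), c(0.150, 2.624, 0.437))
  err <- tryCatch(wk_params("femoral"), error = function(e) conditionMessage(e))
  expect_match(err, "BA")
  expect_match(err, "LCCA")
  expect_match(err, "LSA")
  expect_match(err, "DAo")
  expect_error(wk_params("x", R1 = -1, R2 = 1, C = 1), "positive")
})

test_that("steady pressure is (R1+R2) Q", {
  expect_equal(wk_steady_pressure(wk_params("BA"), 10), 25.8)
  expect_equal(wk_steady_pressure(wk_params("BA"), 0), 0)
  expect_equal(wk_steady_pressure(wk_params("DAo"), 5), 11.19)
})

test_that("backward-Euler step: fixed point and hand-checked value", {
  p <- wk_params("BA")
  # constant flow at the analytic steady state is preserved exactly
  Q <- 7.3
  Pss <- wk_steady_pressure(p, Q)
  st <- wk_step(p, wk_state(Pss, Q, 0), Q, 0.013)
  expect_equal(st$P, Pss, tolerance = 1e-14)
  # hand evaluation: beta = 2.480*0.466/0.01 = 115.568,
  # P1 = (R1+R2+R1*beta)*10 / (1+beta) = 141.368 / 116.568
  st <- wk_step(p, wk_state(0, 0, 0), 10, 0.01)
  expect_equal(st$P, 141.368 / 116.568, tolerance = 1e-12)
  expect_equal(st$P, 1.2127, tolerance = 1e-4)
  expect_error(wk_step(p, wk_state(0, 0, 0), 10, 0), "positive")
  expect_error(wk_step(p, wk_state(0, 0, 0), 10, -0.1), "positive")
})

test_that("zero-flow decay follows exp(-t / (R2 C)) to 0.1% at dt = T/1000", {
  p <- wk_params("BA")
  tau <- p$R2 * p$C
  wf <- flow_waveform(function(t) rep(0, length(t)), period = 2)
  tr <- wk_simulate(p, wf, dt = 2 / 1000, n_cycles = 1, P0 = 100)
  P_at_tau <- approx(tr$t_s, tr$P_mmHg, xout = tau)$y
  expect_equal(P_at_tau, 100 * exp(-1), tolerance = 1e-3)
  # full-trace comparison against the closed form
  expect_lt(max(abs(tr$P_mmHg - 100 * exp(-tr$t_s / tau)) / 100), 1e-3)
})

test_that("stepper converges to the RK4 oracle with order >= 1", {
  p <- wk_params("LCCA")
  T <- 0.8
  Qfun <- function(t) 10 + 5 * sin(2 * pi * t / T)
  dQfun <- function(t) 5 * 2 * pi / T * cos(2 * pi * t / T)
  wf <- flow_waveform(Qfun, period = T)
  P0 <- 20
  errs <- vapply(c(80, 160, 320, 640), function(nsub) {
    dt <- T / nsub
    tr <- wk_simulate(p, wf, dt = dt, n_cycles = 1, P0 = P0)
    ref <- rk4_windkessel(p, Qfun, dQfun, P0, T, dt / 100)
    max(abs(tr$P_mmHg - approx(ref$t, ref$P, xout = tr$t_s)$y))
  }, 0)
  expect_true(all(diff(errs) < 0))
  order <- coef(lm(log(errs) ~ log(T / c(80, 160, 320, 640))))[2]
  expect_gte(unname(order), 0.9)
})

test_that("the dimensionally inconsistent (uncorrected) update does not solve the model", {
  # the corrected update multiplies (R1+R2+R1*beta) by Q_{n+1}; dropping
  # that factor (as in the uncorrected transcription) breaks the solution
  p <- wk_params("BA")
  T <- 0.8
  Qfun <- function(t) 10 + 5 * sin(2 * pi * t / T)
  dQfun <- function(t) 5 * 2 * pi / T * cos(2 * pi * t / T)
  dt <- T / 400
  tt <- seq(0, T, by = dt)
  ref <- rk4_windkessel(p, Qfun, dQfun, 20, T, dt / 100)
  refP <- approx(ref$t, ref$P, xout = tt)$y
  b <- p$R2 * p$C / dt
  P_bad <- P_good <- numeric(length(tt)); P_bad[1] <- P_good[1] <- 20
  for (i in seq_along(tt)[-1]) {
    Qn <- Qfun(tt[i - 1]); Qn1 <- Qfun(tt[i])
    P_good[i] <- ((p$R1 + p$R2 + p$R1 * b) * Qn1 - p$R1 * b * Qn +
                    b * P_good[i - 1]) / (1 + b)
    P_bad[i] <- ((p$R1 + p$R2 + p$R1 * b) - p$R1 * b * Qn +
                   b * P_bad[i - 1]) / (1 + b)
  }
  expect_lt(max(abs(P_good - refP)), 0.05)
  expect_gt(max(abs(P_bad - refP)), 10 * max(abs(P_good - refP)))
})

test_that("waveform-to-pressure map is linear and periodic state settles", {
  p <- wk_params("DAo")
  wf1 <- make_inlet_waveform(100, 20)
  wf3 <- make_inlet_waveform(100, 60)  # 3x the flow
  tr1 <- wk_simulate(p, wf1, dt = wf1$period / 500, n_cycles = 4, P0 = 0)
  tr3 <- wk_simulate(p, wf3, dt = wf1$period / 500, n_cycles = 4, P0 = 0)
  expect_equal(tr3$P_mmHg, 3 * tr1$P_mmHg, tolerance = 1e-10)
  # cycle-to-cycle max change decreases monotonically
  n <- 500
  cyc <- function(tr, c) tr$P_mmHg[((c - 1) * n + 1):(c * n)]
  deltas <- vapply(2:4, function(c) max(abs(cyc(tr1, c) - cyc(tr1, c - 1))), 0)
  expect_true(all(diff(deltas) < 0))
})

test_that("cycle-mean pressure equals (R1+R2) x cycle-mean flow within 0.5%", {
  p <- wk_params("BA")
  wf <- make_inlet_waveform(120, 25)
  dt <- wf$period / 1000
  tr <- wk_simulate(p, wf, dt = dt, n_cycles = 24)  # ~10 time constants
  last <- tr[tr$t_s > 23 * wf$period, ]
  expect_equal(mean(last$P_mmHg),
               (p$R1 + p$R2) * mean(last$Q_ml_s), tolerance = 5e-3)
})

test_that("constant inflow converges monotonically to the steady pressure", {
  p <- wk_params("BA")
  wf <- flow_waveform(function(t) rep(10, length(t)), period = 1)
  tr <- wk_simulate(p, wf, dt = 0.01, n_cycles = 16, P0 = 0)
  expect_equal(tail(tr$P_mmHg, 1), 25.8, tolerance = 1e-3)
  expect_true(all(diff(tr$P_mmHg) >= -1e-12))
  expect_error(wk_simulate(p, wf, dt = 2, n_cycles = 1), "period")
})

test_that("parameter sets round-trip through the YAML config format", {
  ps <- list(BA = wk_params("BA"), custom = wk_params("custom", 0.2, 1.5, 0.3))
  f <- tempfile(fileext = ".yaml")
  write_wk_config(ps, f)
  back <- read_wk_config(f)
  expect_equal(back$BA$R2, 2.480)
  expect_equal(back$custom$C, 0.3)
  tr <- wk_simulate(wk_params("BA"), make_inlet_waveform(100, 20),
                    dt = 0.01, n_cycles = 1)
  f2 <- tempfile(fileext = ".csv")
  write_wk_trace(tr, f2)
  back2 <- read.csv(f2)
  expect_equal(back2$P_mmHg, tr$P_mmHg)
})
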