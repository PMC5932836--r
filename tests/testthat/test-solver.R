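test_that("stable time step combines advective CFL and viscous cap", {
  expect_equal(courant_dt(1, 1, cfl = 0.5), 5e-4)
  expect_equal(courant_dt(1, 2, cfl = 0.5), 2.5e-4)  # doubling u halves dt
  # viscous cap active at small h: rho h^2 / (6 mu)
  expect_equal(courant_dt(0.1, 0.05, cfl = 0.5),
               1050 * (1e-4)^2 / (6 * 0.004), tolerance = 1e-12)
  expect_error(courant_dt(1, 0), "u_max")
})

test_that("rest state with zero boundary conditions is preserved exactly", {
  g <- build_aorta(tube_spec(10, 20))
  dom <- suppressWarnings(voxelize(g, 1))
  f <- flow_field(dom)
  prep <- aortohemo:::solver_prep(dom)
  for (i in 1:5) {
    f <- ns_advance(f, dom, bc = list(inlet_velocity = 0,
                                      outlet_pressures = c(outlet = 0)),
                    dt = 1e-3, prep = prep)
    expect_identical(max(abs(f$u)), 0)
    expect_identical(max(abs(f$w)), 0)
    expect_equal(attr(f, "maxdiv"), 0)
  }
})

test_that("uniform outlet pressure offset leaves the velocity field unchanged", {
  g <- build_aorta(tube_spec(10, 20))
  dom <- suppressWarnings(voxelize(g, 1))
  prep <- aortohemo:::solver_prep(dom)
  run <- function(poff) {
    f <- flow_field(dom)
    for (i in 1:10)
      f <- ns_advance(f, dom,
                      bc = list(inlet_velocity = 0.02,
                                outlet_pressures = c(outlet = poff)),
                      dt = 5e-4, prep = prep)
    f
  }
  f0 <- run(0)
  f1 <- run(2000)
  # agreement limited by the relative tolerance of the pressure solve
  expect_lt(max(abs(f1$u - f0$u)), 1e-6)
  expect_lt(max(abs(f1$w - f0$w)), 1e-6)
  # pressure shifts by exactly the offset
  fl <- dom$mask == 1L
  expect_equal(mean(f1$p[fl] - f0$p[fl]), 2000, tolerance = 1e-6)
})

test_that("steady tube run conserves mass and stays divergence-free", {
  ts <- steady_tube_sim()
  tr <- ts$sim$trace
  last <- tail(tr, 20)
  expect_lt(max(last$maxdiv_rel), ts$sim$controls$div_tol)
  expect_equal(tail(ts$sim$cycles$outlet_vol_ml, 1),
               tail(ts$sim$cycles$inlet_vol_ml, 1), tolerance = 1e-3)
  # converged inlet pressure near the Windkessel steady value (Poiseuille
  # drop at this flow is ~0.2% of it)
  p <- wk_params("BA")
  expect_equal(tail(tr$p_inlet_mmHg, 1),
               wk_steady_pressure(p, ts$Q), tolerance = 0.05)
})

test_that("recorded outlet pressures replay exactly through the 0D stepper", {
  ts <- steady_tube_sim(n_cycles = 2)
  tr <- ts$sim$trace
  p <- ts$sim$outlets$outlet
  # reconstruct the coupling: same initial state, same flux sequence
  Qbar <- ts$sim$inlet$stroke_volume / ts$sim$inlet$period
  st <- wk_state(P = wk_steady_pressure(p, Qbar), Q = Qbar, t = 0)
  dts <- diff(c(0, tr$t_s))
  P_replay <- numeric(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    st <- wk_step(p, st, tr$Q_outlet_ml_s[i], dts[i])
    P_replay[i] <- st$P
  }
  expect_equal(P_replay, tr$P_outlet_mmHg, tolerance = 1e-12)
})

test_that("Stokes-regime wall shear scales linearly with flow", {
  t1 <- steady_tube_sim(Q = 0.2)
  t2 <- steady_tube_sim(Q = 0.4)
  w1 <- wall_shear_stress(t1$sim$peak_field, t1$dom)
  w2 <- wall_shear_stress(t2$sim$peak_field, t2$dom)
  band <- w1$z_mm > 8 & w1$z_mm < 20
  expect_equal(w2$tau_Pa[band], 2 * w1$tau_Pa[band], tolerance = 0.02)
})

test_that("zero inflow keeps all Windkessel outlet pressures at zero", {
  g <- build_aorta(tube_spec(10, 20))
  dom <- suppressWarnings(voxelize(g, 1))
  wf <- flow_waveform(function(t) rep(0, length(t)), period = 0.5)
  ctl <- solver_controls(n_cycles = 2, dt_max_frac = 1 / 20,
                         periodicity_tol = 1)
  sim <- simulate_case(dom, wf, list(outlet = wk_params("BA")),
                       controls = ctl)
  expect_equal(max(abs(sim$trace$P_outlet_mmHg)), 0)
  expect_equal(max(abs(sim$trace$psv_cm_s)), 0)
  expect_error(simulate_case(dom, wf, list(bad_name = wk_params("BA")),
                             controls = ctl),
               "missing Windkessel")
})
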