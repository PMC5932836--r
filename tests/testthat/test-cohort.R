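test_that("half-sine inlet waveform has the stated peak and integral", {
  wf <- make_inlet_waveform(100, 30, 0.5)  # T = 0.6, t_sys = 0.3
  expect_equal(wf$t_sys, 0.3)
  expect_equal(wf$Q_peak, pi * 30 / 0.6, tolerance = 1e-12)
  expect_equal(max(waveform_flow(wf, seq(0, 0.6, 1e-4))), 157.08,
               tolerance = 1e-4)
  # integral over one period recovers the stroke volume for varied inputs
  for (par in list(c(80, 15, 0.3), c(140, 45, 0.4), c(110, 28, 0.35))) {
    wfi <- make_inlet_waveform(par[1], par[2], par[3])
    tt <- seq(0, wfi$period, length.out = 20001)
    q <- waveform_flow(wfi, pmin(tt, wfi$period - 1e-12))
    sv <- sum((q[-1] + q[-length(q)]) / 2 * diff(tt))
    expect_equal(sv, par[2], tolerance = 1e-3)
    expect_true(all(q >= 0))
  }
  wf0 <- make_inlet_waveform(100, 0)
  expect_true(all(waveform_flow(wf0, seq(0, 0.5, 0.01)) == 0))
  expect_error(make_inlet_waveform(100, 30, 1.2), "systolic_fraction")
  expect_error(make_inlet_waveform(-10, 30), "heart_rate")
})

test_that("waveform CSV round-trip preserves the flow curve", {
  wf <- make_inlet_waveform(120, 25)
  f <- tempfile(fileext = ".csv")
  write_waveform(wf, f, n = 400)
  back <- read_waveform(f)
  tt <- seq(0, wf$period, length.out = 101)
  expect_equal(waveform_flow(back, tt), waveform_flow(wf, tt), tolerance = 1e-2)
  expect_equal(back$period, wf$period)
})

test_that("cohort generation is deterministic and extensible", {
  c1 <- generate_cohort(cohort_spec(n = 8, seed = 7))
  c2 <- generate_cohort(cohort_spec(n = 8, seed = 7))
  expect_identical(c1, c2)
  # counter-based substreams: enlarging the cohort preserves earlier cases
  c3 <- generate_cohort(cohort_spec(n = 12, seed = 7))
  expect_identical(c3$cases[1:8], c1$cases)
  # different seed, different cohort
  c4 <- generate_cohort(cohort_spec(n = 8, seed = 8))
  expect_false(identical(c4$cases[[1]]$aorta_spec, c1$cases[[1]]$aorta_spec))
})

test_that("sampled diameters match the cohort distribution targets", {
  co <- generate_cohort(cohort_spec(n = 1000, seed = 3))
  asc <- vapply(co$cases, function(cs) cs$aorta_spec$inlet_diameter, 0)
  ai <- vapply(co$cases, function(cs) cs$aorta_spec$ai_diameter, 0)
  expect_equal(mean(asc), 19.2, tolerance = 0.4 / 19.2)  # 2 SE band
  expect_gt(min(asc), 3)
  expect_true(all(ai < asc))
  # every case of a default 25-case cohort builds a valid geometry
  co25 <- generate_cohort(cohort_spec(n = 25, seed = 1))
  for (cs in co25$cases) expect_s3_class(build_aorta(cs$aorta_spec),
                                         "aorta_geometry")
})

test_that("generated cases land in physiological PSV and PSP ranges", {
  co <- run_cohort(generate_cohort(cohort_spec(n = 40, seed = 5)))
  psv <- vapply(co$cases, `[[`, 0, "true_psv_cm_s")
  psp <- vapply(co$cases, `[[`, 0, "true_psp_mmHg")
  expect_true(all(psv > 50 & psv < 270))
  expect_true(all(psp > 70 & psp < 145))
  # the impedance scaling reproduces each case's pressure target
  tgt <- vapply(co$cases, `[[`, 0, "psp_target_mmHg")
  expect_equal(psp, tgt, tolerance = 1e-6)
})

test_that("measurement noise is additive, seeded and unbiased", {
  co <- run_cohort(generate_cohort(cohort_spec(n = 3, seed = 2)))
  cs <- co$cases[[1]]
  # zero noise SDs: measurement equals truth exactly
  spec0 <- cohort_spec(noise_sd_psv_cm_s = 0, noise_sd_psp_mmHg = 0)
  cs0 <- add_measurement_noise(cs, seed = 5, spec = spec0)
  expect_identical(cs0$meas_psv_cm_s, cs0$true_psv_cm_s)
  expect_identical(cs0$meas_psp_mmHg, cs0$true_psp_mmHg)
  # different seeds give different draws; same seed repeats
  csa <- add_measurement_noise(cs, seed = 5)
  csb <- add_measurement_noise(cs, seed = 6)
  csc <- add_measurement_noise(cs, seed = 5)
  expect_false(csa$meas_psp_mmHg == csb$meas_psp_mmHg)
  expect_identical(csa$meas_psp_mmHg, csc$meas_psp_mmHg)
  # CLT bound on the noise mean over many draws
  spec3 <- cohort_spec(noise_sd_psp_mmHg = 3)
  draws <- vapply(1:1000, function(s)
    add_measurement_noise(cs, seed = s, spec = spec3)$meas_psp_mmHg -
      cs$true_psp_mmHg, 0)
  expect_lt(abs(mean(draws)), 3 * 3 / sqrt(1000))
  # missing truth is an error
  expect_error(add_measurement_noise(generate_cohort(
    cohort_spec(n = 1))$cases[[1]]), "not filled")
})

test_that("correlation between noisy and true values decays with noise", {
  co <- run_cohort(generate_cohort(cohort_spec(n = 25, seed = 9)))
  true_psp <- vapply(co$cases, `[[`, 0, "true_psp_mmHg")
  rs <- vapply(c(1, 6, 25), function(sd) {
    co$spec$noise_sd_psp_mmHg <- sd
    noisy <- cohort_table(add_measurement_noise(co))$psp_cc_mmHg
    cor(true_psp, noisy)
  }, 0)
  expect_true(all(diff(rs) < 0))
})

test_that("cohort serialization round-trips losslessly", {
  co <- add_measurement_noise(run_cohort(generate_cohort(
    cohort_spec(n = 4, seed = 13))))
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort.yaml")))
  expect_true(file.exists(file.path(dir, "case_01", "spec.yaml")))
  expect_true(file.exists(file.path(dir, "measurements.csv")))
  back <- read_cohort(dir)
  expect_equal(cohort_table(back), cohort_table(co), tolerance = 1e-9)
  expect_equal(back$cases[[2]]$aorta_spec$inlet_diameter,
               co$cases[[2]]$aorta_spec$inlet_diameter, tolerance = 1e-9)
  expect_equal(back$cases[[3]]$outlets$BA$R2, co$cases[[3]]$outlets$BA$R2,
               tolerance = 1e-9)
})
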