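# Constructed-field tests: fields are filled analytically on small voxel
# domains so each extractor can be checked against closed forms.

make_domain <- function(D = 12, L = 24, h = 1) {
  suppressWarnings(voxelize(build_aorta(tube_spec(D, L)), h))
}

# fill staggered arrays from functions of the physical face positions (mm)
fill_field <- function(dom, ufun = NULL, vfun = NULL, wfun = NULL,
                       pfun = NULL) {
  f <- flow_field(dom)
  d <- dom$dims
  h <- dom$h
  o <- dom$origin
  if (!is.null(ufun)) {
    for (i in 1:(d[1] + 1)) for (j in 1:d[2]) for (k in 1:d[3])
      f$u[i, j, k] <- ufun(o[1] + (i - 1) * h, o[2] + (j - 0.5) * h,
                           o[3] + (k - 0.5) * h)
  }
  if (!is.null(vfun)) {
    for (i in 1:d[1]) for (j in 1:(d[2] + 1)) for (k in 1:d[3])
      f$v[i, j, k] <- vfun(o[1] + (i - 0.5) * h, o[2] + (j - 1) * h,
                           o[3] + (k - 0.5) * h)
  }
  if (!is.null(wfun)) {
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:(d[3] + 1))
      f$w[i, j, k] <- wfun(o[1] + (i - 0.5) * h, o[2] + (j - 0.5) * h,
                           o[3] + (k - 1) * h)
  }
  if (!is.null(pfun)) {
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
      f$p[i, j, k] <- pfun(o[1] + (i - 0.5) * h, o[2] + (j - 0.5) * h,
                           o[3] + (k - 0.5) * h)
  }
  f
}

test_that("zero-flow field has identically zero wall shear stress", {
  dom <- make_domain()
  wss <- wall_shear_stress(flow_field(dom), dom)
  expect_true(all(wss$tau_Pa == 0))
  # viscosity linearity at fixed kinematics
  f <- fill_field(dom, wfun = function(x, y, z) 0.1)
  w1 <- wall_shear_stress(f, dom, props = fluid_properties(mu = 0.004))
  w2 <- wall_shear_stress(f, dom, props = fluid_properties(mu = 0.008))
  expect_equal(w2$tau_Pa, 2 * w1$tau_Pa, tolerance = 1e-12)
  # dimension mismatch is caught
  dom2 <- make_domain(D = 10, L = 20)
  expect_error(wall_shear_stress(f, dom2), "do not match")
})

test_that("probe extraction converts units exactly", {
  dom <- make_domain()
  f <- fill_field(dom, pfun = function(x, y, z) 13332.2)
  pr <- extract_probes(f, dom)
  expect_equal(pr$psp_mmHg, 100, tolerance = 1e-12)
  f2 <- fill_field(dom, wfun = function(x, y, z) 0.5)
  pr2 <- extract_probes(f2, dom)
  expect_equal(pr2$psv_cm_s, 50, tolerance = 1e-12)
  # unit helpers round-trip to round-off
  x <- c(0.1, 1, 95.7)
  expect_equal(pa_to_mmhg(mmhg_to_pa(x)), x, tolerance = 1e-15)
  expect_equal(m3s_to_mls(mls_to_m3s(x)), x, tolerance = 1e-15)
})

test_that("peak times shift with the waveform and PSV/PSP are cycle maxima", {
  mk_sim <- function(shift) {
    tr <- data.frame(t_s = seq(0.01, 1, 0.01))
    tr$psv_cm_s <- 100 + 50 * sin(4 * pi * (tr$t_s - shift))
    tr$p_ai_mmHg <- 80 + 20 * sin(4 * pi * (tr$t_s - shift))
    structure(list(trace = tr, inlet = list(period = 0.5),
                   controls = list(n_cycles = 2)), class = "hemo_sim")
  }
  p0 <- extract_probes(mk_sim(0))
  p1 <- extract_probes(mk_sim(0.1))
  expect_equal(p1$t_psv_s - p0$t_psv_s, 0.1, tolerance = 0.011)
  expect_equal(p0$psv_cm_s, 150, tolerance = 0.5)
  expect_equal(p0$psp_mmHg, 100, tolerance = 0.5)
})

test_that("PSWSS extrema report the constructed extreme faces", {
  dom <- make_domain()
  # axial plug-like flow plus one boosted column: max must land there
  f <- fill_field(dom, wfun = function(x, y, z) 0.1)
  wss <- wall_shear_stress(f, dom)
  ex <- pswss_extrema(wss)
  expect_s3_class(ex, "pswss_extrema")
  expect_gt(ex$max$value, 0)
  # doctor a single face to a known global max and check it is found,
  # and that the answer is invariant under row permutation
  wss2 <- wss
  hot <- which(wss2$z_mm > 5 & wss2$z_mm < 20)[3]  # inside the kept band
  wss2$tau_Pa[hot] <- max(wss2$tau_Pa) * 10
  ex2 <- pswss_extrema(wss2)
  expect_equal(ex2$max$value, wss2$tau_Pa[hot])
  expect_equal(ex2$max$z_mm, wss2$z_mm[hot])
  perm <- sample(nrow(wss2))
  wss3 <- wss2[perm, ]
  attr(wss3, "h") <- attr(wss2, "h")
  attr(wss3, "z_top") <- attr(wss2, "z_top")
  class(wss3) <- class(wss2)
  ex3 <- pswss_extrema(wss3)
  expect_equal(ex3$max$value, ex2$max$value)
  expect_equal(ex3$min$value, ex2$min$value)
  expect_error(pswss_extrema(wss[0, ]), "empty")
})

test_that("LNH vanishes for irrotational uniform flow", {
  dom <- make_domain()
  f <- fill_field(dom, wfun = function(x, y, z) 0.3)
  hel <- streamlines_and_lnh(f, dom, seeds = matrix(c(0, 0, 2), 1))
  v <- hel$lnh[!is.na(hel$lnh)]
  expect_true(all(v == 0))
  # streamline of uniform axial flow is a straight vertical line
  sl <- hel$streamlines[[1]]
  expect_gt(nrow(sl), 10)
  expect_lt(max(abs(sl[, 1] - sl[1, 1])), 1e-9)
  expect_lt(max(abs(sl[, 2] - sl[1, 2])), 1e-9)
})

test_that("solid-body rotation plus axial flow gives LNH of the right sign", {
  dom <- make_domain()
  Om <- 50; wax <- 0.2
  mk <- function(Om, wax) fill_field(dom,
    ufun = function(x, y, z) -y * 1e-3 * Om,
    vfun = function(x, y, z) x * 1e-3 * Om,
    wfun = function(x, y, z) wax)
  hel <- streamlines_and_lnh(mk(Om, wax), dom)
  d <- dom$dims
  # near-axis fluid cells (|r| < 2 mm), away from caps
  ctr <- aortohemo:::cell_centers(dom$origin, dom$h, d, which(dom$mask == 1L))
  idx <- which(dom$mask == 1L)
  near <- idx[ctr[, 1]^2 + ctr[, 2]^2 < 4 & ctr[, 3] > 4 & ctr[, 3] < 20]
  expect_true(all(hel$lnh[near] > 0))
  expect_gt(mean(hel$lnh[near]), 0.9)
  # flipping the axial direction flips the sign
  hel2 <- streamlines_and_lnh(mk(Om, -wax), dom)
  expect_true(all(hel2$lnh[near] < 0))
  # seed in solid is skipped with a warning
  expect_warning(
    streamlines_and_lnh(mk(Om, wax), dom,
                        seeds = matrix(c(50, 50, 2), 1)),
    "outside the fluid")
})
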