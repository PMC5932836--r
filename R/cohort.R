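# Seeded virtual-patient cohorts: geometry specs, inlet waveforms and noisy
# "TTE"/"catheter" measurements with the statistical structure of the
# 25-infant reference cohort, so the full pipeline and the validation stage
# run end to end without clinical data.

#' Virtual cohort specification
#'
#' Distributional targets for the generator. Diameters are independent
#' truncated Gaussians matched to the reference cohort summary (ascending
#' aorta 19.2 +/- 6.0 mm, isthmus 12.1 +/- 3.5 mm, descending aorta
#' 10.9 +/- 2.6 mm). Each case samples a peak ascending-aorta velocity and
#' a target peak systolic pressure; the stroke volume follows from velocity
#' and lumen area, and the outlet impedances are scaled per case (R up, C
#' down by the same factor, preserving every time constant) so the lumped
#' network reproduces the pressure target. Measurement noise SDs default to
#' the reference limits-of-agreement half-widths divided by 1.96.
#'
#' @param n number of cases (default 25).
#' @param seed integer master seed; per-case substreams are derived from it
#'   by a counter scheme, so enlarging the cohort never reshuffles earlier
#'   cases.
#' @param asc_mm,ai_mm,dao_mm mean/SD pairs for the diameters, mm.
#' @param hr_bpm heart-rate range, beats/min.
#' @param vel_peak_cm_s mean/SD of the peak ascending-aorta velocity, cm/s
#'   (truncated to `vel_range_cm_s`).
#' @param vel_range_cm_s truncation range for the sampled velocity.
#' @param psp_mmHg mean/SD of the target peak systolic pressure, mmHg
#'   (truncated to `psp_range_mmHg`).
#' @param psp_range_mmHg truncation range for the pressure target.
#' @param systolic_fraction systole as a fraction of the cycle.
#' @param noise_sd_psv_cm_s,noise_sd_psp_mmHg additive Gaussian measurement
#'   noise SDs.
#' @param min_diameter_mm lower truncation for all sampled diameters.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 25, seed = 1,
                        asc_mm = c(19.2, 6.0), ai_mm = c(12.1, 3.5),
                        dao_mm = c(10.9, 2.6), hr_bpm = c(95, 140),
                        vel_peak_cm_s = c(110, 35),
                        vel_range_cm_s = c(55, 200),
                        psp_mmHg = c(105, 15.4),
                        psp_range_mmHg = c(75, 140),
                        systolic_fraction = 0.35,
                        noise_sd_psv_cm_s = 11.6,
                        noise_sd_psp_mmHg = 4.4,
                        min_diameter_mm = 3) {
  stopifnot(n >= 1, noise_sd_psv_cm_s >= 0, noise_sd_psp_mmHg >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

# counter-based per-case substream seed (kept below 2^31)
case_seed <- function(seed, i, stream = 0L) {
  as.integer(((seed %% 100000) * 7919 + i * 104729 + stream * 15485863) %%
               2147483647)
}

rtruncnorm1 <- function(mean, sd, lo = -Inf, hi = Inf, max_tries = 2000) {
  for (k in seq_len(max_tries)) {
    x <- rnorm(1, mean, sd)
    if (x > lo && x < hi) return(x)
  }
  stop("could not sample within (", lo, ", ", hi, ") after ", max_tries,
       " tries", call. = FALSE)
}

#' Generate a seeded virtual cohort
#'
#' @param spec a [cohort_spec()].
#' @return Object of class `virtual_cohort`: the spec plus one
#'   `virtual_case` per patient (geometry spec, inlet waveform, per-case
#'   Windkessel parameter set, pressure target; measured/true hemodynamics
#'   are filled by [run_cohort()] / [add_measurement_noise()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  base <- lapply(wk_default_labels(), wk_params)
  names(base) <- wk_default_labels()
  cases <- lapply(seq_len(spec$n), function(i) {
    set.seed(case_seed(spec$seed, i))
    lo <- spec$min_diameter_mm
    # joint resampling: the isthmus and descending diameters must stay
    # below the ascending diameter, so infeasible draws restart the case
    ok <- FALSE
    for (try in 1:50) {
      asc <- rtruncnorm1(spec$asc_mm[1], spec$asc_mm[2], lo = lo)
      if (0.95 * asc <= lo + 0.2) next
      ai <- tryCatch(rtruncnorm1(spec$ai_mm[1], spec$ai_mm[2], lo = lo,
                                 hi = 0.95 * asc, max_tries = 200),
                     error = function(e) NULL)
      dao <- tryCatch(rtruncnorm1(spec$dao_mm[1], spec$dao_mm[2], lo = lo,
                                  hi = 0.95 * asc, max_tries = 200),
                      error = function(e) NULL)
      if (!is.null(ai) && !is.null(dao)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not sample a feasible diameter triple for case ", i,
                  call. = FALSE)
    hr <- runif(1, spec$hr_bpm[1], spec$hr_bpm[2])
    vpk <- rtruncnorm1(spec$vel_peak_cm_s[1], spec$vel_peak_cm_s[2],
                       spec$vel_range_cm_s[1], spec$vel_range_cm_s[2])
    psp_target <- rtruncnorm1(spec$psp_mmHg[1], spec$psp_mmHg[2],
                              spec$psp_range_mmHg[1], spec$psp_range_mmHg[2])
    T <- 60 / hr
    t_sys <- spec$systolic_fraction * T
    area <- pi * (asc / 20)^2           # cm^2
    sv <- 2 * (vpk / 1.3) * area * t_sys / pi  # ml; Q_peak = vpk/1.3 * area
    geo <- aorta_spec(asc, dao, ai, asc_length = max(35, 1.6 * asc))
    wf <- make_inlet_waveform(hr, sv, spec$systolic_fraction)
    # scale the outlet impedances so the lumped network hits the pressure
    # target exactly (R1, R2 scaled up, C down: time constants preserved,
    # so pressures scale linearly at fixed flow)
    base_run <- simulate_case_lumped(wf, base, area)
    gam <- psp_target / base_run$psp_mmHg
    outl <- lapply(base, function(p)
      wk_params(p$label, R1 = gam * p$R1, R2 = gam * p$R2, C = p$C / gam))
    structure(list(id = i, aorta_spec = geo, waveform = wf,
                   heart_rate = hr, stroke_volume = sv,
                   asc_area_cm2 = area, outlets = outl,
                   psp_target_mmHg = psp_target,
                   true_psv_cm_s = NA_real_, true_psp_mmHg = NA_real_,
                   meas_psv_cm_s = NA_real_, meas_psp_mmHg = NA_real_),
              class = "virtual_case")
  })
  structure(list(spec = spec, cases = cases), class = "virtual_cohort")
}

#' @export
print.virtual_cohort <- function(x, ...) {
  asc <- vapply(x$cases, function(cs) cs$aorta_spec$inlet_diameter, 0)
  cat(sprintf("virtual_cohort: %d cases (seed %d); AscAo %.1f +/- %.1f mm\n",
              length(x$cases), x$spec$seed, mean(asc), sd(asc)))
  if (!anyNA(vapply(x$cases, `[[`, 0, "true_psp_mmHg")))
    cat("  simulated hemodynamics filled\n")
  invisible(x)
}

#' Run the simulation pipeline over a cohort
#'
#' Fills each case's true (simulated) PSV/PSP. The default `"lumped"`
#' method drives the per-case Windkessel network with the case waveform
#' (seconds per cohort); `"cfd"` runs the full 3D pipeline per case
#' (geometry build, voxelization at `h`, [simulate_case()], probes) and is
#' correspondingly expensive.
#'
#' @param cohort a [generate_cohort()] result.
#' @param method `"lumped"` or `"cfd"`.
#' @param h voxel spacing for `method = "cfd"`, mm.
#' @param controls [solver_controls()] for `method = "cfd"`.
#' @return The cohort with `true_psv_cm_s` / `true_psp_mmHg` filled.
#' @export
run_cohort <- function(cohort, method = c("lumped", "cfd"), h = NULL,
                       controls = solver_controls()) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "virtual_cohort"))
  cohort$cases <- lapply(cohort$cases, function(cs) {
    if (method == "lumped") {
      run <- simulate_case_lumped(cs$waveform, cs$outlets, cs$asc_area_cm2)
      cs$true_psv_cm_s <- run$psv_cm_s
      cs$true_psp_mmHg <- run$psp_mmHg
    } else {
      geom <- build_aorta(cs$aorta_spec)
      hh <- if (is.null(h)) 2 * min(cs$aorta_spec$branch_diameters) / 9 else h
      dom <- voxelize(geom, hh)
      sim <- simulate_case(dom, cs$waveform, cs$outlets, controls = controls)
      pr <- extract_probes(sim)
      cs$true_psv_cm_s <- pr$psv_cm_s
      cs$true_psp_mmHg <- pr$psp_mmHg
    }
    cs
  })
  cohort$method <- method
  cohort
}

#' Add seeded measurement noise to simulated hemodynamics
#'
#' Emulates the "TTE" velocity and "catheter" pressure readings: noisy
#' value = true value + Gaussian noise with the spec SDs, drawn once per
#' case from a dedicated substream. With zero SDs the measurements equal
#' the truth exactly.
#'
#' @param x a `virtual_case` or `virtual_cohort` with true values filled.
#' @param seed optional noise seed (default: the cohort/case master seed).
#' @return The input with `meas_psv_cm_s` / `meas_psp_mmHg` filled.
#' @export
add_measurement_noise <- function(x, seed = NULL, ...) UseMethod("add_measurement_noise")

#' @export
add_measurement_noise.virtual_case <- function(x, seed = NULL, spec = NULL, ...) {
  if (is.na(x$true_psv_cm_s) || is.na(x$true_psp_mmHg))
    stop("true PSV/PSP not filled; run the pipeline first", call. = FALSE)
  if (is.null(spec)) spec <- cohort_spec()
  if (is.null(seed)) seed <- 0
  set.seed(case_seed(seed, x$id, stream = 1L))
  x$meas_psv_cm_s <- x$true_psv_cm_s + rnorm(1, 0, spec$noise_sd_psv_cm_s)
  x$meas_psp_mmHg <- x$true_psp_mmHg + rnorm(1, 0, spec$noise_sd_psp_mmHg)
  x
}

#' @export
add_measurement_noise.virtual_cohort <- function(x, seed = NULL, ...) {
  if (is.null(seed)) seed <- x$spec$seed
  x$cases <- lapply(x$cases, add_measurement_noise, seed = seed, spec = x$spec)
  x
}

#' Cohort measurement table
#'
#' One row per case, mirroring the layout of the packaged reference table:
#' noisy "TTE"/"catheter" measurements alongside the simulated values.
#'
#' @param cohort a cohort after [run_cohort()] and [add_measurement_noise()].
#' @return Data frame with columns `case`, `psv_tte_cm_s`, `psv_cfd_cm_s`,
#'   `psp_cc_mmHg`, `psp_cfd_mmHg`.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "virtual_cohort"))
  do.call(rbind, lapply(cohort$cases, function(cs)
    data.frame(case = cs$id,
               psv_tte_cm_s = cs$meas_psv_cm_s,
               psv_cfd_cm_s = cs$true_psv_cm_s,
               psp_cc_mmHg = cs$meas_psp_mmHg,
               psp_cfd_mmHg = cs$true_psp_mmHg)))
}

# ---- serialization ---------------------------------------------------------

aorta_spec_to_list <- function(spec) unclass(spec)

list_to_aorta_spec <- function(x) {
  if (identical(x$kind, "tube"))
    return(tube_spec(x$inlet_diameter, x$length, x$outlet_diameter))
  aorta_spec(x$inlet_diameter, x$dao_diameter, x$ai_diameter,
             branch_diameters = unlist(x$branch_diameters),
             arch_radius = x$arch_radius, asc_length = x$asc_length,
             branch_clearance = x$branch_clearance,
             branch_angles_deg = unlist(x$branch_angles_deg),
             ai_offset = x$ai_offset,
             ai_stenosis_factor = x$ai_stenosis_factor,
             ai_width = x$ai_width)
}

#' Write / read a cohort as a directory of plain-text files
#'
#' Layout: `cohort.yaml` (spec, seed, method and per-case scalars),
#' `case_NN/spec.yaml` (geometry), `case_NN/inlet.csv` (waveform samples),
#' and `measurements.csv` (the [cohort_table()] when noise has been added).
#'
#' @param cohort a `virtual_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(spec = unclass(cohort$spec), method = cohort$method,
               cases = lapply(cohort$cases, function(cs)
                 list(id = cs$id, heart_rate = cs$heart_rate,
                      stroke_volume = cs$stroke_volume,
                      asc_area_cm2 = cs$asc_area_cm2,
                      psp_target_mmHg = cs$psp_target_mmHg,
                      true_psv_cm_s = cs$true_psv_cm_s,
                      true_psp_mmHg = cs$true_psp_mmHg,
                      meas_psv_cm_s = cs$meas_psv_cm_s,
                      meas_psp_mmHg = cs$meas_psp_mmHg,
                      outlets = lapply(cs$outlets, function(p)
                        list(R1 = p$R1, R2 = p$R2, C = p$C)))))
  yaml::write_yaml(meta, file.path(dir, "cohort.yaml"), precision = 15)
  for (cs in cohort$cases) {
    cdir <- file.path(dir, sprintf("case_%02d", cs$id))
    dir.create(cdir, showWarnings = FALSE)
    yaml::write_yaml(aorta_spec_to_list(cs$aorta_spec),
                     file.path(cdir, "spec.yaml"), precision = 15)
    write_waveform(cs$waveform, file.path(cdir, "inlet.csv"))
  }
  if (!anyNA(vapply(cohort$cases, `[[`, 0, "meas_psp_mmHg")))
    write.csv(cohort_table(cohort), file.path(dir, "measurements.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "cohort.yaml"))
  spec <- structure(meta$spec, class = "cohort_spec")
  for (nm in c("asc_mm", "ai_mm", "dao_mm", "hr_bpm", "vel_peak_cm_s",
               "vel_range_cm_s", "psp_mmHg", "psp_range_mmHg"))
    spec[[nm]] <- unlist(spec[[nm]])
  cases <- lapply(meta$cases, function(mc) {
    cdir <- file.path(dir, sprintf("case_%02d", mc$id))
    geo <- list_to_aorta_spec(yaml::read_yaml(file.path(cdir, "spec.yaml")))
    wf <- make_inlet_waveform(mc$heart_rate, mc$stroke_volume,
                              spec$systolic_fraction)
    outl <- lapply(names(mc$outlets), function(nm)
      wk_params(nm, R1 = mc$outlets[[nm]]$R1, R2 = mc$outlets[[nm]]$R2,
                C = mc$outlets[[nm]]$C))
    names(outl) <- names(mc$outlets)
    structure(list(id = mc$id, aorta_spec = geo, waveform = wf,
                   heart_rate = mc$heart_rate,
                   stroke_volume = mc$stroke_volume,
                   asc_area_cm2 = mc$asc_area_cm2, outlets = outl,
                   psp_target_mmHg = mc$psp_target_mmHg,
                   true_psv_cm_s = mc$true_psv_cm_s %||% NA_real_,
                   true_psp_mmHg = mc$true_psp_mmHg %||% NA_real_,
                   meas_psv_cm_s = mc$meas_psv_cm_s %||% NA_real_,
                   meas_psp_mmHg = mc$meas_psp_mmHg %||% NA_real_),
              class = "virtual_case")
  })
  structure(list(spec = spec, cases = cases, method = meta$method),
            class = "virtual_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
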