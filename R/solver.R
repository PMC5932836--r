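# R-side driver for the staggered-grid projection solver. The voxel grid is
# in mm; the solver itself works in SI (m, s, Pa) and converts at the
# boundary. Outlet pressures come from the three-element Windkessel models,
# coupled explicitly: the outlet flux measured at one step drives the 0D
# model whose pressure is applied as that outlet's uniform Dirichlet
# pressure at the next step.

#' Blood properties for the flow solver
#'
#' @param rho density, kg/m^3 (default 1050).
#' @param mu dynamic viscosity, Pa s (default 0.004; Newtonian).
#' @param F constant body force, N/m^3 (default zero).
#' @return Object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1050, mu = 0.004, F = c(0, 0, 0)) {
  stopifnot(rho > 0, mu > 0, length(F) == 3)
  structure(list(rho = rho, mu = mu, F = F), class = "fluid_properties")
}

#' Solver controls
#'
#' @param cfl target Courant number (advective), <= 0.5.
#' @param n_cycles number of cardiac cycles to run; the last is analyzed.
#' @param dt_max_frac upper bound on dt as a fraction of the period.
#' @param cg_tol relative residual tolerance of the pressure solve.
#' @param cg_maxit iteration cap of the pressure solve.
#' @param div_tol dimensionless divergence tolerance: the post-projection
#'   check bounds `max |div u| * h / max(u_max, u_floor)` each step.
#' @param periodicity_tol relative cycle-to-cycle change in outlet pressures
#'   below which the run is considered periodic.
#' @param u_floor velocity floor (m/s) used when picking dt at rest.
#' @return Object of class `solver_controls`.
#' @export
solver_controls <- function(cfl = 0.4, n_cycles = 3, dt_max_frac = 1 / 200,
                            cg_tol = 1e-8, cg_maxit = 2000, div_tol = 1e-4,
                            periodicity_tol = 0.02, u_floor = 0.05) {
  stopifnot(cfl > 0, cfl <= 0.5, n_cycles >= 1, cg_tol > 0, div_tol > 0)
  structure(list(cfl = cfl, n_cycles = n_cycles, dt_max_frac = dt_max_frac,
                 cg_tol = cg_tol, cg_maxit = cg_maxit, div_tol = div_tol,
                 periodicity_tol = periodicity_tol, u_floor = u_floor),
            class = "solver_controls")
}

#' Stable time step for the explicit scheme
#'
#' `dt = cfl * h / u_max`, additionally capped by the explicit viscous
#' limit `rho h^2 / (6 mu)`.
#'
#' @param h grid spacing in mm (or a `voxel_domain`).
#' @param u_max velocity scale, m/s (> 0).
#' @param cfl Courant target.
#' @param props [fluid_properties()].
#' @return Time step in seconds.
#' @examples
#' courant_dt(1, 1, cfl = 0.5)  # 5e-4 s
#' @export
courant_dt <- function(h, u_max, cfl = 0.5, props = fluid_properties()) {
  if (inherits(h, "voxel_domain")) h <- h$h
  stopifnot(u_max > 0, h > 0)
  h_m <- h * 1e-3
  min(cfl * h_m / u_max, props$rho * h_m^2 / (6 * props$mu))
}

# Precompute face-type arrays and probe index sets for a domain.
solver_prep <- function(domain) {
  d <- domain$dims
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  m <- domain$mask
  fu <- array(0L, c(nx + 1, ny, nz))
  fu[2:nx, , ] <- (m[1:(nx - 1), , ] == 1L) * (m[2:nx, , ] == 1L)
  fv <- array(0L, c(nx, ny + 1, nz))
  fv[, 2:ny, ] <- (m[, 1:(ny - 1), ] == 1L) * (m[, 2:ny, ] == 1L)
  fw <- array(0L, c(nx, ny, nz + 1))
  fw[, , 2:nz] <- (m[, , 1:(nz - 1)] == 1L) * (m[, , 2:nz] == 1L)
  b1 <- fw[, , 1]
  b1[domain$caps$inlet$cells] <- 2L
  outlet_names <- names(domain$caps$outlets)
  for (o in seq_along(outlet_names)) {
    cap <- domain$caps$outlets[[o]]
    if (cap$side == "bottom") {
      b1[cap$cells] <- 2L + o
    } else {
      bt <- fw[, , nz + 1]
      bt[cap$cells] <- 2L + o
      fw[, , nz + 1] <- bt
    }
  }
  fw[, , 1] <- b1
  list(fu = as.integer(fu), fv = as.integer(fv), fw = as.integer(fw),
       outlet_names = outlet_names, mask = as.integer(m),
       dims = as.integer(d))
}

# cell-centered velocity components on slice k (matrices nx x ny)
slice_cc_velocity <- function(field, k) {
  nx <- dim(field$p)[1]
  u <- (field$u[1:nx, , k] + field$u[2:(nx + 1), , k]) / 2
  ny <- dim(field$p)[2]
  v <- (field$v[, 1:ny, k] + field$v[, 2:(ny + 1), k]) / 2
  w <- (field$w[, , k] + field$w[, , k + 1]) / 2
  list(u = u, v = v, w = w)
}

new_flow_field <- function(domain) {
  d <- domain$dims
  list(u = array(0, c(d[1] + 1, d[2], d[3])),
       v = array(0, c(d[1], d[2] + 1, d[3])),
       w = array(0, c(d[1], d[2], d[3] + 1)),
       p = array(0, d), t = 0)
}

#' Advance the flow field by one time step
#'
#' One projection (fractional) step: explicit upwind advection and
#' diffusion build a provisional velocity, a pressure Poisson solve with
#' the prescribed outlet pressures enforces continuity, and the velocity is
#' corrected with the pressure gradient. After the step the discrete
#' divergence in every fluid cell is below the solver tolerance.
#'
#' @param field flow field as returned by [flow_field()] or a previous call.
#' @param domain a [voxelize()] domain.
#' @param bc list with `inlet_velocity` (m/s, plug value on the inlet cap)
#'   and `outlet_pressures` (named, Pa, one per outlet).
#' @param props [fluid_properties()].
#' @param dt time step, s.
#' @param controls [solver_controls()].
#' @param prep optional cached [solver_prep()] result (internal).
#' @return The advanced field, with attributes `maxdiv`, `outflux` (m^3/s,
#'   named), `influx`, `umax`, `cg_iters`.
#' @export
ns_advance <- function(field, domain, bc, props = fluid_properties(),
                       dt, controls = solver_controls(), prep = NULL) {
  if (is.null(prep)) prep <- solver_prep(domain)
  pout <- mmhg_to_pa(rep(0, length(prep$outlet_names)))
  if (!is.null(bc$outlet_pressures)) {
    stopifnot(all(prep$outlet_names %in% names(bc$outlet_pressures)))
    pout <- as.numeric(bc$outlet_pressures[prep$outlet_names])
  }
  win <- if (is.null(bc$inlet_velocity)) 0 else bc$inlet_velocity
  # work on copies: the kernel updates its arguments in place
  field <- list(u = field$u + 0, v = field$v + 0, w = field$w + 0,
                p = field$p + 0, t = field$t)
  res <- ns_step_cpp(field$u, field$v, field$w, field$p, prep$mask,
                     prep$fu, prep$fv, prep$fw, prep$dims,
                     domain$h * 1e-3, dt, props$rho, props$mu, win, pout,
                     as.numeric(props$F), controls$cg_tol, controls$cg_maxit)
  if (res$iters >= controls$cg_maxit && res$relres > controls$cg_tol)
    stop(sprintf("pressure solve failed to converge: relative residual %.3g after %d iterations",
                 res$relres, res$iters), call. = FALSE)
  field$t <- field$t + dt
  attr(field, "maxdiv") <- res$maxdiv
  attr(field, "outflux") <- structure(res$outflux, names = prep$outlet_names)
  attr(field, "influx") <- res$influx
  attr(field, "umax") <- res$umax
  attr(field, "cg_iters") <- res$iters
  field
}

#' @rdname ns_advance
#' @export
flow_field <- function(domain) new_flow_field(domain)

#' Run a Windkessel-coupled pulsatile simulation
#'
#' Runs `n_cycles` cardiac cycles of the pulsatile inflow through the
#' voxelized domain. At every time step the flux measured through each
#' outlet cap feeds that outlet's three-element Windkessel model
#' ([wk_step()]); the resulting pressure (mmHg, converted to Pa) is applied
#' as the outlet's uniform pressure boundary condition at the following
#' step. The run starts from rest with outlet pressures at the Windkessel
#' steady values for the cycle-mean flow. The final cycle is analyzed; a
#' cycle-to-cycle periodicity metric is recorded and a warning attached if
#' the run has not reached a periodic state.
#'
#' @param domain a [voxelize()] domain.
#' @param inlet a [flow_waveform()] (ml/s), applied as a plug velocity
#'   scaled so the volumetric inflow matches the waveform.
#' @param outlets named list of [wk_params()], one per outlet of the domain.
#' @param props [fluid_properties()].
#' @param controls [solver_controls()].
#' @param verbose print per-cycle progress.
#' @return An object of class `hemo_sim`: probe traces, Windkessel traces,
#'   per-cycle mass/periodicity summary, and the flow field snapshot at the
#'   peak-systolic instant of the final cycle.
#' @export
simulate_case <- function(domain, inlet, outlets, props = fluid_properties(),
                          controls = solver_controls(), verbose = FALSE) {
  stopifnot(inherits(domain, "voxel_domain"), inherits(inlet, "flow_waveform"))
  prep <- solver_prep(domain)
  onames <- prep$outlet_names
  if (!all(onames %in% names(outlets)))
    stop("missing Windkessel parameters for outlet(s): ",
         paste(setdiff(onames, names(outlets)), collapse = ", "), call. = FALSE)
  outlets <- outlets[onames]

  T <- inlet$period
  A_in <- cap_area(domain, "inlet") * 1e-6  # m^2
  wf <- as_waveform_fun(inlet)
  h_m <- domain$h * 1e-3
  visc_cap <- props$rho * h_m^2 / (6 * props$mu)

  # Windkessel initialization: steady pressures at cycle-mean flow,
  # distributed by total-resistance conductance
  Qbar <- inlet$stroke_volume / T  # ml/s
  g <- vapply(outlets, function(p) 1 / (p$R1 + p$R2), 0)
  wk <- lapply(seq_along(outlets), function(o) {
    Qo <- Qbar * g[o] / sum(g)
    wk_state(P = wk_steady_pressure(outlets[[o]], Qo), Q = Qo, t = 0)
  })
  names(wk) <- onames

  # probe cell sets (slice-local (i,j) indices)
  probes <- list()
  for (nm in names(domain$geom$probes)) {
    pl <- domain$geom$probes[[nm]]
    k <- max(1L, min(domain$dims[3],
                     as.integer(round((pl$z - domain$origin[3]) / domain$h + 0.5))))
    slice_reg <- domain$region[, , k]
    keep <- if (domain$geom$kind == "tube") slice_reg > 0L
            else if (pl$segment == "asc") slice_reg == 1L
            else slice_reg %in% c(3L, 4L)
    probes[[nm]] <- list(k = k, cells = which(keep & domain$mask[, , k] == 1L))
  }
  psv_probe <- if (domain$geom$kind == "tube") "mid" else "AscAo"
  pai_probe <- if (domain$geom$kind == "tube") "mid" else "AI"

  field <- new_flow_field(domain)
  t_peak_frac <- if (!is.null(inlet$t_sys)) inlet$t_sys / 2 else {
    ts <- seq(0, T, length.out = 1000)
    ts[which.max(wf(ts))]
  }
  # a peak at the cycle start (constant inflow) is captured at the cycle end
  if (t_peak_frac <= 0) t_peak_frac <- T

  rec <- list()
  cyc <- list()
  p_prev <- NULL
  umax <- 0
  t <- 0
  cycle <- 1L
  in_vol <- 0; out_vol <- numeric(length(onames))
  p_end_prev <- NULL
  peak_field <- NULL
  periodicity <- numeric(0)
  warnings <- character(0)
  step <- 0L

  while (cycle <= controls$n_cycles) {
    t_cyc_end <- cycle * T
    t_peak <- (cycle - 1) * T + t_peak_frac
    win_now <- mls_to_m3s(wf(t)) / A_in
    dt <- min(controls$cfl * h_m / max(umax, abs(win_now), controls$u_floor),
              visc_cap, T * controls$dt_max_frac)
    # land exactly on the peak-systole instant and on cycle boundaries
    if (t < t_peak && t + dt > t_peak) dt <- t_peak - t
    if (t + dt > t_cyc_end) dt <- t_cyc_end - t
    t_new <- t + dt

    win <- mls_to_m3s(wf(t_new)) / A_in
    pout <- vapply(wk, function(s) mmhg_to_pa(s$P), 0)
    # linear extrapolation of the pressure warm start
    if (!is.null(p_prev)) {
      p_now <- field$p + 0
      field$p <- 2 * field$p - p_prev
      p_prev <- p_now
    } else {
      p_prev <- field$p + 0
    }
    res <- ns_step_cpp(field$u, field$v, field$w, field$p, prep$mask,
                       prep$fu, prep$fv, prep$fw, prep$dims, h_m, dt,
                       props$rho, props$mu, win, pout, as.numeric(props$F),
                       controls$cg_tol, controls$cg_maxit)
    umax <- res$umax
    step <- step + 1L
    # explicit 0D coupling: measured outlet fluxes -> next-step pressures
    for (o in seq_along(wk))
      wk[[o]] <- wk_step(outlets[[o]], wk[[o]], m3s_to_mls(res$outflux[o]), dt)
    in_vol <- in_vol + m3s_to_mls(res$influx) * dt
    out_vol <- out_vol + m3s_to_mls(res$outflux) * dt
    field$t <- t_new

    cc <- slice_cc_velocity(field, probes[[psv_probe]]$k)
    cells <- probes[[psv_probe]]$cells
    psv <- if (length(cells)) {
      100 * sqrt(max(cc$u[cells]^2 + cc$v[cells]^2 + cc$w[cells]^2))
    } else NA_real_
    pai_cells <- probes[[pai_probe]]$cells
    pai <- pa_to_mmhg(mean(field$p[, , probes[[pai_probe]]$k][pai_cells]))
    pin <- pa_to_mmhg(mean(field$p[, , 1][domain$caps$inlet$cells]))
    rec[[length(rec) + 1L]] <- c(t_new, wf(t_new), psv, pai, pin,
                                 res$maxdiv,
                                 res$maxdiv * h_m / max(umax, controls$u_floor),
                                 res$iters,
                                 m3s_to_mls(res$influx),
                                 m3s_to_mls(res$outflux),
                                 vapply(wk, function(s) s$P, 0))
    if (abs(t_new - t_peak) < 1e-12) {
      # deep-copy: the live field arrays are updated in place by the kernel
      peak_field <- list(u = field$u + 0, v = field$v + 0, w = field$w + 0,
                         p = field$p + 0, t = field$t,
                         t_in_cycle = t_peak_frac)
    }
    t <- t_new

    if (abs(t - t_cyc_end) < 1e-12) {
      p_end <- vapply(wk, function(s) s$P, 0)
      if (!is.null(p_end_prev)) {
        periodicity <- c(periodicity,
                         max(abs(p_end - p_end_prev) / pmax(abs(p_end), 1)))
      }
      cyc[[cycle]] <- c(cycle = cycle, inlet_vol_ml = in_vol,
                        outlet_vol_ml = sum(out_vol))
      if (verbose)
        message(sprintf("cycle %d: %d steps, inflow %.2f ml, outflow %.2f ml%s",
                        cycle, step, in_vol, sum(out_vol),
                        if (length(periodicity))
                          sprintf(", periodicity %.4f", tail(periodicity, 1))
                        else ""))
      p_end_prev <- p_end
      in_vol <- 0; out_vol <- numeric(length(onames))
      cycle <- cycle + 1L
      step <- 0L
    }
  }

  if (length(periodicity) && tail(periodicity, 1) > controls$periodicity_tol) {
    msg <- sprintf("run not periodic after %d cycles (metric %.3g > %.3g)",
                   controls$n_cycles, tail(periodicity, 1),
                   controls$periodicity_tol)
    warnings <- c(warnings, msg)
    warning(msg, call. = FALSE)
  }

  tr <- do.call(rbind, rec)
  colnames(tr) <- c("t_s", "Q_in_ml_s", "psv_cm_s", "p_ai_mmHg",
                    "p_inlet_mmHg", "maxdiv", "maxdiv_rel", "cg_iters",
                    "influx_ml_s",
                    paste0("Q_", onames, "_ml_s"),
                    paste0("P_", onames, "_mmHg"))
  structure(list(
    trace = as.data.frame(tr),
    cycles = as.data.frame(do.call(rbind, cyc)),
    periodicity = periodicity,
    peak_field = peak_field,
    domain = domain, props = props, controls = controls,
    outlets = outlets, inlet = inlet,
    warnings = warnings
  ), class = "hemo_sim")
}

#' @export
print.hemo_sim <- function(x, ...) {
  T <- x$inlet$period
  last <- x$trace[x$trace$t_s > (x$controls$n_cycles - 1) * T, ]
  cat(sprintf("hemo_sim: %d cycles of %.3f s on %d fluid cells (h = %.2f mm)\n",
              x$controls$n_cycles, T, x$domain$n_fluid, x$domain$h))
  cat(sprintf("  final cycle: PSV %.1f cm/s, PSP(AI) %.1f mmHg, max divergence %.2e /s\n",
              max(last$psv_cm_s), max(last$p_ai_mmHg), max(last$maxdiv)))
  if (length(x$periodicity))
    cat(sprintf("  periodicity metric: %s\n",
                paste(sprintf("%.4f", x$periodicity), collapse = " -> ")))
  if (length(x$warnings)) cat("  warnings:", x$warnings, sep = "\n   ")
  invisible(x)
}
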