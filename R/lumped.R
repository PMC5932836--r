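# Reduced-order (0D) whole-aorta model: a single aortic pressure node fed
# by the inlet waveform and drained through the four three-element
# Windkessel outlets. This is the cohort-scale surrogate for the 3D solver:
# it preserves the pressure dynamics that the Windkessel network imposes
# (and therefore the PSP the catheter probe reads), while PSV follows from
# the peak volumetric flow through the ascending-aorta cross-section times
# a velocity profile factor.

#' Reduced-order Windkessel-network simulation of one case
#'
#' Solves the lumped network: at each instant the aortic node pressure
#' P_ao satisfies sum of outlet flows = inlet flow with
#' `Q_k = (P_ao - P_c,k) / R1_k`, and each outlet's compliance pressure
#' follows `C dP_c/dt = Q_k - P_c/R2` (semi-implicit Euler). Pressures in
#' mmHg, flows in ml/s.
#'
#' @param inlet a [flow_waveform()].
#' @param outlets named list of [wk_params()].
#' @param asc_area_cm2 ascending-aorta cross-section area, cm^2 (for PSV).
#' @param n_cycles cycles to run (last analyzed; default 6).
#' @param steps_per_cycle time resolution.
#' @param profile_factor ratio of peak (sampled) to mean velocity on the
#'   ascending-aorta plane; 1.3 emulates the partially developed inlet
#'   profile a Doppler beam samples.
#' @return Object of class `hemo_sim_0d` with the final-cycle trace and
#'   `psv_cm_s`, `psp_mmHg`.
#' @export
simulate_case_lumped <- function(inlet, outlets, asc_area_cm2,
                                 n_cycles = 6, steps_per_cycle = 1500,
                                 profile_factor = 1.3) {
  stopifnot(inherits(inlet, "flow_waveform"), asc_area_cm2 > 0)
  T <- inlet$period
  dt <- T / steps_per_cycle
  R1 <- vapply(outlets, `[[`, 0, "R1")
  R2 <- vapply(outlets, `[[`, 0, "R2")
  C <- vapply(outlets, `[[`, 0, "C")
  g <- 1 / (R1 + R2)
  Qbar <- inlet$stroke_volume / T
  Pc <- (Qbar * g / sum(g)) * R2  # steady compliance pressures at mean flow
  n <- n_cycles * steps_per_cycle
  tt <- seq(dt, by = dt, length.out = n)
  Qin <- waveform_flow(inlet, tt)
  last <- (n - steps_per_cycle + 1):n
  Pao_tr <- numeric(n)
  Qk_last <- matrix(0, steps_per_cycle, length(outlets))
  for (i in seq_len(n)) {
    Pao <- (Qin[i] + sum(Pc / R1)) / sum(1 / R1)
    Qk <- (Pao - Pc) / R1
    Pc <- (Pc + (dt / C) * Qk) / (1 + dt / (R2 * C))
    Pao_tr[i] <- Pao
    if (i >= last[1]) Qk_last[i - last[1] + 1, ] <- Qk
  }
  psp <- max(Pao_tr[last])
  psv <- profile_factor * max(Qin) / asc_area_cm2  # ml/s / cm^2 = cm/s
  structure(list(
    trace = data.frame(t_s = tt[last] - tt[last[1]] + dt,
                       Q_in_ml_s = Qin[last], P_ao_mmHg = Pao_tr[last]),
    outlet_flows = Qk_last, outlet_names = names(outlets),
    psv_cm_s = psv, psp_mmHg = psp,
    profile_factor = profile_factor, asc_area_cm2 = asc_area_cm2
  ), class = "hemo_sim_0d")
}

#' @export
print.hemo_sim_0d <- function(x, ...) {
  cat(sprintf("reduced-order case: PSV %.1f cm/s, PSP %.1f mmHg (aortic node, final cycle)\n",
              x$psv_cm_s, x$psp_mmHg))
  invisible(x)
}
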