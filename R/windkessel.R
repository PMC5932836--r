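# Three-element Windkessel (lumped-parameter) outlet model.
#
# The model relates outlet pressure P (mmHg) to outlet flow Q (ml/s) through
# a characteristic resistance R1 in series with a parallel combination of a
# peripheral resistance R2 and a compliance C:
#
#   P + R2*C dP/dt = (R1 + R2) Q + R1*R2*C dQ/dt
#
# Time stepping uses the backward-Euler discretization with b = R2*C/dt:
#
#   P_{n+1} = [ (R1 + R2 + R1*b) Q_{n+1} - R1*b Q_n + b P_n ] / (1 + b)

# Reference parameter table for the four aortic outlets
# (units: R in mmHg s/ml, C in ml/mmHg).
.wk_table <- data.frame(
  label = c("BA", "LCCA", "LSA", "DAo"),
  R1 = c(0.100, 0.110, 0.150, 0.120),
  R2 = c(2.480, 2.510, 2.624, 2.118),
  C  = c(0.466, 0.443, 0.437, 0.421),
  stringsAsFactors = FALSE
)

#' Three-element Windkessel parameters
#'
#' Construct a parameter set for the three-element Windkessel outlet model,
#' either from a named reference outlet (brachiocephalic artery `"BA"`, left
#' common carotid `"LCCA"`, left subclavian `"LSA"`, descending aorta
#' `"DAo"`) or from explicit values.
#'
#' @param label outlet name. With no other arguments, returns the packaged
#'   reference values for that outlet; with explicit `R1`, `R2`, `C` it is
#'   just a tag.
#' @param R1 characteristic resistance, mmHg s/ml.
#' @param R2 peripheral resistance (impedance), mmHg s/ml.
#' @param C arterial compliance, ml/mmHg.
#' @return An object of class `wk_params` with fields `R1`, `R2`, `C`,
#'   `label`.
#' @examples
#' wk_params("BA")
#' wk_params("custom", R1 = 0.1, R2 = 2.0, C = 0.5)
#' @export
wk_params <- function(label, R1 = NULL, R2 = NULL, C = NULL) {
  if (is.null(R1) && is.null(R2) && is.null(C)) {
    i <- match(label, .wk_table$label)
    if (is.na(i)) {
      stop("unknown outlet label '", label, "'; known labels: ",
           paste(.wk_table$label, collapse = ", "), call. = FALSE)
    }
    R1 <- .wk_table$R1[i]; R2 <- .wk_table$R2[i]; C <- .wk_table$C[i]
  }
  stopifnot(is.numeric(R1), is.numeric(R2), is.numeric(C))
  if (R1 <= 0 || R2 <= 0 || C <= 0)
    stop("Windkessel parameters R1, R2, C must all be positive", call. = FALSE)
  structure(list(R1 = R1, R2 = R2, C = C, label = label),
            class = "wk_params")
}

#' @rdname wk_params
#' @export
wk_default_labels <- function() .wk_table$label

#' @export
print.wk_params <- function(x, ...) {
  cat(sprintf("Windkessel outlet '%s': R1 = %.3f, R2 = %.3f mmHg s/ml, C = %.3f ml/mmHg (tau = R2*C = %.4f s)\n",
              x$label, x$R1, x$R2, x$C, x$R2 * x$C))
  invisible(x)
}

#' Steady-state Windkessel pressure
#'
#' In the steady limit (dP/dt = dQ/dt = 0) the model reduces to
#' `P = (R1 + R2) * Q`.
#'
#' @param params a [wk_params()] object.
#' @param Q flow rate, ml/s.
#' @return Pressure in mmHg.
#' @examples
#' wk_steady_pressure(wk_params("BA"), 10) # 25.8 mmHg
#' @export
wk_steady_pressure <- function(params, Q) {
  stopifnot(inherits(params, "wk_params"), is.finite(Q))
  (params$R1 + params$R2) * Q
}

#' Windkessel state
#'
#' A snapshot of the 0D outlet model: pressure `P` (mmHg), flow `Q` (ml/s)
#' and time `t` (s).
#'
#' @param P pressure, mmHg.
#' @param Q flow rate, ml/s.
#' @param t time, s.
#' @export
wk_state <- function(P = 0, Q = 0, t = 0) {
  structure(list(P = P, Q = Q, t = t), class = "wk_state")
}

#' One backward-Euler step of the Windkessel model
#'
#' Advances the outlet pressure by one time step given the flow at the new
#' time level, using the backward-Euler discretization of the three-element
#' model (see the package vignette for the update formula and its
#' derivation).
#'
#' @param params a [wk_params()] object.
#' @param state a [wk_state()] holding `P_n`, `Q_n` at time `t`.
#' @param Q_next flow rate at time `t + dt`, ml/s.
#' @param dt time step, s; must be positive.
#' @return A new [wk_state()] at `t + dt`.
#' @examples
#' s <- wk_step(wk_params("BA"), wk_state(0, 0, 0), Q_next = 10, dt = 0.01)
#' s$P # about 1.2127 mmHg
#' @export
wk_step <- function(params, state, Q_next, dt) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  b <- params$R2 * params$C / dt
  P_next <- ((params$R1 + params$R2 + params$R1 * b) * Q_next -
               params$R1 * b * state$Q + b * state$P) / (1 + b)
  wk_state(P = P_next, Q = Q_next, t = state$t + dt)
}

#' Simulate the Windkessel model over cardiac cycles
#'
#' Integrates the outlet model against a periodic inflow waveform with the
#' backward-Euler stepper, sampling every `dt` over `n_cycles` periods.
#'
#' @param params a [wk_params()] object.
#' @param waveform a [flow_waveform()] (or any function of time returning
#'   ml/s together with a `period` attribute).
#' @param dt time step, s; must be smaller than the waveform period.
#' @param n_cycles number of cardiac cycles to cover (>= 1).
#' @param P0 initial pressure, mmHg. Default: the steady pressure at the
#'   cycle-mean flow, which minimizes the startup transient.
#' @return A data frame of class `wk_trace` with columns `t_s`, `Q_ml_s`,
#'   `P_mmHg` (first row is the initial state at t = 0).
#' @examples
#' wf <- flow_waveform(function(t) rep(10, length(t)), period = 1)
#' tr <- wk_simulate(wk_params("BA"), wf, dt = 0.01, n_cycles = 3)
#' tail(tr$P_mmHg, 1) # approaches 25.8 mmHg
#' @export
wk_simulate <- function(params, waveform, dt, n_cycles = 1, P0 = NULL) {
  wf <- as_waveform_fun(waveform)
  T <- attr(wf, "period")
  if (dt >= T) stop("dt must be smaller than the waveform period", call. = FALSE)
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  n <- ceiling(n_cycles * T / dt)
  tt <- seq(0, by = dt, length.out = n + 1)
  Q <- wf(tt)
  if (is.null(P0)) P0 <- wk_steady_pressure(params, mean(Q))
  P <- numeric(n + 1)
  P[1] <- P0
  st <- wk_state(P0, Q[1], 0)
  for (i in seq_len(n)) {
    st <- wk_step(params, st, Q[i + 1], dt)
    P[i + 1] <- st$P
  }
  structure(data.frame(t_s = tt, Q_ml_s = Q, P_mmHg = P),
            class = c("wk_trace", "data.frame"), params = params)
}

#' Export a Windkessel pressure trace as CSV
#'
#' @param trace a `wk_trace` from [wk_simulate()].
#' @param path output file path.
#' @export
write_wk_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Read or write Windkessel parameter sets as a YAML config block
#'
#' Parameter sets are stored keyed by outlet label, e.g.
#' `BA: {R1: 0.1, R2: 2.48, C: 0.466}`. `read_wk_config()` returns a named
#' list of [wk_params()].
#'
#' @param params_list named list of [wk_params()] objects.
#' @param path file path.
#' @export
write_wk_config <- function(params_list, path) {
  out <- lapply(params_list, function(p) list(R1 = p$R1, R2 = p$R2, C = p$C))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_wk_config
#' @export
read_wk_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    wk_params(nm, R1 = raw[[nm]]$R1, R2 = raw[[nm]]$R2, C = raw[[nm]]$C)
  })
  names(out) <- names(raw)
  out
}
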