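# Periodic volumetric inflow waveforms, the stand-in for echocardiographic
# velocity-time data at the aortic inlet.

#' Periodic inflow waveform
#'
#' Wraps a function `Q(t)` (ml/s) with a period so it can drive both the
#' Windkessel model and the flow solver. Evaluation wraps time modulo the
#' period.
#'
#' @param fun function of a numeric time vector (s) returning flow (ml/s),
#'   defined on one period `[0, period)`.
#' @param period cardiac period T, s.
#' @param stroke_volume optional known integral of Q over one period, ml.
#' @return An object of class `flow_waveform`; callable via [waveform_flow()].
#' @export
flow_waveform <- function(fun, period, stroke_volume = NULL) {
  stopifnot(is.function(fun), period > 0)
  if (is.null(stroke_volume)) {
    tt <- seq(0, period, length.out = 4001)
    q <- fun(tt %% period)
    stroke_volume <- sum((q[-1] + q[-length(q)]) / 2 * diff(tt))
  }
  structure(list(fun = fun, period = period, stroke_volume = stroke_volume),
            class = "flow_waveform")
}

#' Evaluate a waveform at arbitrary times
#'
#' @param wf a [flow_waveform()].
#' @param t numeric times, s (wrapped into the period).
#' @return Flow rates, ml/s.
#' @export
waveform_flow <- function(wf, t) wf$fun(t %% wf$period)

# Internal: coerce a waveform to an evaluation function carrying its period.
as_waveform_fun <- function(waveform) {
  if (inherits(waveform, "flow_waveform")) {
    f <- function(t) waveform$fun(t %% waveform$period)
    attr(f, "period") <- waveform$period
    return(f)
  }
  if (is.function(waveform) && !is.null(attr(waveform, "period"))) return(waveform)
  stop("waveform must be a flow_waveform or a function with a 'period' attribute",
       call. = FALSE)
}

#' Half-sine systolic inlet waveform
#'
#' Builds the pulsatile inflow used throughout the package: a half-sine
#' pulse during systole and zero flow in diastole,
#' `Q(t) = Q_peak * sin(pi * t / t_sys)` for `t < t_sys`, with
#' `t_sys = systolic_fraction * T` and `Q_peak = pi * SV / (2 * t_sys)` so
#' that the integral over one period equals the stroke volume.
#'
#' @param heart_rate heart rate, beats per minute.
#' @param stroke_volume stroke volume, ml.
#' @param systolic_fraction fraction of the cycle spent in systole,
#'   in (0, 1). Default 0.35.
#' @return A [flow_waveform()].
#' @examples
#' wf <- make_inlet_waveform(100, 30, 0.5) # t_sys = 0.3 s
#' max(waveform_flow(wf, seq(0, 0.6, 1e-4))) # ~157.08 ml/s
#' @export
make_inlet_waveform <- function(heart_rate, stroke_volume, systolic_fraction = 0.35) {
  if (heart_rate <= 0) stop("heart_rate must be positive", call. = FALSE)
  if (stroke_volume < 0) stop("stroke_volume must be non-negative", call. = FALSE)
  if (systolic_fraction <= 0 || systolic_fraction >= 1)
    stop("systolic_fraction must lie in (0, 1)", call. = FALSE)
  T <- 60 / heart_rate
  t_sys <- systolic_fraction * T
  Q_peak <- pi * stroke_volume / (2 * t_sys)
  fun <- function(t) ifelse(t < t_sys, Q_peak * sin(pi * t / t_sys), 0)
  wf <- flow_waveform(fun, period = T, stroke_volume = stroke_volume)
  wf$t_sys <- t_sys
  wf$Q_peak <- Q_peak
  wf
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("flow_waveform: period %.3f s, stroke volume %.2f ml%s\n",
              x$period, x$stroke_volume,
              if (!is.null(x$Q_peak)) sprintf(", peak %.1f ml/s", x$Q_peak) else ""))
  invisible(x)
}

#' Write / read an inflow waveform as a CSV time series
#'
#' The CSV has columns `t_s`, `Q_ml_s` sampled densely over one period;
#' reading back interpolates linearly and wraps periodically.
#'
#' @param wf a [flow_waveform()].
#' @param path file path.
#' @param n number of samples over one period.
#' @export
write_waveform <- function(wf, path, n = 200) {
  tt <- seq(0, wf$period, length.out = n + 1)
  write.csv(data.frame(t_s = tt, Q_ml_s = waveform_flow(wf, pmin(tt, wf$period - 1e-12))),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("t_s", "Q_ml_s") %in% names(d)))
  T <- max(d$t_s)
  fun <- function(t) approx(d$t_s, d$Q_ml_s, xout = t %% T, rule = 2)$y
  flow_waveform(fun, period = T)
}
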