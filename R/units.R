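#' Unit conversion constants and helpers
#'
#' The lumped-parameter (Windkessel) side of the pipeline works in clinical
#' units (mmHg, ml/s), matching how outlet parameters are tabulated; the
#' flow solver works in SI (Pa, m, s). Conversions use the fixed constant
#' 1 mmHg = 133.322 Pa and happen only at the coupling boundary.
#'
#' @param x numeric vector to convert.
#' @return Converted numeric vector.
#' @examples
#' mmhg_to_pa(100)     # 13332.2 Pa
#' pa_to_mmhg(133.322) # 1 mmHg
#' @name units
NULL

#: Pa per mmHg
MMHG_PA <- 133.322

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * MMHG_PA

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / MMHG_PA

#' @rdname units
#' @export
mls_to_m3s <- function(x) x * 1e-6

#' @rdname units
#' @export
m3s_to_mls <- function(x) x * 1e6
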