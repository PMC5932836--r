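# Method-agreement statistics: Bland-Altman analysis, correlation/linear
# fitting, and normality/variance-gated paired comparisons, as used to
# validate simulated hemodynamics against reference clinical measurements.

#' Bland-Altman agreement analysis
#'
#' Quantifies agreement between a reference method and a new method measured
#' on the same cases. Differences are defined as `new - ref`; the limits of
#' agreement are `bias +/- 1.96 * SD(differences)` with the sample (n-1)
#' standard deviation.
#'
#' @param ref reference-method values (e.g. catheter PSP), numeric.
#' @param new new-method values (e.g. CFD PSP), numeric, paired with `ref`.
#' @param conf multiplier for the limits of agreement (default 1.96).
#' @return An object of class `bland_altman`: `n`, `mean_ref`, `sd_ref`,
#'   `mean_new`, `sd_new`, `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `pearson_r`, `r_squared`, `slope`, `intercept`, `p_value`.
#' @examples
#' tab <- aorta_tables()$psv_psp
#' bland_altman(tab$psp_cc_mmHg, tab$psp_cfd_mmHg)
#' @export
bland_altman <- function(ref, new, conf = 1.96) {
  check_paired(ref, new)
  d <- new - ref
  bias <- mean(d)
  sd_diff <- sd(d)
  cf <- correlation_and_fit(ref, new)
  structure(list(
    n = length(ref),
    mean_ref = mean(ref), sd_ref = sd(ref),
    mean_new = mean(new), sd_new = sd(new),
    bias = bias, sd_diff = sd_diff,
    loa_low = bias - conf * sd_diff, loa_high = bias + conf * sd_diff,
    pearson_r = cf$pearson_r, r_squared = cf$pearson_r^2,
    slope = cf$slope, intercept = cf$intercept, p_value = cf$p_value,
    conf = conf, ref = ref, new = new
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  reference: %.2f +/- %.2f    new method: %.2f +/- %.2f\n",
              x$mean_ref, x$sd_ref, x$mean_new, x$sd_new))
  cat(sprintf("  bias (new - ref): %.3f   LoA: (%.3f, %.3f)\n",
              x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  Pearson r: %.3f (r^2 = %.3f, p = %.3g)   fit: new = %.3f * ref + %.3f\n",
              x$pearson_r, x$r_squared, x$p_value, x$slope, x$intercept))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of methods",
                              ylab = "difference (new - ref)", ...) {
  m <- (x$ref + x$new) / 2
  d <- x$new - x$ref
  plot(m, d, xlab = xlab, ylab = ylab,
       ylim = range(c(d, x$loa_low, x$loa_high)), ...)
  abline(h = x$bias, lty = 1)
  abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Pearson correlation and ordinary least-squares fit
#'
#' @inheritParams bland_altman
#' @return List with `pearson_r`, `slope`, `intercept` (OLS fit of `new` on
#'   `ref`) and the two-sided `p_value` for the correlation.
#' @export
correlation_and_fit <- function(ref, new) {
  check_paired(ref, new)
  if (sd(ref) == 0 || sd(new) == 0)
    stop("zero-variance input: correlation undefined", call. = FALSE)
  r <- cor(ref, new)
  fit <- lm(new ~ ref)
  p <- if (abs(r) >= 1) 0 else cor.test(ref, new)$p.value
  list(pearson_r = r, slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]), p_value = p)
}

#' Paired comparison with normality-gated test choice
#'
#' Tests whether two paired series differ. Normality of the paired
#' differences is assessed with the Kolmogorov-Smirnov test in its
#' estimated-parameter (Lilliefors-corrected) form; if normality is not
#' rejected at alpha the paired Student t test is used, otherwise the paired
#' Wilcoxon signed-rank test. Levene's test of variance homogeneity between
#' the two series is reported alongside.
#'
#' @param x,y paired numeric series, length >= 3.
#' @param alpha significance level for the normality gate (default 0.05).
#' @return An object of class `paired_test`: `method` (`"paired-t"` or
#'   `"wilcoxon"`), `statistic`, `p_value`, `normality_p`, `levene_p`,
#'   `degenerate` (TRUE when all differences are zero, in which case
#'   `p_value = 1`).
#' @export
paired_compare <- function(x, y, alpha = 0.05) {
  check_paired(x, y)
  d <- y - x
  if (all(d == 0)) {
    return(structure(list(method = "degenerate", statistic = NA_real_,
                          p_value = 1, normality_p = NA_real_,
                          levene_p = NA_real_, degenerate = TRUE),
                     class = "paired_test"))
  }
  lev <- tryCatch({
    g <- factor(rep(c("x", "y"), each = length(x)))
    car::leveneTest(c(x, y) ~ g)[["Pr(>F)"]][1]
  }, error = function(e) NA_real_)
  norm_p <- tryCatch(nortest::lillie.test(d)$p.value, error = function(e) NA_real_)
  if (!is.na(norm_p) && norm_p >= alpha) {
    tt <- t.test(y, x, paired = TRUE)
    res <- list(method = "paired-t", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(y, x, paired = TRUE))
    res <- list(method = "wilcoxon", statistic = unname(wt$statistic),
                p_value = wt$p.value)
  }
  structure(c(res, list(normality_p = norm_p, levene_p = lev,
                        degenerate = FALSE)),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  if (x$degenerate) {
    cat("paired comparison: identical series (p = 1)\n")
  } else {
    cat(sprintf("paired %s test: statistic = %.4g, p = %.4g\n",
                x$method, x$statistic, x$p_value))
    cat(sprintf("  normality (Lilliefors KS) p = %.3g; Levene p = %.3g\n",
                x$normality_p, x$levene_p))
  }
  invisible(x)
}

#' Cohort summary table (mean +/- SD per column)
#'
#' @param records data frame of per-case measurements; all numeric columns
#'   are summarized with the sample (n-1) SD. With a single record the SD is
#'   reported as `NA`.
#' @return Data frame with columns `variable`, `mean`, `sd`, `formatted`
#'   (mean +/- SD to 2 decimals).
#' @export
summarize_cohort <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  num <- vapply(records, is.numeric, logical(1))
  cols <- names(records)[num]
  m <- vapply(records[cols], mean, numeric(1))
  s <- if (nrow(records) > 1) vapply(records[cols], sd, numeric(1))
       else rep(NA_real_, length(cols))
  data.frame(variable = cols, mean = unname(m), sd = unname(s),
             formatted = sprintf("%.2f +/- %.2f", m, s),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Packaged reference measurement tables
#'
#' Returns the transcribed per-case reference tables of a 25-infant CHD
#' cohort used to exercise the validation statistics: cross-sectional
#' diameters of the reconstructed versus measured aorta at the ascending
#' aorta (AscAo), aortic isthmus (AI) and descending aorta (DAo), and peak
#' systolic velocity (TTE vs CFD) and peak systolic pressure (catheter vs
#' CFD) per case.
#'
#' @return List with elements `diameters` (columns `case`, `location`,
#'   `reconstructed_mm`, `measured_mm`) and `psv_psp` (columns `case`,
#'   `psv_tte_cm_s`, `psv_cfd_cm_s`, `psp_cc_mmHg`, `psp_cfd_mmHg`).
#' @export
aorta_tables <- function() {
  d <- read.csv(system.file("extdata", "table2_diameters.csv",
                            package = "aortohemo"), comment.char = "#")
  p <- read.csv(system.file("extdata", "table3_psv_psp.csv",
                            package = "aortohemo"), comment.char = "#")
  list(diameters = d, psv_psp = p)
}

check_paired <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y))
    stop("inputs must be numeric", call. = FALSE)
  if (length(x) != length(y))
    stop("paired series must have equal length", call. = FALSE)
  if (length(x) < 3)
    stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values not allowed", call. = FALSE)
  invisible(TRUE)
}
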