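#' Compare two measurement groups
#'
#' The study's testing scheme: a two-sided homoscedastic (pooled-variance)
#' t-test at alpha = 0.05 (paired where the design is paired), with a Welch
#' variant reported as a robustness check, variance homogeneity screened by an
#' F-test (two groups) and per-group normality screened by a
#' Kolmogorov-Smirnov test at alpha = 0.01. The screens are reported, not used
#' to switch the primary test automatically.
#'
#' Percent change is `(mean(a) - mean(b)) / mean(b) * 100`, i.e. group `b` is
#' the control.
#'
#' @param a test-group replicates
#' @param b control-group replicates
#' @param paired logical; paired-sample t-test (groups must be equal length)
#' @return object of class `group_comparison`: `percent_change`,
#'   `t_statistic`, `p_value` (primary), `p_welch`, `variance_test_p`,
#'   `normality_p_a`, `normality_p_b`, `test_variant`
#' @export
compare_groups <- function(a, b, paired = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal group sizes")
  if (abs(mean(b)) < .Machine$double.eps)
    stop("control mean is zero; percent change undefined")
  pct <- (mean(a) - mean(b)) / mean(b) * 100
  primary <- t.test(a, b, paired = paired, var.equal = !paired)
  welch <- if (paired) NULL else t.test(a, b, var.equal = FALSE)
  vt <- if (paired) NA_real_ else var.test(a, b)$p.value
  ks_p <- function(x) {
    if (sd(x) == 0) return(NA_real_)
    suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
  }
  structure(list(
    group_a = a, group_b = b, paired = paired,
    percent_change = pct,
    t_statistic = unname(primary$statistic),
    p_value = primary$p.value,
    p_welch = if (is.null(welch)) NA_real_ else welch$p.value,
    variance_test_p = vt,
    normality_p_a = ks_p(a),
    normality_p_b = ks_p(b),
    test_variant = if (paired) "paired" else "homoscedastic"
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s t-test: %+.2f%% change, t = %.3f, p = %.4g\n",
              x$test_variant, x$percent_change, x$t_statistic, x$p_value))
  if (!is.na(x$p_welch)) cat(sprintf("  Welch p = %.4g\n", x$p_welch))
  if (!is.na(x$variance_test_p))
    cat(sprintf("  variance F-test p = %.4g; KS normality p = %.4g / %.4g\n",
                x$variance_test_p, x$normality_p_a, x$normality_p_b))
  invisible(x)
}

#' Ellipsoid-approximation tumour volume from calliper axes
#'
#' `volume = 0.52 * short_axis^2 * long_axis` (mm^3).
#'
#' @param short_axis,long_axis calliper measurements, mm
#' @return volume in mm^3
#' @export
tumor_volume <- function(short_axis, long_axis) {
  if (any(short_axis < 0) || any(long_axis < 0))
    stop("axes must be non-negative")
  0.52 * short_axis^2 * long_axis
}
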