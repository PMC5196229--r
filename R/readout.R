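#' Pulsed-gradient scheme
#'
#' Describes a single-axis pulsed-gradient (stimulated-echo) diffusion
#' weighting: gradient duration `delta`, gradient interval `Delta`, strength
#' `g`, gyromagnetic ratio `gamma`. Derived quantities: `q = (gamma delta g)^2`,
#' `b = q * (Delta - delta/3)` and the effective diffusion time
#' `Delta_eff = Delta - delta/3`.
#'
#' Either `g` (mT m^-1, possibly a vector) or `b_values` (s mm^-2) may be
#' given; when both are present they must agree.
#'
#' @param Delta gradient interval, ms
#' @param delta gradient duration, ms (default 7)
#' @param g gradient strength(s), mT m^-1
#' @param b_values b-value(s), s mm^-2
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1 (default 2.675e8 for 1H)
#' @param axis unit gradient direction (default x)
#' @return object of class `gradient_scheme`
#' @export
gradient_scheme <- function(Delta, delta = 7, g = NULL, b_values = NULL,
                            gamma = GAMMA_1H, axis = c(1, 0, 0)) {
  stopifnot(Delta > delta, delta > 0, gamma > 0)
  axis <- axis / sqrt(sum(axis^2))
  if (is.null(g) && is.null(b_values))
    stop("supply gradient strengths g or b_values")
  if (!is.null(g)) {
    stopifnot(all(g >= 0))
    b_from_g <- b_value_from_g(g, delta, Delta, gamma)
    if (!is.null(b_values) && any(abs(b_from_g - b_values) > 1e-6 * pmax(1, b_values)))
      stop("supplied g and b_values disagree")
    b_values <- b_from_g
  } else {
    stopifnot(all(b_values >= 0))
    g <- g_from_b_value(b_values, delta, Delta, gamma)
  }
  structure(list(gamma = gamma, delta = delta, Delta = Delta, g = g,
                 b_values = b_values,
                 Delta_eff = effective_diffusion_time(Delta, delta),
                 axis = axis),
            class = "gradient_scheme")
}

#' Effective diffusion time
#'
#' `Delta_eff = Delta - delta/3`, the time over which spin displacements are
#' probed by a pulsed-gradient pair.
#'
#' @param Delta gradient interval, ms
#' @param delta gradient duration, ms
#' @return Delta_eff in ms (exact; see [display_diffusion_time()] for the
#'   rounded value used in figure labels)
#' @export
effective_diffusion_time <- function(Delta, delta) {
  out <- Delta - delta / 3
  if (any(out <= 0)) stop("Delta - delta/3 must be positive")
  out
}

#' @rdname effective_diffusion_time
#' @export
display_diffusion_time <- function(Delta, delta) {
  round(effective_diffusion_time(Delta, delta))
}

#' b-value of a pulsed-gradient scheme
#'
#' `b = (gamma delta g)^2 (Delta - delta/3)`, returned in s mm^-2.
#'
#' @param scheme a `gradient_scheme`
#' @return b-value(s) in s mm^-2
#' @export
b_value <- function(scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  scheme$b_values
}

# g in mT/m, delta/Delta in ms, gamma in rad s^-1 T^-1 -> b in s mm^-2
b_value_from_g <- function(g, delta, Delta, gamma = GAMMA_1H) {
  k <- gamma * (delta / 1000) * (g / 1000)     # rad m^-1
  k^2 * (effective_diffusion_time(Delta, delta) / 1000) * 1e-6
}

# invert b (s mm^-2) to g (mT/m)
g_from_b_value <- function(b, delta, Delta, gamma = GAMMA_1H) {
  k <- sqrt(b * 1e6 / (effective_diffusion_time(Delta, delta) / 1000)) # rad m^-1
  k / (gamma * (delta / 1000)) * 1000
}

#' ADC from walker displacements
#'
#' Primary estimator: the narrow-pulse signal attenuation
#' `E(b) = <cos(gamma delta g x)>` over walkers, with the ADC taken from the
#' slope of `ln E` versus `b` (or `-ln E / b` for a single non-zero b).
#' Secondary estimator: the mean square displacement along the gradient axis,
#' `ADC = <x^2> / (2 Delta_eff)`. Both are reported, with their discrepancy,
#' in the returned `adc_result`.
#'
#' A third readout, `adc_msd3d = <sum of squared displacement over all three
#' axes> / (2 Delta_eff)`, is reported when full 3-D displacements are given.
#' For isotropic diffusion it equals 3x the per-axis ADC; it is the
#' sum-square-displacement convention needed to reproduce the published
#' permeability calibration curve (see the methods vignette), not a physical
#' single-axis ADC.
#'
#' @param displacements per-walker displacement: either an n x 3 matrix (um),
#'   projected onto `scheme$axis`, or a numeric vector already along the axis
#' @param scheme a `gradient_scheme`; its `b_values` define the attenuation
#'   samples and its `Delta_eff` the displacement window
#' @param n_boot bootstrap resamples for the standard error (default 100)
#' @return object of class `adc_result`: `adc` (um^2 s^-1, attenuation
#'   estimator), `adc_msd`, `adc_msd3d` (NA for vector input),
#'   `intercept_S0`, `r_squared`, `standard_error` (per estimator, named),
#'   `discrepancy`
#' @export
adc_from_trajectories <- function(displacements, scheme, n_boot = 100) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  r2_3d <- NULL
  if (is.matrix(displacements)) {
    x <- drop(displacements %*% scheme$axis)
    r2_3d <- rowSums(displacements^2)
  } else {
    x <- as.numeric(displacements)
  }
  if (length(x) < 100) stop("need at least 100 walkers for a stable estimate")
  b <- scheme$b_values
  if (length(unique(b)) < 1) stop("scheme carries no b-values")
  # phase per unit displacement: gamma*delta*g = sqrt(b / Delta_eff) in SI
  k <- sqrt(b * 1e6 / (scheme$Delta_eff / 1000)) * 1e-6  # rad um^-1
  C <- outer(x, k, function(xx, kk) cos(kk * xx))
  E <- colMeans(C)
  if (any(E <= 0))
    stop("non-positive echo attenuation; reduce the gradient strength or add walkers")
  adc_ms <- attenuation_slope(b, E)                      # um^2 ms^-1
  adc_msd_ms <- mean(x^2) / (2 * scheme$Delta_eff)
  n <- length(x)
  se_msd <- sd(x^2) / sqrt(n) / (2 * scheme$Delta_eff) * 1000
  adc_msd3d_ms <- if (is.null(r2_3d)) NA_real_ else mean(r2_3d) / (2 * scheme$Delta_eff)
  se_msd3d <- if (is.null(r2_3d)) NA_real_ else
    sd(r2_3d) / sqrt(n) / (2 * scheme$Delta_eff) * 1000
  # walker-level bootstrap for the attenuation estimator
  se <- NA_real_
  if (n_boot > 0) {
    boots <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      Eb <- colMeans(C[idx, , drop = FALSE])
      if (any(Eb <= 0)) NA_real_ else attenuation_slope(b, Eb)
    })
    se <- sd(boots, na.rm = TRUE) * 1000
  }
  lnE <- log(E)
  r2 <- if (length(b) > 2) {
    fit <- lm(lnE ~ b)
    summary(fit)$r.squared
  } else 1
  structure(list(
    adc = adc_um2ms_to_um2s(adc_ms),
    adc_msd = adc_um2ms_to_um2s(adc_msd_ms),
    adc_msd3d = adc_um2ms_to_um2s(adc_msd3d_ms),
    intercept_S0 = 1,
    r_squared = r2,
    standard_error = se,
    standard_error_msd = se_msd,
    standard_error_msd3d = se_msd3d,
    discrepancy = adc_um2ms_to_um2s(adc_ms - adc_msd_ms),
    n_walkers = n
  ), class = "adc_result")
}

# slope of -ln E vs b, returned in um^2 ms^-1 (b in s mm^-2)
attenuation_slope <- function(b, E) {
  lnE <- log(E)
  slope <- if (length(b) == 1) {
    if (b[1] <= 0) stop("single b-value must be positive")
    lnE[1] / b[1]
  } else {
    unname(coef(lm(lnE ~ b))[2])
  }
  -slope * 1000 # mm^2 s^-1 -> um^2 ms^-1 (1e6 um^2/mm^2 / 1e3 ms/s ... )
}

#' A multi-b signal decay curve
#'
#' @param b_values b-values, s mm^-2
#' @param signals signal intensities (> 0 for log-domain fitting)
#' @param noise_sd optional known noise level
#' @return object of class `decay_curve`
#' @export
decay_curve <- function(b_values, signals, noise_sd = NULL) {
  stopifnot(length(b_values) == length(signals))
  structure(list(b_values = b_values, signals = signals, noise_sd = noise_sd),
            class = "decay_curve")
}

#' ADC from a measured signal decay
#'
#' Ordinary least squares of `ln S` on `b`; the ADC is minus the slope,
#' converted to um^2 s^-1. Invariant to rescaling all signals by a constant.
#'
#' @param curve a `decay_curve`
#' @param weighted logical; weight points by squared signal (approximate
#'   maximum likelihood under additive noise). Default FALSE, the plain slope
#'   of the logarithmic decay.
#' @return an `adc_result` with `adc`, `intercept_S0`, `r_squared`,
#'   `standard_error`
#' @export
adc_from_decay <- function(curve, weighted = FALSE) {
  stopifnot(inherits(curve, "decay_curve"))
  b <- curve$b_values
  S <- curve$signals
  if (length(unique(b)) < 2) stop("need at least 2 distinct b-values")
  if (any(S <= 0)) stop("signals must be positive for log-domain fitting")
  fit <- if (weighted) lm(log(S) ~ b, weights = S^2) else lm(log(S) ~ b)
  sm <- summary(fit)
  slope <- unname(coef(fit)[2])       # per (s mm^-2) -> mm^2 s^-1
  structure(list(
    adc = -slope * 1e6,               # um^2 s^-1
    adc_msd = NA_real_,
    intercept_S0 = exp(unname(coef(fit)[1])),
    r_squared = sm$r.squared,
    standard_error = sm$coefficients[2, 2] * 1e6,
    discrepancy = NA_real_,
    n_points = length(b)
  ), class = "adc_result")
}

#' @export
print.adc_result <- function(x, ...) {
  cat("ADC:", signif(x$adc, 6), "um^2/s")
  if (!is.na(x$standard_error)) cat(" (SE", signif(x$standard_error, 3), ")")
  if (!is.null(x$adc_msd) && !is.na(x$adc_msd))
    cat("; MSD estimator:", signif(x$adc_msd, 6))
  cat("\n")
  invisible(x)
}

#' Read/write decay curves as CSV
#'
#' Columns `b_s_per_mm2`, `signal`.
#' @param curve a `decay_curve`
#' @param path file path
#' @export
write_decay_csv <- function(curve, path) {
  utils::write.csv(data.frame(b_s_per_mm2 = curve$b_values,
                              signal = curve$signals),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decay_csv
#' @export
read_decay_csv <- function(path) {
  d <- utils::read.csv(path)
  decay_curve(d$b_s_per_mm2, d$signal)
}
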