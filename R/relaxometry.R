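#' A relaxation measurement series
#'
#' @param kind `"T1_RECOVERY"` (variable-TR saturation recovery) or
#'   `"T2_ECHO_TRAIN"` (multi-echo decay, times are `n * TE`)
#' @param times TR values or echo times, ms, strictly increasing
#' @param signals signal intensities
#' @return object of class `relaxation_series`
#' @export
relaxation_series <- function(kind = c("T1_RECOVERY", "T2_ECHO_TRAIN"),
                              times, signals) {
  kind <- match.arg(kind)
  stopifnot(length(times) == length(signals), all(diff(times) > 0))
  structure(list(kind = kind, times = times, signals = signals),
            class = "relaxation_series")
}

#' The variable-TR grid used for the pellet T1 measurements
#' @return TR values in ms
#' @export
default_tr_grid <- function() {
  c(146.19, 321.47, 519.98, 748.83, 1018.9, 1348.72, 1771.99,
    2363.81, 3355.44, 7500)
}

#' Fit a T1 saturation-recovery series
#'
#' Nonlinear least squares of `S = S0 * (1 - exp(-TR/T1))` (saturation
#' recovery, the model underlying a variable-TR acquisition). An
#' inversion-recovery variant `S = S0 * (1 - 2 exp(-TR/T1))` is available.
#'
#' @param series a `relaxation_series` of kind `T1_RECOVERY`
#' @param model `"saturation"` (default) or `"inversion"`
#' @return list with `T1` (ms), `S0`, `residual_sd`
#' @export
fit_t1 <- function(series, model = c("saturation", "inversion")) {
  stopifnot(inherits(series, "relaxation_series"),
            series$kind == "T1_RECOVERY", length(series$times) >= 3)
  model <- match.arg(model)
  tr <- series$times
  S <- series$signals
  if (sd(S) < 1e-12 * max(abs(S), 1))
    stop("signals are constant; T1 is unidentifiable")
  fac <- if (model == "saturation") 1 else 2
  S0_start <- max(S)
  # log-linearised start: 1 - S/S0 = fac * exp(-TR/T1)
  frac <- pmax(1 - S / (S0_start * 1.05), 1e-6)
  T1_start <- -1 / unname(coef(lm(log(frac) ~ tr))[2])
  if (!is.finite(T1_start) || T1_start <= 0) T1_start <- stats::median(tr)
  fit <- minpack.lm::nlsLM(S ~ S0 * (1 - fac * exp(-tr / T1)),
                           start = list(S0 = S0_start, T1 = T1_start),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  if (est["T1"] <= 0 || est["S0"] <= 0)
    stop("T1 fit did not converge to positive parameters; residual sd ",
         signif(sd(stats::residuals(fit)), 4))
  list(T1 = unname(est["T1"]), S0 = unname(est["S0"]),
       residual_sd = sd(stats::residuals(fit)))
}

#' Fit a T2 echo-train decay
#'
#' Fits `S = S0 * exp(-t/T2)` to the first `n_echoes_used` echoes
#' (log-linear least squares by default; late echoes are excluded to avoid
#' noise-floor and slow-component bias).
#'
#' @param series a `relaxation_series` of kind `T2_ECHO_TRAIN`
#' @param n_echoes_used number of leading echoes fitted (default 19)
#' @param method `"loglinear"` (default) or `"nls"`
#' @return list with `T2` (ms), `S0`, `residual_sd`
#' @export
fit_t2 <- function(series, n_echoes_used = 19,
                   method = c("loglinear", "nls")) {
  stopifnot(inherits(series, "relaxation_series"),
            series$kind == "T2_ECHO_TRAIN", length(series$times) >= 2,
            n_echoes_used >= 2)
  method <- match.arg(method)
  n <- min(n_echoes_used, length(series$times))
  t <- series$times[seq_len(n)]
  S <- series$signals[seq_len(n)]
  if (any(S <= 0))
    stop("non-positive signals within the fitted echo window")
  if (method == "loglinear") {
    fit <- lm(log(S) ~ t)
    T2 <- -1 / unname(coef(fit)[2])
    S0 <- exp(unname(coef(fit)[1]))
    rsd <- sd(S - S0 * exp(-t / T2))
  } else {
    start <- list(S0 = max(S), T2 = max(t) / 2)
    fit <- minpack.lm::nlsLM(S ~ S0 * exp(-t / T2), start = start)
    est <- coef(fit)
    T2 <- unname(est["T2"]); S0 <- unname(est["S0"])
    rsd <- sd(stats::residuals(fit))
  }
  if (!is.finite(T2) || T2 <= 0) stop("T2 fit returned a non-positive rate")
  list(T2 = T2, S0 = S0, residual_sd = rsd)
}
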