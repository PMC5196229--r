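#' MRI magnitude noise model
#'
#' Gaussian (high-SNR limit) or Rician (magnitude reconstruction at low SNR;
#' strictly positive output).
#'
#' @param kind `"GAUSSIAN"` or `"RICIAN"`
#' @param sigma noise standard deviation in signal units
#' @return object of class `noise_model`
#' @export
noise_model <- function(kind = c("GAUSSIAN", "RICIAN"), sigma = 0) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("sigma must be non-negative")
  structure(list(kind = kind, sigma = sigma), class = "noise_model")
}

apply_noise <- function(signal, noise) {
  if (noise$sigma == 0) return(signal)
  n <- length(signal)
  if (noise$kind == "GAUSSIAN") {
    signal + rnorm(n, 0, noise$sigma)
  } else {
    sqrt((signal + rnorm(n, 0, noise$sigma))^2 + rnorm(n, 0, noise$sigma)^2)
  }
}

#' Generate a mono-exponential diffusion decay curve
#'
#' `S(b) = S0 * exp(-b * adc_true)` plus noise; the exact forward model of
#' [adc_from_decay()].
#'
#' @param adc_true ADC, um^2 s^-1
#' @param S0 unattenuated signal
#' @param b_values b-values, s mm^-2
#' @param noise a [noise_model()]
#' @param seed integer RNG seed
#' @return a `decay_curve`
#' @export
gen_decay_curve <- function(adc_true, S0 = 100,
                            b_values = seq(0, 800, by = 100),
                            noise = noise_model("GAUSSIAN", 0),
                            seed = 1L) {
  stopifnot(adc_true > 0, S0 > 0)
  set.seed(seed)
  S <- S0 * exp(-b_values * adc_true * 1e-6) # b s/mm^2 * ADC mm^2/s * 1e-6
  decay_curve(b_values, apply_noise(S, noise), noise_sd = noise$sigma)
}

#' Generate a relaxation series
#'
#' Forward models matching [fit_t1()] (saturation recovery) and [fit_t2()]
#' (mono-exponential echo decay).
#'
#' @param kind `"T1_RECOVERY"` or `"T2_ECHO_TRAIN"`
#' @param true_value T1 or T2, ms
#' @param S0 equilibrium signal
#' @param times TR grid (T1) or echo times (T2), ms; defaults: the package TR
#'   grid, or 63 echoes spaced 11 ms
#' @param noise a [noise_model()]
#' @param seed integer RNG seed
#' @return a `relaxation_series`
#' @export
gen_relaxation_series <- function(kind = c("T1_RECOVERY", "T2_ECHO_TRAIN"),
                                  true_value, S0 = 100, times = NULL,
                                  noise = noise_model("GAUSSIAN", 0),
                                  seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(true_value > 0, S0 > 0)
  if (is.null(times))
    times <- if (kind == "T1_RECOVERY") default_tr_grid() else 11 * seq_len(63)
  set.seed(seed)
  S <- if (kind == "T1_RECOVERY") S0 * (1 - exp(-times / true_value))
       else S0 * exp(-times / true_value)
  relaxation_series(kind, times, apply_noise(S, noise))
}

#' Configuration for a synthetic replicate group study
#'
#' Emulates the pellet replicate structure: each condition's true ADC is the
#' control ADC scaled by a percent change, and replicates vary
#' multiplicatively with a coefficient of variation. The default CV (0.0552)
#' makes the synthetic control group's standard deviation match the measured
#' control spread (20.86 about 377.57 um^2 s^-1).
#'
#' @param control_adc control-condition ADC, um^2 s^-1 (default 377.57)
#' @param percent_changes named or unnamed vector of per-condition percent
#'   changes relative to control
#' @param n_replicates replicates per group (default 4)
#' @param cv multiplicative coefficient of variation (default 20.86/377.57)
#' @param b_values b-value grid for per-replicate decay curves
#' @param seed integer RNG seed
#' @return list of class `synthetic_study_config`
#' @export
synthetic_study_config <- function(control_adc = 377.57,
                                   percent_changes = c(dox_0.01 = 54, dox_1 = 187),
                                   n_replicates = 4,
                                   cv = 20.86 / 377.57,
                                   b_values = seq(0, 800, by = 100),
                                   seed = 1L) {
  stopifnot(control_adc > 0, n_replicates >= 2, cv >= 0)
  structure(list(control_adc = control_adc, percent_changes = percent_changes,
                 n_replicates = n_replicates, cv = cv, b_values = b_values,
                 seed = seed),
            class = "synthetic_study_config")
}

#' Generate replicate ADC tables for a synthetic group study
#'
#' Per condition, draws `n_replicates` ADC values
#' `control_adc * (1 + pct/100) * (1 + N(0, cv))`. A control condition
#' (percent change 0) is always included.
#'
#' @param config a [synthetic_study_config()]
#' @return data frame with columns `condition`, `replicate`, `adc`
#' @export
gen_group_study <- function(config) {
  stopifnot(inherits(config, "synthetic_study_config"))
  if (config$n_replicates < 2)
    stop("need at least 2 replicates per group")
  set.seed(config$seed)
  pct <- c(control = 0, config$percent_changes)
  if (is.null(names(config$percent_changes)))
    names(pct) <- c("control", paste0("condition_", seq_along(config$percent_changes)))
  rows <- lapply(names(pct), function(cond) {
    mu <- config$control_adc * (1 + pct[[cond]] / 100)
    data.frame(condition = cond,
               replicate = seq_len(config$n_replicates),
               adc = mu * (1 + rnorm(config$n_replicates, 0, config$cv)))
  })
  do.call(rbind, rows)
}
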