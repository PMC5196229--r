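#' Simulated ADC as a function of membrane permeability
#'
#' For each permeability value a fresh uniformly-labelled lattice is built,
#' walkers are propagated over the effective diffusion time of the scheme, and
#' the ADC is estimated from the displacement ensemble. Monte Carlo standard
#' errors come from walker-level bootstrap resampling.
#'
#' @param P_values membrane permeabilities, um ms^-1
#' @param Delta_values gradient intervals Delta, ms (one sweep per value)
#' @param lattice_config list of arguments for [build_fcc_lattice()]
#' @param sim_config list of arguments for [sim_params()] (`n_walkers`, `tau`,
#'   diffusivities, ...)
#' @param scheme_config list of arguments for [gradient_scheme()] other than
#'   `Delta` (default: `delta = 7`, b-values 0-800 s mm^-2)
#' @param seed integer master seed; per-condition seeds are derived from it
#' @return a `sweep_table` data frame: `axis` (P), `Delta_eff`, `adc`,
#'   `adc_se`, `adc_msd`, `n_walkers`, `seed`
#' @export
permeability_sweep <- function(P_values, Delta_values,
                               lattice_config = list(),
                               sim_config = list(),
                               scheme_config = list(),
                               seed = 1L) {
  stopifnot(all(P_values >= 0), all(Delta_values > 0))
  rows <- list()
  i <- 0L
  for (Delta in Delta_values) {
    scheme <- do.call(gradient_scheme, c(list(Delta = Delta),
                                         default_scheme_args(scheme_config)))
    for (P in P_values) {
      i <- i + 1L
      cond_seed <- derive_seed(seed, i)
      lat <- do.call(build_fcc_lattice,
                     c(lattice_config, list(seed = cond_seed)))
      params <- do.call(sim_params,
                        c(sim_config,
                          list(permeability_by_label = c(LOW_PERM = P, HIGH_PERM = P))))
      res <- simulate_adc(lat, params, scheme, seed = cond_seed + 1L)
      rows[[i]] <- data.frame(axis = P, Delta_eff = scheme$Delta_eff,
                              adc = res$adc, adc_se = res$standard_error,
                              adc_msd = res$adc_msd,
                              n_walkers = params$n_walkers, seed = cond_seed)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  attr(out, "axis_kind") <- "permeability"
  out
}

#' Simulated ADC as a function of the high-permeability cell fraction
#'
#' Models mixed populations: a fraction of cells carries the high (water
#' channel) permeability, the rest the control value. For each fraction the
#' ADC is averaged over `n_arrangements` random label arrangements to remove
#' geometry/arrangement bias.
#'
#' @param fractions fractions of high-permeability cells, in \[0, 1\]
#' @param P_high,P_low permeabilities of labelled and control cells, um ms^-1
#'   (defaults 0.14 and 0.039)
#' @param n_arrangements random arrangements per fraction (default 100)
#' @param Delta gradient interval, ms
#' @inheritParams permeability_sweep
#' @return a `sweep_table`: `axis` (fraction), `Delta_eff`, `adc` (mean over
#'   arrangements), `adc_se` (standard error of that mean: arrangement
#'   variance plus walker noise), `adc_sd_arrangements`, `n_walkers`, `seed`
#' @export
fraction_sweep <- function(fractions, P_high = 0.14, P_low = 0.039,
                           n_arrangements = 100, Delta = 400,
                           lattice_config = list(),
                           sim_config = list(),
                           scheme_config = list(),
                           seed = 1L) {
  stopifnot(all(fractions >= 0 & fractions <= 1), n_arrangements >= 1)
  scheme <- do.call(gradient_scheme, c(list(Delta = Delta),
                                       default_scheme_args(scheme_config)))
  rows <- list()
  i <- 0L
  for (f in fractions) {
    adcs <- ses <- numeric(n_arrangements)
    for (k in seq_len(n_arrangements)) {
      i <- i + 1L
      cond_seed <- derive_seed(seed, i)
      lat <- do.call(build_fcc_lattice, c(lattice_config, list(seed = cond_seed)))
      lat <- assign_labels(lat, f, seed = cond_seed + 1L)
      params <- do.call(sim_params,
                        c(sim_config,
                          list(permeability_by_label = c(LOW_PERM = P_low,
                                                         HIGH_PERM = P_high))))
      res <- simulate_adc(lat, params, scheme, seed = cond_seed + 2L)
      adcs[k] <- res$adc
      ses[k] <- res$standard_error
    }
    se_mean <- sqrt((if (n_arrangements > 1) var(adcs) / n_arrangements else 0) +
                      mean(ses^2) / n_arrangements)
    rows[[f_key <- length(rows) + 1]] <- data.frame(
      axis = f, Delta_eff = scheme$Delta_eff,
      adc = mean(adcs), adc_se = se_mean,
      adc_sd_arrangements = if (n_arrangements > 1) sd(adcs) else NA_real_,
      n_arrangements = n_arrangements,
      n_walkers = params$n_walkers, seed = seed)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  attr(out, "axis_kind") <- "fraction"
  out
}

#' Simulate one ADC value for a lattice/parameter/scheme combination
#'
#' Initialises walkers uniformly, propagates them over the scheme's effective
#' diffusion time and applies [adc_from_trajectories()].
#'
#' @param lattice a `cell_lattice`
#' @param params a `sim_params`
#' @param scheme a `gradient_scheme`
#' @param seed integer RNG seed
#' @return an `adc_result`
#' @export
simulate_adc <- function(lattice, params, scheme, seed = 1L) {
  n_steps <- round(scheme$Delta_eff / (params$tau / 1000))
  ens <- init_walkers(lattice, params$n_walkers, seed = seed)
  ens <- propagate(ens, lattice, params, n_steps)
  adc_from_trajectories(ens$displacement, scheme)
}

#' Invert a measured ADC to membrane permeability
#'
#' Monotone piecewise-linear interpolation of the simulated permeability to
#' ADC curve, evaluated in reverse. Monte Carlo noise is smoothed by isotonic
#' regression before inversion; measured values outside the simulated ADC
#' range raise an error reporting the bracketing values rather than
#' extrapolating.
#'
#' @param adc_measured measured ADC, um^2 s^-1
#' @param sweep a `sweep_table` from [permeability_sweep()]
#' @param Delta_eff effective diffusion time of the measurement, ms (must be
#'   present in the sweep; default 398)
#' @param out_of_range `"error"` (default): refuse to extrapolate when the
#'   measured ADC lies outside the simulated range; `"clamp"`: return the
#'   grid-endpoint permeability with a warning, flagging that the estimate is
#'   a bound, not an interpolated value
#' @return permeability in um ms^-1
#' @export
invert_adc_to_permeability <- function(adc_measured, sweep,
                                       Delta_eff = 398,
                                       out_of_range = c("error", "clamp")) {
  out_of_range <- match.arg(out_of_range)
  stopifnot(inherits(sweep, "sweep_table"))
  sub <- sweep[abs(sweep$Delta_eff - Delta_eff) < 0.5, ]
  if (nrow(sub) < 2)
    stop("sweep does not cover the requested Delta_eff")
  sub <- sub[order(sub$axis), ]
  adc_mono <- isoreg(sub$axis, sub$adc)$yf  # enforce monotone non-decreasing
  out <- vapply(adc_measured, function(a) {
    if (a < min(adc_mono) || a > max(adc_mono)) {
      msg <- sprintf(
        "measured ADC %.4g outside simulated range [%.4g, %.4g]",
        a, min(adc_mono), max(adc_mono))
      if (out_of_range == "error") stop(msg, "; extend the sweep")
      warning(msg, "; returning the grid-endpoint permeability (a bound)")
      return(if (a < min(adc_mono)) sub$axis[1] else sub$axis[nrow(sub)])
    }
    approx(adc_mono, sub$axis, xout = a, ties = "ordered")$y
  }, numeric(1))
  out
}

#' Convert membrane permeability to channel expression
#'
#' Volumetric water flow per cell is `P * surface_area`; dividing by the unit
#' channel water conductance gives the channel count per cell, and dividing by
#' cell volume (times Avogadro's number and an optional multimer factor) gives
#' the membrane protein concentration in uM.
#'
#' @param P membrane permeability, um ms^-1
#' @param surface_area cell surface area, um^2 (default 380, CHO cell)
#' @param unit_conductance single-channel water conductance, um^3 ms^-1
#'   (default 6e-5)
#' @param cell_volume cell volume, um^3; default 697, the volume of the sphere
#'   whose surface area is 380 um^2. The volume of a 6.8-um-radius sphere
#'   (1317 um^3) is a documented alternative.
#' @param multimer_factor channels per counted unit (default 1, i.e. the
#'   conductance is per monomer)
#' @return object of class `expression_estimate`: `permeability`,
#'   `volumetric_flow` (um^3 ms^-1), `channels_per_cell`, `concentration_uM`,
#'   `assumptions`
#' @export
permeability_to_concentration <- function(P, surface_area = 380,
                                          unit_conductance = 6e-5,
                                          cell_volume = 697,
                                          multimer_factor = 1) {
  stopifnot(surface_area > 0, unit_conductance > 0, cell_volume > 0,
            multimer_factor > 0, all(P >= 0))
  flow <- P * surface_area                   # um^3 ms^-1
  channels <- flow / unit_conductance
  vol_l <- cell_volume * 1e-15               # um^3 -> litres
  conc_uM <- channels / (multimer_factor * AVOGADRO * vol_l) * 1e6
  structure(list(
    permeability = P,
    volumetric_flow = flow,
    channels_per_cell = channels,
    concentration_uM = conc_uM,
    assumptions = list(surface_area = surface_area,
                       unit_conductance = unit_conductance,
                       cell_volume = cell_volume,
                       multimer_factor = multimer_factor)
  ), class = "expression_estimate")
}

#' Extrapolate expression at a lower induction dose
#'
#' When expression at a low induction dose is below the direct detection
#' limit, it can be extrapolated from the measured high-dose concentration via
#' the transcriptional dose-response ratio of a co-transcribed fluorescent
#' reporter (the two genes share one polycistronic transcript).
#'
#' @param high_dose_uM measured membrane concentration at full induction, uM
#'   (default 2.54)
#' @param response_ratio low/high dose-response ratio of the co-transcribed
#'   reporter (default 0.18)
#' @return extrapolated concentration in nM
#' @export
extrapolate_low_dose_concentration <- function(high_dose_uM = 2.54,
                                               response_ratio = 0.18) {
  stopifnot(high_dose_uM >= 0, response_ratio >= 0)
  high_dose_uM * response_ratio * 1000
}

#' @export
print.expression_estimate <- function(x, ...) {
  cat("expression estimate: P =", signif(x$permeability, 4), "um/ms;",
      "flow =", signif(x$volumetric_flow, 4), "um^3/ms;",
      "channels/cell =", signif(x$channels_per_cell, 4), ";",
      "concentration =", signif(x$concentration_uM, 4), "uM\n")
  invisible(x)
}

default_scheme_args <- function(scheme_config) {
  if (is.null(scheme_config$g) && is.null(scheme_config$b_values))
    scheme_config$b_values <- seq(0, 800, by = 100)
  scheme_config
}

# small deterministic seed derivation, kept below 2^31
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 2654435761 + i * 97003) %% 2147483629) + 1L
}
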