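#' Simulation parameters for the water-exchange random walk
#'
#' @param tau time step, us (default 50)
#' @param D_in intracellular free diffusivity, um^2 s^-1 (default 554.7, water
#'   at the scanner bore temperature of 12.9 C)
#' @param D_ex extracellular free diffusivity, um^2 s^-1 (default 1664.2)
#' @param permeability_by_label named numeric: membrane permeability P in
#'   um ms^-1 per label (defaults: `LOW_PERM` 0.039, `HIGH_PERM` 0.14,
#'   literature values for control and water-channel-expressing cells)
#' @param n_walkers number of water molecules
#' @param max_crossings maximum membrane intersections handled within one time
#'   step before aborting with a diagnostic (default 1000; grazing-incidence
#'   specular reflections legitimately chain many short chords in one step, so
#'   the cap is a runaway guard rather than an expected limit)
#' @param transmission_reference which free diffusivity enters the membrane
#'   transmission probability: `"intracellular"` (default, both crossing
#'   directions use D_in) or `"donor"` (the compartment the walker leaves)
#' @param rescale_on_transmission logical; if TRUE (default), the residual
#'   step length after a transmitted crossing is rescaled by
#'   `sqrt(D_new/D_old)`, so the remaining sub-step is taken at the scale of
#'   the compartment the walker has entered. FALSE preserves the drawn step
#'   length across the membrane, the new diffusivity applying only from the
#'   next time step on (see the methods vignette)
#' @return list of class `sim_params`
#' @export
sim_params <- function(tau = 50,
                       D_in = 554.7, D_ex = 1664.2,
                       permeability_by_label = c(LOW_PERM = 0.039, HIGH_PERM = 0.14),
                       n_walkers = 10000L,
                       max_crossings = 1000L,
                       transmission_reference = c("intracellular", "donor"),
                       rescale_on_transmission = TRUE) {
  stopifnot(tau > 0, D_in > 0, D_ex > 0, all(permeability_by_label >= 0),
            n_walkers >= 1)
  transmission_reference <- match.arg(transmission_reference)
  p <- structure(list(tau = tau, D_in = D_in, D_ex = D_ex,
                      permeability_by_label = permeability_by_label,
                      n_walkers = as.integer(n_walkers),
                      max_crossings = as.integer(max_crossings),
                      transmission_reference = transmission_reference,
                      rescale_on_transmission = isTRUE(rescale_on_transmission)),
                 class = "sim_params")
  # fail early if the time step makes any transmission probability exceed 1
  for (P in permeability_by_label) transmission_probability(P, D_in, tau)
  p
}

#' Per-axis random-walk step scale
#'
#' The walker advances by `sqrt(2 * D * tau) * N` per axis and time step,
#' `N` a standard normal variate.
#'
#' @param D free diffusivity, um^2 s^-1
#' @param tau time step, us
#' @return step scale in um
#' @export
step_sigma <- function(D, tau) {
  if (any(D <= 0) || any(tau <= 0)) stop("step_sigma: D and tau must be positive")
  sqrt(2 * D_um2s_to_um2ms(D) * (tau / 1000))
}

#' Membrane transmission probability
#'
#' Probability that a walker hitting a cell surface crosses it rather than
#' reflecting: `p = P * sqrt(pi * tau / D_ref)`, the fixed-time-step
#' Gaussian-walk membrane rule. By the study's convention `D_ref` is the
#' intracellular free diffusivity for both crossing directions.
#'
#' @param P membrane permeability, um ms^-1
#' @param D_reference free diffusivity entering the rule, um^2 s^-1
#' @param tau time step, us
#' @return transmission probability in \[0, 1\]
#' @export
transmission_probability <- function(P, D_reference, tau) {
  stopifnot(all(P >= 0), D_reference > 0, tau > 0)
  p <- P * sqrt(pi * (tau / 1000) / D_um2s_to_um2ms(D_reference))
  if (any(p > 1))
    stop("transmission probability exceeds 1; use a smaller time step tau")
  p
}

#' Initialise walkers uniformly over the periodic box
#'
#' @param lattice a `cell_lattice`
#' @param n_walkers number of walkers
#' @param seed integer RNG seed
#' @return object of class `walker_ensemble`: `start_positions`, `positions`
#'   (unwrapped, um), `compartments` (0 = extracellular), `displacement`
#' @export
init_walkers <- function(lattice, n_walkers, seed = 1L) {
  stopifnot(n_walkers >= 1)
  set.seed(seed)
  pos <- cbind(runif(n_walkers, 0, lattice$box_lengths[1]),
               runif(n_walkers, 0, lattice$box_lengths[2]),
               runif(n_walkers, 0, lattice$box_lengths[3]))
  structure(list(
    start_positions = pos,
    positions = pos,
    compartments = locate(pos, lattice),
    displacement = matrix(0, n_walkers, 3),
    seed = seed
  ), class = "walker_ensemble")
}

#' Propagate walkers through the lattice
#'
#' Each time step a walker takes an isotropic Gaussian step scaled by the
#' diffusivity of its current compartment. Where the step crosses a cell
#' surface the walker is moved to the intersection point and then transmitted
#' (with the label's transmission probability, continuing the remaining step
#' length rescaled by `sqrt(D_new/D_old)`) or specularly reflected; multiple
#' crossings within one step are handled iteratively.
#'
#' Reproducibility: the walk consumes R's RNG stream, so call `set.seed()`
#' (or pass `seed`) beforehand.
#'
#' @param ensemble a `walker_ensemble`
#' @param lattice a `cell_lattice`
#' @param params a `sim_params`
#' @param n_steps number of time steps
#' @param seed optional integer; when supplied, `set.seed(seed)` is called
#' @param transmission_override optional numeric in \[0,1\] forcing the
#'   transmission probability for every cell (testing hook, e.g. 1 for a
#'   transparent membrane)
#' @return the updated `walker_ensemble`
#' @export
propagate <- function(ensemble, lattice, params, n_steps,
                      seed = NULL, transmission_override = NULL) {
  stopifnot(inherits(ensemble, "walker_ensemble"), inherits(params, "sim_params"),
            n_steps >= 0)
  if (n_steps == 0) return(ensemble)
  if (!is.null(seed)) set.seed(seed)
  ncell <- length(lattice$radii)
  if (ncell > 0) {
    P <- params$permeability_by_label[as.character(lattice$labels)]
    if (anyNA(P)) stop("lattice labels missing from permeability_by_label")
    p_exit <- transmission_probability(unname(P), params$D_in, params$tau)
    p_enter <- if (params$transmission_reference == "donor")
      transmission_probability(unname(P), params$D_ex, params$tau)
    else p_exit
  } else {
    p_exit <- p_enter <- numeric(0)
  }
  if (!is.null(transmission_override))
    p_exit <- p_enter <- rep(transmission_override, ncell)
  res <- mc_propagate(ensemble$positions, as.integer(ensemble$compartments),
                      if (ncell > 0) lattice$centers else matrix(0, 0, 3),
                      lattice$radii, p_exit, p_enter, lattice$box_lengths,
                      step_sigma(params$D_in, params$tau),
                      step_sigma(params$D_ex, params$tau),
                      as.integer(n_steps), params$max_crossings,
                      params$rescale_on_transmission)
  ensemble$positions <- res$positions
  ensemble$compartments <- res$compartments
  ensemble$displacement <- res$positions - ensemble$start_positions
  ensemble
}

#' @export
print.walker_ensemble <- function(x, ...) {
  cat("walker ensemble:", nrow(x$positions), "walkers;",
      sum(x$compartments > 0), "intracellular\n")
  invisible(x)
}
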