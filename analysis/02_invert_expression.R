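#!/usr/bin/env Rscript

# Inversion chain: measured ADC -> membrane permeability -> volumetric water
# flow -> channel count -> membrane concentration, plus the low-dose
# extrapolation. Reads results/permeability_sweep.csv (from
# analysis/01_simulate_sweeps.R) and writes results/expression_estimates.json.
#
# Usage: Rscript analysis/02_invert_expression.R

suppressPackageStartupMessages(library(aqpdwi))

path <- "results/permeability_sweep.csv"
if (!file.exists(path))
  stop("run analysis/01_simulate_sweeps.R first (missing ", path, ")")
sweep <- utils::read.csv(path)
class(sweep) <- c("sweep_table", "data.frame")

control_adc <- 377.57
measured <- c(control = control_adc,
              low_induction = control_adc * 1.54,
              full_induction = control_adc * 2.87)

estimates <- lapply(names(measured), function(cond) {
  P <- withCallingHandlers(
    invert_adc_to_permeability(measured[[cond]], sweep, Delta_eff = 398,
                               out_of_range = "clamp"),
    warning = function(w) {
      message("NOTE [", cond, "]: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  est_small <- permeability_to_concentration(P) # 697 um^3 cell volume
  est_large <- permeability_to_concentration(P, cell_volume = 1317)
  list(condition = cond,
       adc_measured = measured[[cond]],
       permeability = P,
       volumetric_flow = est_small$volumetric_flow,
       channels_per_cell = est_small$channels_per_cell,
       concentration_uM_v697 = est_small$concentration_uM,
       concentration_uM_v1317 = est_large$concentration_uM)
})

out <- list(
  estimates = estimates,
  low_dose_extrapolation_nM = extrapolate_low_dose_concentration(2.54, 0.18),
  sweep_file = path
)
jsonlite::write_json(out, "results/expression_estimates.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/expression_estimates.json")
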