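#' Unit conversions used throughout the package
#'
#' Internal computations use micrometres and milliseconds; user-facing
#' interfaces follow the conventions of the diffusion-MRI literature:
#' diffusivities in um^2 s^-1, membrane permeability in um ms^-1, b-values in
#' s mm^-2. `b = 1000 s mm^-2` is equivalent to `1 ms um^-2`.
#'
#' @param D diffusivity in um^2 s^-1
#' @param b b-value in s mm^-2
#' @name units
NULL

#' @rdname units
#' @return `D_um2s_to_um2ms()`: diffusivity in um^2 ms^-1.
#' @export
D_um2s_to_um2ms <- function(D) D / 1000

#' @rdname units
#' @return `b_smm2_to_msum2()`: b-value in ms um^-2.
#' @export
b_smm2_to_msum2 <- function(b) b * 1e-3

#' @rdname units
#' @param adc_um2ms diffusivity in um^2 ms^-1
#' @return `adc_um2ms_to_um2s()`: diffusivity in um^2 s^-1.
#' @export
adc_um2ms_to_um2s <- function(adc_um2ms) adc_um2ms * 1000
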