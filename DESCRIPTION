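Package: aqpdwi
Title: Monte Carlo Modelling of Transmembrane Water Exchange for
    Diffusion-Weighted MRI of Aquaporin Reporter Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates restricted water diffusion and membrane exchange in a
    periodic face-centered-cubic lattice of spherical cells emulating a packed
    cell pellet, computes apparent diffusion coefficients (ADC) from walker
    displacements or multi-b signal decays, inverts measured ADC values to
    membrane water permeability and aquaporin channel concentration, fits
    T1 saturation-recovery and T2 echo-train series, and provides the group
    statistics and synthetic-data generators needed to analyse pellet MRI
    experiments of water-channel reporter genes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "installed")
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
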