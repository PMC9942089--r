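Package: afmsim
Title: Simulation of CO-Tip High-Resolution AFM Images from Molecular
    Geometry and Charge-Density Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates frequency-modulation atomic force microscopy (AFM)
    images acquired with a CO-functionalized tip.  The tip-sample
    interaction is split into an attractive r^-6 van der Waals term, an
    electrostatic term computed as the FFT cross-correlation of the sample
    electrostatic potential with the tip differential charge density, and a
    short-range Pauli term computed from the overlap of tip and sample
    electron densities.  The CO probe is relaxed on a lever sphere against
    a torsional spring, relaxed force curves are converted to frequency
    shift at finite oscillation amplitude, and constant-height grayscale
    image stacks are laid out in a browsable dataset with index files.
    Includes XSF/Gaussian-cube volumetric I/O, synthetic
    density/potential generators for desk-scale work without DFT inputs,
    molecule filtering (element whitelist, size, cell fit, quasi-planarity),
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
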