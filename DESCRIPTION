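Package: lemfit
Title: Equilibrium Unfolding Analysis of Proteins by the Linear
    Extrapolation Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits two-state and three-state chemical denaturation curves and
    two-state thermal melts of proteins by nonlinear least squares under the
    linear extrapolation method (LEM), in which the unfolding free energy
    varies linearly with denaturant concentration.  Provides closed-form
    evaluation of the unfolding models and of species-population profiles
    (native, intermediate, unfolded), extraction of spectroscopic probe
    signals from circular-dichroism and tryptophan-fluorescence wavelength
    scans (mean residue ellipticity at 222 nm, relative fluorescence at
    340 nm, emission-maximum wavelength), A280 extinction-coefficient
    utilities, a synthetic-experiment generator for parameter-recovery
    studies, and a report driver that aggregates replicate fits into
    mean +/- SEM stability tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    seqinr,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
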