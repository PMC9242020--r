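Package: methbend
Title: DNA Bending Mechanics and Cytosine Methylation from D-Shaped
    Nanostructures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying how cytosine methylation changes the
    bendability of double-stranded DNA using D-shaped DNA nanostructures.
    Provides a discrete worm-like-chain Metropolis Monte Carlo sampler of
    a coarse-grained closed loop (rigid dsDNA portion plus flexible ssDNA
    string, with optional denatured kink joints), an ALEX single-molecule
    FRET burst pipeline (intensity corrections, efficiency and
    stoichiometry, burst selection, Gaussian mixture fitting of FRET
    histograms, kink-fraction estimation), stiffness inference from
    FRET-derived end-to-end distances against the entropic force of the
    ssDNA string, high-resolution melting-curve analysis, and seeded
    synthetic-data generators that emulate each measurement so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
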