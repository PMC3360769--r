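Package: mtaster
Title: Steady-State Theory of Centrosome-Nucleated Microtubule Asters
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytical steady-state theory of microtubule asters nucleated at
    a centrosome, under the diffusion-with-drift approximation of dynamic
    instability. Solves the partitioning of a finite cellular tubulin pool
    between monomer and polymer as a function of centrosome nucleation
    capacity, computes radial microtubule density profiles and Poisson
    organelle-capture probabilities, and locates the nucleation capacity that
    maximizes capture. Includes the spherical-ectoplasm model of female
    pronucleus capture in the physiologically polyspermic egg of Beroe ovata,
    and a stochastic reflected drift-diffusion simulator of microtubule
    lengths competing for the shared tubulin pool, used as an independent
    check of the analytical results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
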