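Package: nanogelmc
Title: Coarse-Grained Monte Carlo Simulation of Thermosensitive Charged
    Nanogels and Their Nanoparticle Composites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds bead-spring models of cross-linked polyelectrolyte
    nanogels, samples them with Metropolis Monte Carlo under periodic
    boundary conditions (Ewald electrostatics, nanoparticle-counterion
    cluster moves, temperature-switched hydrophobic attraction), and
    computes the observables that characterise thermoresponsive
    nanocomposites: radius of gyration and geometric radius, number of
    absorbed nanoparticles, radial density and charge profiles, surface
    electrostatic potential, and nanoparticle-nanoparticle pair
    correlations. A modified Poisson-Boltzmann cell model with
    excluded-volume saturation of local concentrations is included for
    mean-field comparison with the particle-level results.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
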