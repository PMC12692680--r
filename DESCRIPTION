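Package: segrowth
Title: Timeline-Segregated Batch Growth Models for Bacterial Mono- and
    Co-Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and calibration of a segregated batch growth model
    for bacterial mono- and co-cultures in which cell birth is a discrete
    event: all cells of a strain divide synchronously once their cumulative
    specific growth reaches one mass doubling, each division halving every
    existing age cluster and founding a new generation cluster.  Between
    divisions, clusters grow by Monod kinetics on a shared substrate, die by
    a first-order process into a common dead-biomass pool, and dead biomass
    is recycled into substrate by a delayed first-order lysis process.  An
    optional lactic-acid state couples two strains (producer and inhibited)
    in co-culture.  The package provides an event-driven integrator for the
    resulting hybrid delay system, a root-mean-square objective on viable
    biomass observations, real-coded genetic-algorithm and differential-
    evolution fitters with a ten-run uncertainty protocol, synthetic
    observation generation with multiplicative lognormal noise, preset
    parameter sets for Escherichia coli and Lactobacillus acidophilus on
    two media, and delimited-file input/output with a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
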