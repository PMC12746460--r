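Package: dissipath
Title: Dissipation Pathways for Excitonic Energy Transfer in Structured
    Harmonic Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Golden-rule simulation of excitation energy transfer and of the
    mode-, frequency-, chromophore-, and time-resolved dissipation that
    accompanies it, for Frenkel exciton models coupled to structured harmonic
    environments such as light-harvesting pigment-protein complexes.
    Implements line-broadening functions, pairwise transfer rate constants,
    dissipative potentials and dissipative spectral densities, population
    dynamics with accumulated dissipation fields, a slow/fast spectral-density
    splitting with a quasi-static Gaussian disorder ensemble, and a synthetic
    generator of chromophore-specific spectral densities together with an
    embedded 7-site Fenna-Matthews-Olson-like exciton Hamiltonian.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    parallel,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
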