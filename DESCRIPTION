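Package: coilmelt
Title: Thermal Unfolding and Actin-Binding Analysis of Coiled-Coil Tropomyosins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of temperature-sensitive coiled-coil
    tropomyosin variants. Deconvolves circular-dichroism melting curves into
    one or two two-state van't Hoff unfolding transitions (melting temperature,
    van't Hoff enthalpy, amplitude) via first-derivative Gaussian fitting and
    direct model fits; analyses actin-tropomyosin co-sedimentation densitometry
    with the Hill equation (half-saturation constant K50 with free-ligand
    depletion correction); annotates heptad registers, core alanine clusters
    and intra- and inter-helix charge pairs of the coiled coil; and provides a
    seeded synthetic-data generator so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
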