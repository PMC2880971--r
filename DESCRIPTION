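Package: emdesign
Title: Strain Design from Elementary Flux Modes, Pathway Thermodynamics,
    and Genetic Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates the elementary flux modes (EMs) of small stoichiometric
    metabolic models, reconstructs flux distributions as convex combinations of
    EMs weighted either equally or by pathway standard Gibbs free energy, and
    searches binary reaction-knockout genotypes with a genetic algorithm (and a
    multi-objective NSGA-II variant) to maximize product yield, biomass yield,
    or their product. Includes a flux balance analysis baseline, an essentiality
    pre-screen, brute-force oracles for elementary modes and knockout search,
    and a catalogue of toy fixture networks with analytically known mode sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
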