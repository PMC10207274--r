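Package: micropka
Title: Microstate Thermodynamics of Multiprotic Ionization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-thermodynamics treatment of multiprotic ionization
    equilibria. From a set of ionization microconstants (or per-microstate
    relative free energies), computes pH-dependent microstate and macrostate
    populations, apparent (macroscopic) pKa values, per-group averaged site
    protonation (ASP, the site titration curve), averaged single-proton
    acidity (ASPA/pASPA), and the pH-independent single-proton midpoint pK50.
    Includes validated readers and writers for microstate systems given as
    free energies, hypercube edge lists of micro-pKa values, or pairwise
    interaction models, plus synthetic-system generators with known ground
    truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
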