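Package: cfpath
Title: Carbon Flux Paths in Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds K-shortest carbon flux paths (CFPs) between two metabolites
    of a stoichiometric metabolic network. A CFP is a simple directed path in
    the metabolite graph restricted to effective carbon exchange whose steps
    can be carried by a steady-state flux distribution of the whole network;
    the joint problem is solved as a mixed-integer linear program with
    big-M reaction activity coupling, reversible-pair exclusion and integer
    cuts for enumeration. Includes downstream pathway analyses (recovery and
    accuracy against reference pathways, connectivity curves with and without
    stoichiometry, arc/metabolite frequency tables, baseline graph
    strategies), packaged example networks, a seeded random-network
    generator, readers for SBML and a JSON model dialect, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with scipy (MILP/LP backend, resolved on
    PATH at run time)
Config/testthat/edition: 3
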