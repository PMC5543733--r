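Package: epitopr
Title: Classical Linear B-Cell Epitope Prediction and Conservation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts linear B-cell epitopes on protein sequences with the
    classical propensity-scale toolkit: sliding-window hydrophilicity
    (Hopp-Woods or Kyte-Doolittle), Emini hexapeptide surface probability,
    Karplus-Schulz chain flexibility, Chou-Fasman and GOR-style secondary
    structure, and a Jameson-Wolf-type composite antigenic index. Maximal
    high-index segments are extracted, filtered by explicit reportable rules
    (minimum length, surface accessibility, rigid-structure fraction,
    hydrophilicity, flexibility, forbidden active-site regions) and ranked.
    Also scores per-column conservation of an epitope window across a
    multiple alignment with group contrasts (e.g. venomous versus
    non-venomous species), expands IUPAC-degenerate primers, and generates
    seeded synthetic proteins and alignments with planted ground truth so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
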