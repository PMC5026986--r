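Package: nitritrace
Title: Isotope Mass Balance and Nitrogen Budgets for Throughfall
    Nitrification Incubations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring microbial nitrification in incubated
    throughfall and rainfall samples. Implements dual-isotope (delta-18O,
    delta-15N) two-end-member mixing of nitrate, including prediction of the
    nitrification endmember from water and dissolved-O2 oxygen isotopes,
    inorganic nitrogen budgeting across filter treatments, qPCR amoA
    copy-number normalization with limit-of-quantification censoring, and a
    seeded stochastic simulator of incubation experiments used to validate
    the analysis chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
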