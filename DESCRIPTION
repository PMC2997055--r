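Package: oxitrans
Title: Quantify Oxime Transport Across an In Vitro Blood-Brain Barrier by
    Acetylcholinesterase Reactivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An enzymatic-biosensor pipeline for Transwell blood-brain-barrier
    transport assays in which the transported reactivator (oxime) concentration
    is read out from the recovery of organophosphate-inhibited
    acetylcholinesterase activity. Implements the pseudo-first-order
    reactivation model (forward rate law, monoexponential time-course
    prediction, one-parameter nonlinear least-squares rate fitting, and the
    algebraic inversion of fitted rates to oxime concentrations), dilution
    standardization for the assay cuvette and Transwell system, transport
    differences of nanoparticle formulations relative to free drug, and an
    exact (full-enumeration) two-tailed Mann-Whitney U test. A seeded
    synthetic-data generator emulates the complete Transwell experiment so
    every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
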