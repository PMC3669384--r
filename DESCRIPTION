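Package: metabodiv
Title: Metabolomic Microdiversity Analysis of Ultra-High-Resolution Mass
    Spectrometry Peak Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for exploring metabolomic microdiversity among
    co-occurring bacterial strains profiled by direct-infusion ion cyclotron
    resonance Fourier-transform mass spectrometry (ICR-FT/MS). Reads per-sample
    peak lists, aligns them into a feature matrix within a ppm tolerance,
    assigns CHNOS elemental formulas under standard chemical constraints,
    removes carbon-13 isotopologue satellites, builds mass-difference and
    sample-correlation networks, selects group-discriminative metabolites with
    OPLS-DA (VIP scores and the joint covariance/correlation rule) and Wilcoxon
    tests, clusters strains into metabotype OTUs on Ward dendrograms with
    rarefaction, Shannon and Good's coverage statistics, and summarises
    annotation against a local formula-to-metabolite reference table. Includes
    a synthetic peak-list generator with known ground truth so every stage of
    the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
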