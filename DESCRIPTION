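Package: sizeseason
Title: Seasonal Analysis of Size-Fractionated Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for monthly time series of size-fractionated
    bacterial community data spanning the particulate-matter continuum
    (0.2-200 um). Provides OTU-table preprocessing (taxon filtering,
    rarefaction, taxonomic aggregation, dominant-group selection), true
    alpha/beta/gamma diversity partitioning across size-fractions,
    Bray-Curtis reference-month trajectories and warm/cold period
    composition summaries, the Heterogeneous Distribution Index (HDI)
    quantifying how consistently a taxonomic group keeps its size-fraction
    preference over the year, harmonic (annual cosine) regression with
    Levenberg-Marquardt fitting and peak-date ordering, single-factor
    PERMANOVA and bioenv-style environmental driver search, and a seeded
    synthetic-data generator emulating the monthly six-fraction sampling
    design of a temperate coastal observatory.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    vegan,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
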