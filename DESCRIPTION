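Package: sipCoculture
Title: Single-Cell Stable Isotope Probing Analysis of
    Phototroph-Heterotroph Cocultures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative analysis of carbon and nitrogen transfer in algal-
    bacterial cocultures from nanoSIMS-style secondary ion count images.
    Provides per-cell isotope enrichment quantification (atom percent
    enrichment and net assimilation fractions from 12C2-/12C13C- and
    12C14N-/12C15N- ion ratios), an expected-biomass-synthesis model that
    diagnoses reductive division from CFU doublings, a lysis-budget model of
    necromass-driven trophic transfer, microbiological vitamin B12 bioassay
    and cytotoxicity quantification, and a seeded synthetic-data generator
    (coculture dynamics, Poisson ion-count image fields with ground truth,
    and assay plates) so the full pipeline can be exercised and validated
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
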