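Package: darksip
Title: Single-Cell Isotope Probing, Nitrification Rates and Urease Gene
    Prevalence in the Dark Ocean
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis chain for deep-sea urea-utilization
    studies: converts nanoSIMS single-cell ion ratios into isotope-based
    growth (Ka) and elemental assimilation rates with a 2-standard-deviation
    enrichment call against 0-h controls; estimates ammonia- and urea-based
    nitrification rates from 15N-NOx incubation time series by linear
    regression; computes copy-number-corrected ureC/recA marker-gene
    prevalence and contig consensus taxonomy from metagenome coverage
    tables; and builds a nitrification-fueled carbon-fixation budget
    compared against the gravitational particulate organic carbon flux.
    Includes a synthetic-data generator emulating all input tables so every
    stage is testable without cruise data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
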