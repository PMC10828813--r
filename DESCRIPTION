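Package: allocsaw
Title: Bacterial Proteome Resource Allocation and Growth Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies bacterial proteome resource allocation from label-free
    proteomics and links it to growth physiology. Computes iBAQ-mass
    fractions from MaxQuant-style protein group tables, aggregates them into
    functional proteome sectors with replicate statistics, derives LFQ-based
    fold changes and regulon activation folds, and tests gene lists for
    over-representation in flat gene-set catalogs. Companion growth-physiology
    tools fit exponential growth rates from OD600 series, extract
    nutrient-downshift lag times by back-extrapolation of the post-shift
    exponential, and summarize stress-survival (CFU/OD) kinetics. A seeded
    synthetic-data generator with presets provides ground-truth proteomes and
    curves for validation and teaching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
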