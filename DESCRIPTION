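Package: aromalip
Title: Flavoromics Screening, ROAV Scoring and Lipid Shorthand Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for flavoromics and lipidomics analysis of food matrices:
    quality screening of replicate GC-MS volatile peak tables (detection-rate
    and coefficient-of-variation filters), relative percentage content,
    relative odor activity value (ROAV) scoring with automatic selection of
    the standard compound, contribution-category classification, shorthand
    lipid nomenclature parsing and category aggregation, taste-class
    annotation of free amino acids, and Pearson block correlation between
    lipid or amino-acid features and volatile compounds. Includes a
    synthetic-data generator with known ground truth for every stage and a
    packaged odor-threshold table for dry-cured ham volatiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
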