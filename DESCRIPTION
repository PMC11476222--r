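Package: gangliotk
Title: Targeted Ganglioside and Sphingolipid Profiling from LC-MS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted quantitative profiling of gangliosides and
    other sphingolipids from negative-mode LC-MS runs. Builds theoretical
    m/z databases for glycosphingolipid classes across ceramide variants
    and deprotonated charge states from shorthand lipid nomenclature,
    computes exact monoisotopic masses and isotopic distributions from
    elemental compositions, extracts and integrates ppm-tolerance ion
    chromatograms from centroided mzML runs, fits internal-standard
    calibration curves with LOD/LOQ estimation, filters LipidSearch-style
    result tables, and summarizes percent relative abundance across
    replicates. Includes synthetic-run and synthetic-table generators so
    the whole workflow is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mzR,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
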