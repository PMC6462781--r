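Package: fermentr
Title: Fermentation Time-Course Analysis with Hierarchical Trial Metadata
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parses raw microbial-fermentation analyte data (tidy long tables,
    HPLC-style wide exports, plate-reader matrices) into a hierarchical trial
    schema keyed by a flat strain/media/environment identifier grammar,
    extracts physiological features (numerical rates, exponential and sigmoid
    growth-model fits, titer, yield and specific productivity, replicate
    statistics with missing-data and outlier handling, blank and stage
    corrections), integrates measured exchange rates with a stoichiometric
    model to estimate CO2 evolution and carbon recovery by linear programming,
    and persists experiments to a single-file relational (SQLite) store with
    exact round-trip. A synthetic-data generator with known ground truth makes
    every analysis step testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    readxl,
    xml2,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
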