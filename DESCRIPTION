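Package: segmetals
Title: Racial Residential Segregation and Fine Particulate Metal Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline linking racial residential segregation to
    exposure to trace metals in fine particulate matter (PM2.5). Provides
    monitor-level quality control and annual county aggregation of speciated
    PM2.5 records, the Duncan dissimilarity index of segregation with
    categorical classification, population-weighted exposure means per
    segregation category, relative disparity (coefficient of variation) with
    stratified bootstrap confidence intervals, log-log elasticity regression
    reporting percent change per 10 percent increase in segregation, global
    and local Moran's I spatial autocorrelation with permutation inference,
    and a synthetic-data generator with planted truth so the whole pipeline
    is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    dplyr,
    rlang,
    jsonlite,
    yaml,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    optparse,
    sandwich,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
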