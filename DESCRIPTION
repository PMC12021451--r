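Package: papartition
Title: Lipophilicity and Blood Partitioning of Pyrrolizidine Alkaloids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Assay-based estimation of the n-octanol:water partition
    coefficient (log P, miniaturized shake-flask method) and the
    blood-to-plasma concentration ratio (Rb, depletion assay) from
    replicate peak-area data, together with Henderson-Hasselbalch
    speciation (log D), two in-silico Rb prediction models (acid/base
    classification and a mechanistic erythrocyte-composition model),
    deviation-based evaluation of predictions against experimental
    values, and a synthetic assay-data generator for parameter-recovery
    and method-validation studies of pyrrolizidine alkaloids and their
    N-oxides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
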