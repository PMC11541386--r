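Package: metidscreen
Title: Suspect Screening of Pharmaceutical Metabolites in Untargeted LC-HRMS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A suspect-screening pipeline for identifying pharmaceutical
    metabolites in untargeted LC-HRMS feature tables. Enumerates candidate
    metabolites from parent drugs by applying biotransformation reaction
    deltas (phase I/II conjugation mass shifts), builds in silico MS2
    spectral libraries in MSP format (with a precursor-shift rule for
    tentative structures), matches libraries against aligned feature
    tables under configurable mass and retention-time tolerances, and
    triages features with pooled-QC prefilters and volcano selection.
    Ships a synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ChemmineOB,
    ChemmineR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
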