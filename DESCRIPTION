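Package: phenocapture
Title: Scriptable Field-Book Sessions for Manual Plant Phenotyping
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Create, drive and export field-book phenotyping sessions from
    scripts or the command line. Implements the two-sheet location/descriptor
    input workbook, a five-type trait model (rating scales, measured values,
    dates, free text and BBCH phenology codes), the three-level BBCH
    growth-stage registry with Excel template import, serpentine (zigzag)
    plot traversal with first-empty search and partial descriptor selection,
    and lossless spreadsheet/CSV export suitable for LIMS ingestion.
    Includes a deterministic fixture generator for synthetic field layouts.
License: MIT
Encoding: UTF-8
Imports:
    readxl,
    readr,
    tibble,
    jsonlite,
    zip,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
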