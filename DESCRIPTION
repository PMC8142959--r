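Package: edlink
Title: Deterministic Linkage of Ambulance and Emergency Department Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking emergency ambulance conveyance records to
    emergency department (ED) attendance extracts without patient
    identifiers, using the two automatically generated event identifiers
    available in UK prehospital data: the computer aided dispatch (CAD)
    incident number and the crew call sign. Provides a ground-truthed
    synthetic data generator emulating per-trust ED recording behaviour
    (separate identifier fields, one unformatted free-text field, or CAD
    only), an extract format validator, free-text identifier parsing and
    cleaning, a two-pathway deterministic linkage algorithm (CAD plus date
    first, then call sign plus date corroborated by ED arrival time), and
    reporting of match rates, unmatched-record trends, and
    precision/recall against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
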