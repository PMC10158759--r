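Package: rdes
Title: Read, Validate, Reshape and Analyze Raw Real-Time PCR Data in the
    RDES Format
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for disclosing and auditing raw RT-qPCR data in the
    Real-time PCR Data Essential Spreadsheet (RDES) format: strict
    reading, canonical writing and validation of RDES tables
    (amplification and melt variants), reshaping of arbitrary wide or
    long instrument exports into RDES, interchange with a subset of the
    XML-based Real-Time PCR Data Markup Language (RDML), and the
    curve-level analyses that raw-data disclosure enables reviewers to
    verify: baseline estimation, window-of-linearity PCR efficiency,
    quantification-cycle (Cq) determination, efficiency-corrected target
    quantification and normalization, and melting-curve Tm peak calling.
    Includes a simulator of amplification and melt plates with recorded
    ground truth, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
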