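Package: bidsforge
Title: Rule-Based Conversion of Source Neuroimaging Data to BIDS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless, plugin-driven engine for converting minimally
    organized source neuroimaging data into a Brain Imaging Data Structure
    (BIDS) tree. Source data types are discovered by matching regular
    expressions against file properties and header attributes; a generic
    template rule document (a "bidsmap") is narrowed into a study-specific
    one; and each session is converted into BIDS-named output files with
    JSON sidecars, a participants table, and dataset scaffolding. Rule
    values support a dynamic-value mini-language (bracketed property or
    attribute lookups with optional substring-extracting regular
    expressions), run-index auto-increment, and shell-style wildcard
    resolution of fieldmap IntendedFor lists. Ships a deterministic
    synthetic source-data generator in a plain-text "toy scan" format so
    the whole workflow is testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    yaml,
    jsonlite,
    tibble,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
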