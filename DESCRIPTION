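Package: redcapqc
Title: Data Management and Quality Control for REDCap Exports
Version: 0.1.0
Authors@R: person("Biostat", "Tools", email = "tools@example.org", role = c("aut", "cre"))
Description: Turns raw REDCap project exports (records, data dictionary and
    event-form mapping CSV files) into analysis-ready, quality-checked
    datasets. Includes a parser and three-valued evaluator for REDCap
    branching-logic and calculated-field expressions, a transformation
    pipeline (calculated-field recalculation, checkbox restructuring,
    factor substitution, branching-logic translation and pattern-based
    column deletion), a discrepancy query system (rule-based queries,
    missing-event detection, report summaries and longitudinal report
    diffing), a seeded synthetic project generator for testing, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
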