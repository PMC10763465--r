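Package: dassr
Title: Defined Approaches for Skin Sensitization: Hazard and Potency
    Prediction from Non-Animal Assay Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Applies the three internationally harmonized defined approaches
    (DAs) for skin sensitization -- the Two-out-of-Three (2o3), the Key Event
    3/1 Sequential Testing Strategy (KE 3/1 STS), and the Integrated Testing
    Strategy (ITS) -- to per-chemical tables of in chemico (DPRA), in vitro
    (KeratinoSens, h-CLAT), and in silico assay results. Provides tabular
    input/output (TSV, CSV, XLSX), column auto-mapping against a canonical
    data template, machine-readable validation flags, harmonization of raw
    cells into standardized calls and calculated inputs, GHS hazard and
    potency predictions, and performance evaluation of predictions against
    user-supplied reference classifications via contingency tables and
    summary metrics. Includes a seeded synthetic-data generator with a
    defect ledger and an independent rule oracle, and a batch command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    readxl,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
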