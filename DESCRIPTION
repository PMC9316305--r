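Package: capturesim
Title: Cycle-Time, Binding-Capacity and Productivity Modeling for Protein A
    Capture Chromatography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic process models for the protein A capture step in
    monoclonal antibody downstream processing. Estimates dynamic binding
    capacity (total and at 10% breakthrough) from breakthrough-curve and
    fraction data, pools elution peaks by UV threshold, models the dependence
    of binding capacity on residence time, simulates recipe-driven
    chromatography cycles (phase durations, buffer consumption, regeneration
    amortization), computes volumetric productivity with flow-rate and titer
    sweeps and flow-rate optimization, and provides product-quality metrics
    (step yield, impurity log reduction values). A synthetic-data module
    generates Thomas-model breakthrough curves with closed-form oracles and
    per-cycle UV/pressure traces so every stage is testable without
    instrument exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
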