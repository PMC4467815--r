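Package: phoscea
Title: Cost-Effectiveness of Second-Line Lanthanum Carbonate for
    Hyperphosphatemia in Chronic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lifetime decision-tree plus three-state Markov cohort model
    (predialysis, dialysis, death) comparing second-line lanthanum
    carbonate against continued calcium-based phosphate binders for
    hyperphosphatemia in chronic kidney disease, from the Spanish
    healthcare payer perspective. Implements serum-phosphorus-stratified
    relative risks on mortality and progression, half-cycle correction,
    discounting, incremental cost-effectiveness (ICER, dominance, net
    monetary benefit), one-way scenario analyses, and a probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves.
    Includes a patient-level microsimulation used as a brute-force check
    of the cohort engine and generators for synthetic parameter sets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    tibble
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
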