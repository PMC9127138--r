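Package: markovcea
Title: Markov Cohort Cost-Effectiveness Modelling of Second-Line Therapy in
    Advanced Endometrial Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (progression-free, progressive disease, death)
    Markov cohort model for cost-utility analysis of lenvatinib plus
    pembrolizumab versus single-agent chemotherapy in pretreated advanced
    endometrial cancer, with full per-state cost accounting (drug
    acquisition, adverse-event management, crossover subsequent therapy,
    disease management, palliative-care transition costs), discounting and
    half-cycle correction, conversion of published survival medians to
    monthly transition probabilities, one-way (tornado) and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves, a
    mismatch-repair-proficient subgroup scenario, and a synthetic
    patient-level survival data generator for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
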