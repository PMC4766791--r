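Package: hierVA
Title: Hierarchical Expert-Algorithm Assignment of Verbal Autopsy Causes of Death
Version: 0.1.0
Authors@R:
    person("hierVA", "Developers", email = "hierva@example.org", role = c("aut", "cre"))
Description: Assigns causes of neonatal (0-27 days) and child (1-59 months)
    death from close-ended verbal autopsy (VA) questionnaire responses using
    expert algorithms -- boolean symptom predicates -- arranged in a
    pre-specified cause hierarchy, and validates the assignments against
    reference-standard causes.  Provides harmonization of co-morbid
    reference-standard causes to single underlying causes, mortality-scenario
    resampling of a labelled death pool against country cause-of-death
    distributions, population-level agreement metrics (CSMF accuracy,
    per-cause absolute CSMF differences) and individual-level metrics
    (Cohen's kappa, chance-corrected concordance), a synthetic questionnaire
    generator with controlled symptom sensitivity and specificity, and a
    replicated validation pipeline with median-and-range summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
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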