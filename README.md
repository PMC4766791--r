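# hierVA

Hierarchical expert-algorithm assignment of verbal autopsy (VA) causes of
death, with a complete validation framework.

## What this is for

Where civil registration is unreliable, causes of neonatal (0–27 days)
and child (1–59 months) death are inferred from verbal autopsy:
structured interviews with caregivers of the deceased.  *Expert
algorithms* analyse these interviews deterministically — each cause of
death has a boolean predicate over close-ended symptom questions, and
every predicate that fires contributes a cause.  When several causes
fire, a pre-specified **hierarchy** of causes selects the single primary
one (the earliest-ranked fired cause).  The method is automated,
requires no training data set, and is easily explained to non-medical
professionals.

hierVA provides, for epidemiologists and VA methodologists:

* a rules engine (`parse_ruleset()`, `evaluate_records()`,
  `classify_dataset()`) with JSON rule sets as user-editable config and
  nine bundled hierarchies from the literature (six neonatal:
  Arifeen, Baqui, Kalter, Lawn, Liu and a Compromise hierarchy; three
  child: Arifeen, Kalter, Liu);
* reference-standard harmonization of co-morbid causes to single
  underlying causes via ICD-10-style rules, with deterministic
  largest-remainder proportional reallocation (`harmonize_comorbid()`,
  `collapse_groups()`);
* mortality-scenario resampling of a labelled death pool against country
  cause-of-death distributions: high under-five mortality (U5MR > 35 per
  1000 live births) with and without endemic malaria (> 5 % of
  under-five deaths), moderate mortality (20–35 per 1000), and a general
  scenario with cause fractions uniform on 5–40 %
  (`scenario_spec()`, `draw_target_csmf()`, `resample_to_target()`);
* agreement metrics at the population level — CSMF accuracy
  `1 − Σ|p̂ⱼ − pⱼ| / (2(1 − minⱼ pⱼ))` and per-cause absolute CSMF
  differences — and the individual level — Cohen's kappa and
  chance-corrected concordance `CCCⱼ = (sensⱼ − 1/N)/(1 − 1/N)`;
* a synthetic questionnaire generator with controlled symptom
  sensitivity/specificity (`synthetic_fixture()`) and a replicated
  validation pipeline reporting medians and ranges
  (`run_validation()`, `summarize_validation()`).

See `vignettes/hierVA-methods.Rmd` for the model, its assumptions, and
all numerical choices.

## Worked example

The population-level statistic in one line — an algorithm estimating
52 %, 29 %, 2 % and 4 % of neonatal deaths for sepsis/pneumonia, birth
asphyxia, congenital malformation and prematurity, where the actual
fractions are 32 %, 31 %, 11 % and 11 %:

```r
library(hierVA)
round(csmf_accuracy(
  c(sepsis_pneumonia = .52, birth_asphyxia = .29,
    congenital_malformation = .02, preterm_delivery = .04),
  c(sepsis_pneumonia = .32, birth_asphyxia = .31,
    congenital_malformation = .11, preterm_delivery = .11)), 2)
#> [1] 0.79
```

0.79 indicates good *overall* performance even though sepsis/pneumonia is
overestimated by 0.20 — CSMF accuracy can mask poor performance on
particular causes, which is why the per-cause absolute differences are
reported alongside it.

A full synthetic validation run (1000 deaths, sensitivity 0.8,
specificity 0.97, three hierarchies, 100 replicates per scenario):

```r
fix <- synthetic_fixture("neonate", n = 1000, sensitivity = 0.8,
                         specificity = 0.97, background = 0.02)
res <- run_validation(fix$records, fix$labels, fix$ruleset,
                      c("baqui", "lawn", "compromise"),
                      table = read_country_table("neonate"),
                      replicates = 100, seed = 7)
res
#> run_validation: 42 tie/unranked-cause event(s) during classification
#> <va_validation> neonate, n = 1000 per replicate, seed = 7
#> CSMF accuracy, median (range):
#>   general                baqui        0.81 (0.74-0.87)
#>   general                compromise   0.83 (0.77-0.87)
#>   general                lawn         0.81 (0.74-0.87)
#>   high_u5mr_malaria      baqui        0.79 (0.74-0.84)
#>   high_u5mr_malaria      compromise   0.82 (0.80-0.85)
#>   high_u5mr_malaria      lawn         0.79 (0.74-0.84)
#>   high_u5mr_no_malaria   baqui        0.80 (0.75-0.85)
#>   high_u5mr_no_malaria   compromise   0.82 (0.78-0.85)
#>   high_u5mr_no_malaria   lawn         0.80 (0.75-0.85)
#>   moderate_u5mr          baqui        0.81 (0.77-0.83)
#>   moderate_u5mr          compromise   0.81 (0.77-0.84)
#>   moderate_u5mr          lawn         0.81 (0.77-0.83)
```

Each row is the median (min–max) CSMF accuracy over 100 replicates of
that scenario: a target cause distribution is drawn (a random eligible
country, or uniform 5–40 % fractions for `general`), the labelled pool
is resampled to match it, and every hierarchy scores the same resample.
`summarize_validation(res)` returns the full tidy table including kappa,
chance-corrected concordance, the unclassified fraction and per-cause
absolute CSMF differences; `write_validation(res, dir)` writes
per-replicate and summary CSV/JSON.

A command-line front end ships in `inst/exec/hierva`
(`classify`, `simulate`, `validate` subcommands; see `?hierva_cli`).

## Real-data validation

Published validation of this method uses the PHMRC hospital reference
deaths (1629 neonatal, 1456 child), which are an external download and
not bundled here; the bundled rule sets are illustrative placeholders
for the published algorithm suites.  To reproduce such an analysis:
export the questionnaire to the CSV layout of `read_va_records()` (a
JSON column-mapping file translates arbitrary headers), transcribe the
algorithm suite into the rule-set JSON schema, supply the
reference-standard causes as pipe-separated CSV and the WHO/CHERG
country CSMFs in the `read_country_table()` layout, then run
`hierva validate --replicates 1000`.
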