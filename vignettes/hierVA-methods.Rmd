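---
title: "Methods: hierarchical expert-algorithm verbal autopsy analysis and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical expert-algorithm verbal autopsy analysis and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierVA)
```

## The problem

In settings without reliable civil registration, causes of neonatal
(0–27 days) and child (1–59 months) death are inferred from verbal
autopsy (VA): a structured interview with the caregivers of the deceased.
Expert algorithms analyse VA data deterministically: each candidate cause
of death has a boolean predicate over close-ended symptom questions
("combinations of illness signs and symptoms judged predictive of the
cause"), and every predicate that evaluates true contributes a cause.
Because several algorithms can fire for one death, the *primary* cause is
selected by a pre-specified **hierarchy**: an ordered list of causes, the
earliest-ranked fired cause winning.  The method needs no training data
and is fully explainable — identical responses always produce identical
causes — which is its chief advantage over tariff- or
probability-based classifiers.

hierVA implements this classifier together with the complete validation
framework used to assess it against reference-standard causes: co-morbid
reference-cause harmonization, mortality-scenario resampling, and four
agreement metrics.

## The classifier

A **rule set** (JSON; see `?parse_ruleset`) declares a symptom dictionary
and one predicate per cause, built from atoms `symptom == yes`,
`symptom == no`, or numeric threshold comparisons (`>=`, `<=`, with units
declared in the dictionary — no implicit conversion), combined with
`all`/`any`/`not`.  Published algorithm suites are field-editable
configuration, not code: the package ships illustrative rule sets
(`demo_ruleset()`) whose causes match the validation vocabulary, clearly
documented as placeholders.

**Missing and don't-know responses.**  The default policy makes any atom
referencing a missing or don't-know response evaluate false — the
conservative reading, since an algorithm should not fire on information
the respondent could not provide.  A per-rule-set (and per-atom) switch
`dk_policy: "as_no"` instead lets such responses satisfy `symptom == no`
atoms, for questionnaires where an unanswered sign is best read as
absent.  Evaluation is total under both policies.

**Hierarchies.**  Nine hierarchies from the literature are bundled: six
neonatal (`arifeen`, `baqui`, `kalter`, `lawn`, `liu`, and a `compromise`
hierarchy restricted to four cause groups common to all five prior ones)
and three child (`arifeen`, `kalter`, `liu`).  Within-rank ties (some
ranks list several causes at one level) are broken by the listed
left-to-right order; the original studies do not state their tie rule, so
this convention is an assumption, and every tie-break raises a
`hierVA_tie` warning so it can be audited.  Deaths firing no algorithm
receive the fallback cause `unspecified`.

The bundled configs *extend* the published columns with grouped synonyms
(each file's `extended` field lists them): e.g. `pneumonia` is placed in
the "ARI" rank of the hierarchies that predate the pneumonia label, and
`meningitis` in the serious-infection rank of hierarchies that group it
with sepsis/pneumonia.  Without these placements, several hierarchies
could never emit causes that the validation scores for them; the
placements follow each hierarchy's own grouping logic, and users who
disagree can edit the JSON.

## Reference-standard harmonization

Reference causes may be co-morbid.  Following ICD-10 practice that a mode
of perinatal death (prematurity) is not the underlying cause unless it is
the only condition known, the bundled neonatal cause map assigns
preterm/birth-asphyxia deaths to birth asphyxia, preterm/sepsis to
sepsis, and preterm/sepsis/asphyxia *proportionately* to sepsis and birth
asphyxia; co-morbid child pneumonia/diarrhea deaths are proportionately
reallocated the same way.  "Proportionately" is implemented as
deterministic **largest-remainder** rounding of the exact shares (the
ratio of deaths already singly assigned to the targets), so validation
replicates differ only through the resampler's RNG and every allocation
deviates from its real-valued share by less than one death.  The source
studies do not state their rounding mechanism; largest-remainder is this
package's documented choice.

"Possible" VA causes (possible pneumonia, possible diarrhea, residual
infection as possible malaria, …) are distinct cause ids at rule and
hierarchy level and are merged into their definite counterparts only at
scoring time (`collapse_groups()`), so the hierarchy can still
distinguish them.

## Scenario resampling

Hospital reference data do not match community cause distributions, so
the validation resamples the labelled pool to target distributions from
four scenarios: high under-five mortality (U5MR > 35 per 1000 live
births) with malaria endemic (> 5 % of under-five deaths due to
malaria), high U5MR without malaria, moderate U5MR (20–35 per 1000), and
a general scenario in which every cause fraction is drawn uniformly
between 5 % and 40 % and the vector renormalized to sum to one (whether
the original draw renormalized or rejected is unstated; renormalization
is our choice).  Country scenarios draw one eligible country uniformly at
random from a user-supplied CSMF table; a clearly synthetic table ships
for testing only.

Causes absent from the pool are dropped and the remaining fractions
rescaled (relative proportions preserved), mirroring reference causes
such as neonatal tetanus that real pools may lack.  Target fractions
become integer counts by largest-remainder apportionment, and deaths are
drawn **with replacement** per cause (configurable; without-replacement
fails whenever a target fraction exceeds a cause's pool share).  The
replicate size defaults to the pool size, which the source design
implies but does not state.  By construction the empirical CSMF of every
resample equals the apportioned counts divided by n, so it is within 1/n
of the target per cause.

## Agreement metrics

With estimated fractions $\hat p_j$ and reference fractions $p_j$ over
$N$ causes:

* **CSMF accuracy** $= 1 - \dfrac{\sum_j |\hat p_j - p_j|}{2(1 - \min_j p_j)} \in [0, 1]$,
  the population-level summary (1 iff the distributions coincide);
* **absolute CSMF difference** $|\hat p_j - p_j|$ per cause;
* **Cohen's kappa** $\kappa = (p_o - p_e)/(1 - p_e)$ on the
  true-by-predicted confusion matrix, in $[-1, 1]$;
* **chance-corrected concordance**
  $\mathrm{CCC}_j = (\mathrm{sens}_j - 1/N)/(1 - 1/N)$, averaged
  unweighted over causes, spanning $1/(1-N)$ to 1.

Numerical choices where the sources are silent: `csmf_accuracy()` accepts
raw fraction vectors without forcing them to sum to one, because the
published worked example uses rounded percentages summing to 0.87 and
0.85 and still prints 0.79; the CCC average runs over causes with at
least one reference death (undefined sensitivities are skipped, not
zero-filled), and $N$ is the count of those causes, which preserves the
stated floor $1/(1-N)$; `unspecified` is a scoreable category in CSMF
differences and (by default) in kappa's confusion matrix — a
`unspecified = "drop"` switch excludes unclassified deaths from the
individual-level matrix instead — but it never enters the CCC average
unless present in the reference vocabulary.  Metrics are reported at full
precision and conventionally printed to 2 decimals.

## The synthetic-data generator

`synthetic_fixture()` stands in for real interview data so the entire
pipeline is testable offline.  It draws single reference causes from a
configured CSMF, upgrades them to the enumerated co-morbid combinations
(neonate: preterm with asphyxia and/or sepsis; child:
pneumonia + diarrhea) at configured rates, and emits records via a
symptom model derived from the *same rule set the classifier evaluates*:
each cause's signature is a satisfying assignment of its predicate, found
by enumeration (unsatisfiable rules are rejected by name).  A record
satisfies its true cause's predicate with probability `sensitivity`,
satisfies each foreign predicate with probability `1 − specificity`
(leakage is per rule, not per symptom, so specificity has a direct
confusion-matrix interpretation), and unrelated binary symptoms are "yes"
at a background rate.  Co-morbid deaths receive the union of their
causes' signatures under one sensitivity draw.

Defaults are fixed once: n = 1000, seed = 20160601, and cause
distributions chosen as plausible high-mortality community profiles
(neonate: prematurity .30, birth asphyxia .25, sepsis .20, pneumonia .10,
congenital malformation .08, meningitis .07; child: pneumonia .20,
diarrhea .15, other infectious .15, non-infectious .15, malaria .12,
injury .08, meningitis .06, AIDS .05, measles .04); co-morbid rates .05
for each pairwise set and .02 for the neonatal triple.

What a green test establishes — and does not.  In the noiseless limit
(sensitivity = specificity = 1, background 0, disjoint signatures, no
comorbidity) the full pipeline must return CSMF accuracy = κ = CCC = 1
exactly, and the test suite verifies it for every bundled hierarchy and
scenario; degrading sensitivity must not increase median CSMF accuracy.
This validates the plumbing and the metrics, not field performance: the
generator has no symptom correlation structure, no free-text narratives,
and signatures are disjoint by construction, all of which real VA data
violate.  Published validation results for this method on the PHMRC
hospital deaths (e.g. best neonatal CSMF accuracy 0.80, child 0.76)
require that external download and are *not* reproducible from this
package alone; a recipe is sketched in the README.

## Degenerate inputs and errors

Undeclared symptoms, unknown operators and malformed predicates are parse
errors naming the offending rule or atom.  Age-group mismatches between
records, rule sets and hierarchies are usage errors.  CSMF accuracy is
undefined for fewer than two causes; kappa when both margins concentrate
on one cause; CCC for fewer than two reference causes.  An unmatched
co-morbid cause set is a mapping error listing the set; a proportional
rule whose targets have no singly assigned deaths is an allocation error.
A scenario with no eligible countries, or a target with no cause left in
the pool, is a scenario error.

## Reproducibility

All randomness flows through R's RNG: `set.seed()` before any draw
reproduces it exactly.  `run_validation()` derives one independent seed
per (scenario, replicate) cell from its master seed, so summaries are
invariant to evaluation order and worker count, and all hierarchies score
the *same* resample within a replicate (a paired comparison, as the
original design implies by holding the algorithms constant while varying
the hierarchy).  Summaries report the median with the min–max range by
default; a 2.5–97.5 percentile mode is available because published
figures whisker confidence intervals rather than extremes.
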