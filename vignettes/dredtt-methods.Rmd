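---
title: "Screening ED visits for adverse drug events: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening ED visits for adverse drug events: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dredtt)
library(dplyr)
```

## The problem

Adverse drug events (ADEs) — harm from appropriate or inappropriate drug
use — are a common, underdocumented reason for emergency department (ED)
visits. Reviewing every chart is infeasible; a *trigger tool* screens
records with cheap mechanical rules (symptom keywords, abnormal vitals and
labs, marker medications such as antidotes, diagnosis codes) and routes
only flagged visits to in-depth chart review. The tool implemented here,
DrEDTT, is a 28-trigger set designed specifically for drug-related ED
visits, deliberately tuned toward high sensitivity at the cost of a low
positive predictive value (PPV): the screen should miss few ADEs and let
the chart review sort out the false alarms.

`dredtt` provides the screening engine, the case-adjudication logic that
defines a "true ADE", the evaluation statistics that characterise a
trigger tool (PPV, sensitivity, specificity, prevalence, all with binomial
confidence intervals), and a synthetic cohort generator so the whole
pipeline can be exercised and tested without patient data.

## The screening model

A visit record is one row: demographics, pre-tokenised chief-complaint
terms, vital signs, a laboratory panel, ED medication orders, and an
ordered diagnosis-code list whose first element is the main diagnosis.
Each trigger is a declarative predicate of one of seven kinds (keyword,
vital threshold, lab threshold, compound threshold, medication list,
conditional medication, code list). Evaluation semantics are fixed by
three rules:

* **Strict comparators.** Every cutoff uses `<` or `>` exactly as the
  tool states them (SBP < 80 mmHg, INR > 4, glucose < 50 / > 300 mg/dL,
  WBC < 3000/mm³, ANC < 1500/mm³, platelets < 50,000/mm³, Hgb < 10 g/dL,
  ALT > 84 U/L, Na < 130 mEq/L, K > 6.0 mEq/L, HR < 50, SBP > 180 or
  DBP > 110 mmHg). A boundary value (INR = 4.0) does not fire.
* **Missing data never fires.** A retrospective screen can only react to
  recorded values, so absence of a lab is evidence of nothing. This makes
  the engine monotone: removing data can only shrink a visit's fired set.
* **Adult gating.** T2 (nausea/vomiting), T18 (5-HT3 antagonists) and T22
  (antidiarrheals) apply only at `age >= 18` years (fractional ages
  compare numerically).

Two triggers are internal disjunctions (T6 blood-pressure, T11
leukopenia/neutropenia) and count at most once per visit. The
flumazenil trigger (T23) is conditional: it fires only when flumazenil is
ordered *without* concomitant midazolam, the reading that treats
midazolam reversal after procedural sedation as expected care. Co-presence
is assessed per visit; order timing is not modelled.

Some membership lists are inherently a local dialect: the tool names
"rash analogue terms" or "5-HT3 antagonist" without enumerating members,
and its diagnosis-code trigger rests on a 265-code list that is cited
rather than printed. The package ships documented defaults (keyword lists
chosen from standard clinical vocabulary; class members for the
medication triggers; synthetic placeholder code lists, `N17*` for acute
renal failure and a representative drug-induced/poisoning set including
the `T36`–`T50` prefixes) and treats all of them as configuration:
`load_trigger_set()` can override any field of any trigger from YAML or
JSON. Diagnosis matching defaults to prefix matching (`N17.9` matches a
configured `N17`), switchable to exact per trigger, because real
deployments differ in how deeply their coding truncates.

Keyword matching is exact token equality after lowercasing, not substring
search: `"rashes"` does not fire the rash trigger. This keeps false fires
auditable; synonym expansion belongs in the configured term list, not in
the matcher.

## Adjudication: what counts as a true ADE

Chart review assigns each visit a WHO-UMC causality level, a severity
(serious = hospitalisation or death, per the modified NCC-MERP index), and
Hallas-style preventability reasons (wrong drug, sub-/supra-therapeutic
dose, non-adherence). Two exclusions dominate everything: ADEs caused by
medications administered *in* the ED, and intentional overdose. An
excluded visit is never a case regardless of causality.

The inclusion gate "higher-than-possible causality" admits two readings —
{certain, probable} or {certain, probable, possible}. The package makes
the floor an explicit parameter of `is_true_ade()` rather than guessing;
the default is `"possible"`-and-above, the reading consistent with the
case volumes this tool was characterised with, and `"probable"` gives the
stricter gate. Raising the floor can only shrink the case count, a
property the tests check.

Dual review is supported as data plumbing only: identical labels pass
through, any disagreement becomes an explicit conflict row that
downstream classification refuses to consume. There is no automatic
tie-break, because consensus resolution is a human step.

## Evaluation statistics

Validation reviews a stratified random sample: simple random sampling
without replacement within the flagged and unflagged strata separately,
with stratum sizes `round-half-up(fraction × stratum size)` and a seeded,
restorable RNG (determinism given the seed is the reproducibility
contract; the original study's sample is not reconstructible). From the
sampled 2×2:

* sensitivity = tp/(tp+fn), specificity = tn/(fp+tn);
* PPV = confirmed/flagged, overall and per trigger — a visit firing
  several triggers counts in each denominator, so per-trigger
  denominators sum to more than the distinct flagged count;
* prevalence = ADEs/reviewed.

For the serious and preventable subgroups the positive class is the
subgroup and the negative class is *every other sampled visit*,
including ADEs outside the subgroup; this is the only convention that
reconciles subgroup specificity with the total-row specificity in the
published cross-tabulation.

Confidence intervals default to the Wilson score interval, which remains
sensible at the very small denominators a 28-trigger tool produces (one
trigger here has n = 6); Wald and Clopper–Pearson are selectable. The
published per-trigger interval widths are not reproducible by any
standard binomial method (n = 6 with a ±0.7-point interval), so the
package makes no attempt to match them; its intervals are tested instead
against exact enumeration of binomial coverage and against
`stats::binom.test`. Zero denominators raise errors rather than silent
`NaN`s. Group contrasts use the Pearson chi-square without continuity
correction (with Fisher's exact test alongside when expected cells are
small); on the published flagged-vs-unflagged preventability contrast
(17.3% vs 11.2%, n = 745 vs 214) this gives p ≈ 0.03, not the < 0.001
the source reports — the test actually used there is unstated, so the
package reports its own.

Displayed percentages round half-up to one decimal (`round_half_up()`),
matching how clinical tables are printed; base R's round-half-to-even
would disagree on exact ties.

## The synthetic generator

`generate_cohort()` draws, per visit: a visit reason (traffic-accident
and trauma visits are generated unadjudicated and unflaggable, mirroring
their exclusion upstream); a latent ADE status (default prevalence
0.058); and a flag intent conditional on it (0.777 given ADE, 0.296 =
1 − 0.704 given none — the pair that simultaneously reproduces the 32.0%
flag rate and 14.0% PPV the tool was characterised with, an internal
consistency check of those published numbers). Flagged visits draw
1 + Poisson(0.505) distinct triggers (mean ≈ 1.5, the observed ratio of
per-trigger fires to distinct flagged visits) with allocation weights
proportional to the observed per-trigger fire counts; adult-only triggers
are never allocated below the age cutoff, and mutually contradictory
pairs (glucose low/high, SBP low/high) are never co-assigned. Record
fields are then materialised uniformly inside each firing region (an INR
trigger draws INR in (4.1, 10)), while unflagged visits receive benign
values chosen to fire nothing. Serious and preventable indicators are
drawn independently given flag status (only marginals are available to
calibrate against: 0.352/0.206 serious, 0.173/0.112 preventable), and
adjudication columns are written consistently with the latent status.

What this emulates is the *statistical* structure the validation design
assumes — conditional flag rates, subgroup composition, multi-fire
behaviour. What it does not emulate: realistic joint distributions of
vitals and labs, correlated comorbidity, coding practice, or triggers
firing for clinically related reasons. Passing tests therefore
demonstrate that the pipeline's mechanics and statistics are correct
under the declared model, not that the tool performs at these levels on
any particular real population.

Age is truncated normal (mean 41.6, SD 25.9, clipped to [0, 105]) and sex
is Bernoulli(0.512 female), matching the published cohort description;
both are cosmetic for the statistics but keep the adult gate exercised.

Two deterministic fixtures complement the stochastic generator.
`fixture_flagging_cohort()` rebuilds the screening census: 76,724 visits
across four hospitals, 3700 traffic-accident and 6460 trauma exclusions,
and exactly 21,268 of the remaining 66,564 visits constructed to fire
(largest-remainder allocation across the 28 triggers, per-hospital flag
counts 4650/4441/6597/5580). `fixture_review_cohort()` rebuilds the
adjudicated review sample of 16,427 visits with the exact
cross-tabulation (745/4572/214/10,896, serious 262/44, preventable
129/24), so every headline metric — PPV 14.0%, sensitivity 77.7%,
specificity 70.4%, subgroup values 85.6/68.6 and 84.3/68.1, composition
35.2%/17.3% vs 20.6%/11.2% — is recomputed end-to-end by the engine and
evaluator rather than asserted. Hospital membership is encoded as a
`visit_id` prefix so the file dialect stays fixed. Note the review
fixture's unflagged stratum is 11,110 visits while stratified 25%
sampling of the census yields 11,324; the two published denominators
disagree by 214 visits with no stated reconciliation, and the package
follows the cross-tabulation for the fixture and the sampling arithmetic
for the sampler. The prevalence 959/16,641 = 5.8% is quoted on the
sampling denominator; the fixture's 959/16,427 rounds to the same value.

## Numerical and design choices

* One value per analyte per visit: whether that is first-recorded or
  worst-in-visit is upstream of the dialect, which carries a single
  number.
* Unit discipline at the boundary: lab column names carry units
  (`glucose_mgdl`); a header declaring a foreign unit is a fatal read
  error naming the expected unit, and conversion is the caller's duty.
* Cohorts round-trip bit-for-bit through CSV and JSON-lines; list-valued
  fields are semicolon-joined, missing is the empty cell / `null`.
* The engine is vectorised per trigger over the cohort; the per-record
  surface (`evaluate_predicate()`, `fire_triggers()`) wraps the same
  path, and a scalar brute-force interpreter exists only in the test
  suite as an independent oracle.
* Sampling preserves and restores the caller's RNG state, so a seeded
  draw does not perturb the surrounding analysis stream.
* Problem sizes in the test suite: engine-vs-oracle comparison on
  randomized cohorts of a few hundred visits, generator–engine
  consistency over 20 seeds at 250–500 visits, and one 200,000-visit
  cohort for parameter recovery judged at 3 binomial standard errors —
  sizes at which the binomial bounds are tight enough to be informative
  while the whole suite stays desk-scale.

## Known limitations

Keyword screening is token-exact and English-only; no NLP over narrative
text. Code-system translation (ICD-9 ↔ ICD-10) and ingredient
normalisation (RxNorm/ATC) are out of scope — lists are matched as
configured. The default diagnosis-code lists are placeholders, not the
cited 265-code list, and real deployments must supply their own. Temporal
logic (repeat labs, order timing within the visit) is not modelled.
Drug-induced falls and delirium — important geriatric ADE presentations —
have no trigger in this tool by design, and the generator inherits that
blind spot.
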