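# dredtt

Trigger-tool screening of emergency department (ED) visits for adverse
drug events (ADEs), for pharmacoepidemiologists and medication-safety
teams who need to find drug-related ED visits in flat visit-level data
without reviewing every chart.

A *trigger* is a cheap mechanical rule over a visit record — a
chief-complaint keyword, an abnormal vital sign or laboratory value, a
marker medication order, a diagnosis code — and a visit firing at least
one trigger is routed to in-depth chart review. `dredtt` implements the
28-trigger drug-related ED visit trigger tool (DrEDTT: 4 symptom, 3
vital-sign, 9 laboratory, 10 medication and 2 diagnosis-code triggers,
three of them adult-only), every rule configurable, plus the full
validation machinery around it:

- **screening engine** — `flag_cohort()` applies a trigger set to a
  cohort tibble; strict comparators, missing data never fires;
- **adjudication** — `is_true_ade()` / `classify_cases()` encode the
  WHO-UMC causality gate (floor parameterised), exclusions
  (ED-administered medication, intentional overdose), NCC-MERP-style
  severity (serious = hospitalisation or death) and Hallas
  preventability;
- **evaluation** — stratified review sampling and the screening-test
  statistics with binomial confidence intervals:

  sens = TP/(TP+FN), spec = TN/(FP+TN), PPV = confirmed/flagged,
  Wilson score CI by default;

- **synthetic cohorts** — `generate_cohort()` draws visits with a latent
  ADE status and conditional flag intent and materialises record fields
  that really fire the assigned triggers, so the whole pipeline is
  testable without patient data; two deterministic fixtures rebuild the
  published multi-center validation counts end to end.

Everything takes and returns tibbles; results have `tidy()`, `glance()`
and `autoplot()` methods.

## Worked example

Simulate a 20,000-visit cohort, screen it, and evaluate the tool against
the simulated gold standard with a 25% stratified review sample:

```r
library(dredtt)

sim    <- generate_cohort(generator_config(n_visits = 20000, seed = 42))
cohort <- exclude_nonmedical_visits(sim$cohort)   # drop traffic/trauma visits

flags <- flag_cohort(cohort, dredtt_triggers())
flags
#> <flag_summary> 5608/17372 visits flagged (32.3%)
#> top triggers: T17 (1153), T13 (1086), T2 (598), T3 (576), T6 (573)

metrics <- evaluate_cohort(cohort, fraction = 0.25, seed = 42)
metrics
#> <dredtt_metrics>
#>   screened: 5608/17372 flagged (32.3%)
#>   reviewed: 1402 flagged + 2941 unflagged (fraction 0.25)
#>   prevalence: 5.7%  PPV: 13.1%  sensitivity: 73.9%  specificity: 70.2%
```

32.3% of medical visits fire at least one trigger (the review workload
the tool implies); 5.7% of reviewed visits are true ADEs; 13.1% of
flagged-and-reviewed visits are confirmed (the yield per chart pulled);
and the screen catches 73.9% of the ADEs present in the sample. These
track the generator's configured operating characteristics (prevalence
0.058, sensitivity 0.777, specificity 0.704) up to sampling noise.
`glance(metrics)` returns the same numbers as a one-row tibble,
`tidy(metrics)` the full estimate table, and `autoplot(metrics)` a
per-trigger PPV forest plot. Single records work too:

```r
rec <- new_cohort(1)
rec$visit_id <- "v001"; rec$age <- 72; rec$sex <- "female"
rec$visit_reason <- "other"; rec$inr <- 5.1; rec$medications <- "vitamin k/iv"
fire_triggers(rec)
#> $visit_id
#> [1] "v001"
#> $fired
#> [1] "T8"  "T19"   # INR > 4; vitamin K ordered
#> $flagged
#> [1] TRUE
```

Cohorts are read and written in a fixed CSV / JSON-lines dialect
(`read_cohort()`, `write_cohort()`; unit-checked headers), and trigger
sets can be retuned from YAML/JSON (`load_trigger_set()`), including the
diagnosis-code lists, which ship as documented synthetic placeholders. A
thin command-line front end lives at `inst/cli/dredtt.R`
(`flag`, `evaluate`, `simulate`, `fixture` subcommands).

See `vignettes/dredtt-methods.Rmd` for the screening semantics,
adjudication model, evaluation conventions and the generator's design.

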