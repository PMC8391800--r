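trigs <- dredtt_triggers()
one <- function(id) trigs[trigs$trigger_id == id, ]

test_that("thresholds are strict and missing data never fires", {
  expect_true(evaluate_predicate(mini_record(inr = 4.5), one("T8")))
  expect_false(evaluate_predicate(mini_record(inr = 4.0), one("T8")))
  expect_false(evaluate_predicate(mini_record(), one("T8")))
  expect_true(evaluate_predicate(mini_record(sbp = 79, dbp = 50), one("T5")))
  expect_false(evaluate_predicate(mini_record(sbp = 80, dbp = 50), one("T5")))
  # either disjunct of a compound clause suffices
  expect_true(evaluate_predicate(mini_record(sbp = 190, dbp = 90), one("T6")))
  expect_true(evaluate_predicate(mini_record(sbp = 150, dbp = 111), one("T6")))
  expect_false(evaluate_predicate(mini_record(sbp = 180, dbp = 110), one("T6")))
  expect_true(evaluate_predicate(mini_record(wbc = 2900), one("T11")))
  expect_true(evaluate_predicate(mini_record(anc = 1400), one("T11")))
  expect_false(evaluate_predicate(mini_record(wbc = 3000, anc = 1500), one("T11")))
})

test_that("adult-only triggers gate on age >= cutoff with fractional ages", {
  kid <- mini_record(age = 10, medications = "ondansetron/iv")
  adult <- mini_record(age = 20, medications = "ondansetron/iv")
  expect_false(evaluate_predicate(kid, one("T18")))
  expect_true(evaluate_predicate(adult, one("T18")))
  expect_true(evaluate_predicate(mini_record(age = 18.0,
                                             medications = "ondansetron/iv"),
                                 one("T18")))
  expect_false(evaluate_predicate(mini_record(age = 17.9,
                                              symptom_terms = "nausea"),
                                  one("T2")))
  expect_true(evaluate_predicate(mini_record(age = 18.1,
                                             symptom_terms = "nausea"),
                                 one("T2")))
})

test_that("medication predicates respect route, concentration and co-orders", {
  expect_true(evaluate_predicate(mini_record(medications = "flumazenil/iv"),
                                 one("T23")))
  expect_false(evaluate_predicate(
    mini_record(medications = "flumazenil/iv;midazolam/iv"), one("T23")))
  expect_true(evaluate_predicate(mini_record(medications = "pantoprazole/iv"),
                                 one("T20")))
  expect_false(evaluate_predicate(mini_record(medications = "pantoprazole/po"),
                                  one("T20")))
  expect_true(evaluate_predicate(mini_record(medications = "dextrose@50/iv"),
                                 one("T21")))
  expect_false(evaluate_predicate(mini_record(medications = "dextrose@5/iv"),
                                  one("T21")))
  expect_true(evaluate_predicate(
    mini_record(medications = "sodium chloride@3/iv"), one("T25")))
  expect_false(evaluate_predicate(
    mini_record(medications = "sodium chloride@0.9/iv"), one("T25")))
})

test_that("keyword matching is case-insensitive exact token membership", {
  expect_true(evaluate_predicate(mini_record(symptom_terms = "RASH;fever"),
                                 one("T1")))
  # substring of a token is not a match
  expect_false(evaluate_predicate(mini_record(symptom_terms = "rashes"),
                                  one("T1")))
})

test_that("code lists consult the main (first) diagnosis only", {
  expect_true(evaluate_predicate(
    mini_record(diagnosis_codes = "N17.9;I10"), one("T27")))
  expect_false(evaluate_predicate(
    mini_record(diagnosis_codes = "I10;N17.9"), one("T27")))
  # prefix match by default, switchable to exact
  expect_true(evaluate_predicate(
    mini_record(diagnosis_codes = "T50.901"), one("T28")))
  exact <- load_trigger_set(list(triggers = list(
    list(trigger_id = "T27", params = list(match = "exact"))
  )))
  expect_false(evaluate_predicate(mini_record(diagnosis_codes = "N17.95"),
                                  exact[exact$trigger_id == "T27", ]))
  expect_true(evaluate_predicate(mini_record(diagnosis_codes = "N17.9"),
                                 exact[exact$trigger_id == "T27", ]))
})

test_that("fire_triggers returns the fired set with set semantics", {
  empty <- fire_triggers(mini_record())
  expect_equal(empty$fired, character())
  expect_false(empty$flagged)

  shock <- fire_triggers(mini_record(sbp = 70, dbp = 45, glucose_mgdl = 40))
  expect_true(all(c("T5", "T9") %in% shock$fired))
  expect_equal(anyDuplicated(shock$fired), 0)

  many <- fire_triggers(mini_record(
    inr = 5, glucose_mgdl = 40, wbc = 2000, platelet = 40000,
    hemoglobin_gdl = 9, alt_ul = 100, sodium_meql = 125, potassium_meql = 6.5
  ))
  expect_equal(sort(many$fired),
               sort(c("T8", "T9", "T11", "T12", "T13", "T14", "T15", "T16")))
})

test_that("flag_cohort aggregates completely and is order-invariant", {
  cohort <- random_cohort(200, seed = 5)
  fs <- flag_cohort(cohort)
  expect_equal(fs$n_total, 200)
  expect_equal(fs$n_flagged, sum(fs$results$flagged))
  expect_equal(nrow(fs$per_trigger_counts), 28)
  expect_equal(sum(purrr::map_int(fs$results$fired, length)),
               sum(fs$per_trigger_counts$n_fired))

  perm <- sample(nrow(cohort))
  fs2 <- flag_cohort(cohort[perm, ])
  expect_equal(dplyr::arrange(tidy(fs2), visit_id),
               dplyr::arrange(tidy(fs), visit_id))
  expect_equal(fs2$per_trigger_counts, fs$per_trigger_counts)

  empty <- flag_cohort(new_cohort(0))
  expect_equal(empty$n_total, 0)
  expect_true(all(empty$per_trigger_counts$n_fired == 0))
})

test_that("engine agrees with the brute-force per-record oracle", {
  set <- dredtt_triggers()
  for (seed in c(1, 2, 3)) {
    cohort <- random_cohort(400, seed = seed)
    fs <- flag_cohort(cohort, set)
    for (i in seq_len(nrow(cohort))) {
      expect_identical(sort(fs$results$fired[[i]]),
                       sort(oracle_fired(cohort[i, ], set)),
                       label = paste0("seed ", seed, " row ", i))
    }
  }
})

test_that("screening is monotone in the trigger set and in the data", {
  cohort <- random_cohort(150, seed = 9)
  full <- flag_cohort(cohort)
  reduced <- dredtt_triggers()[1:20, ]
  attr(reduced, "set_name") <- "reduced"
  attr(reduced, "adult_age_cutoff") <- 18
  class(reduced) <- c("trigger_set", class(tibble::tibble()))
  part <- flag_cohort(cohort, reduced)
  for (i in seq_len(nrow(cohort))) {
    expect_true(all(part$results$fired[[i]] %in% full$results$fired[[i]]))
  }
  # blanking data never adds a fire
  blanked <- cohort
  blanked$inr <- NA_real_
  blanked$medications <- NA_character_
  fs_blank <- flag_cohort(blanked)
  for (i in seq_len(nrow(cohort))) {
    expect_true(all(fs_blank$results$fired[[i]] %in% full$results$fired[[i]]))
  }
})

test_that("tidy and glance views reconcile with the summary", {
  cohort <- random_cohort(100, seed = 21)
  fs <- flag_cohort(cohort)
  td <- tidy(fs)
  expect_equal(sum(td$flagged), fs$n_flagged)
  expect_equal(sum(td$n_fired), sum(fs$per_trigger_counts$n_fired))
  gl <- glance(fs)
  expect_equal(gl$flag_rate, fs$n_flagged / fs$n_total)
})
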