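# minimal valid record with fields overridable by name
mini_record <- function(visit_id = "v1", age = 40, sex = "female",
                        visit_reason = "other", ...) {
  rec <- new_cohort(1)
  rec$visit_id <- visit_id
  rec$age <- age
  rec$sex <- sex
  rec$visit_reason <- visit_reason
  dots <- list(...)
  for (nm in names(dots)) rec[[nm]] <- dots[[nm]]
  rec
}

mini_cohort <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(rows)
}

# random cohorts spanning firing boundaries, missing data and odd combos
random_cohort <- function(n, seed) {
  set.seed(seed)
  maybe <- function(v, p = 0.6) ifelse(runif(n) < p, v, NA_real_)
  df <- new_cohort(n)
  df$visit_id <- sprintf("rc%05d", seq_len(n))
  df$age <- round(runif(n, 0, 95), 1)
  df$sex <- sample(c("female", "male", "unknown"), n, TRUE)
  df$visit_reason <- sample(c("other", "trauma", "traffic_accident"), n, TRUE,
                            prob = c(0.8, 0.1, 0.1))
  vocab <- c("rash", "nausea", "vomiting", "bleeding", "palpitation",
             "fever", "headache", "pruritus", "melena", "dizziness")
  df$symptom_terms <- vapply(seq_len(n), function(i) {
    k <- sample(0:3, 1)
    if (k == 0) NA_character_ else paste(sample(vocab, k), collapse = ";")
  }, character(1))
  df$sbp <- maybe(round(runif(n, 60, 220)))
  df$dbp <- ifelse(is.na(df$sbp), NA_real_,
                   pmin(df$sbp, round(runif(n, 40, 130))))
  df$heart_rate <- maybe(round(runif(n, 35, 130)))
  df$inr <- maybe(round(runif(n, 0.8, 6), 1))
  df$glucose_mgdl <- maybe(round(runif(n, 30, 400)))
  df$wbc <- maybe(round(runif(n, 1000, 15000)))
  df$anc <- maybe(round(runif(n, 500, 8000)))
  df$platelet <- maybe(round(runif(n, 20000, 450000)))
  df$hemoglobin_gdl <- maybe(round(runif(n, 6, 17), 1))
  df$alt_ul <- maybe(round(runif(n, 5, 200)))
  df$sodium_meql <- maybe(round(runif(n, 120, 150)))
  df$potassium_meql <- maybe(round(runif(n, 3, 7), 1))
  meds_pool <- c("chlorpheniramine/iv", "ondansetron/po", "vitamin k/iv",
                 "pantoprazole/iv", "pantoprazole/po", "dextrose@50/iv",
                 "dextrose@5/iv", "loperamide/po", "flumazenil/iv",
                 "midazolam/iv", "dimenhydrinate/iv", "sodium chloride@3/iv",
                 "sodium chloride@0.9/iv", "polystyrene sulfonate calcium/po",
                 "acetaminophen/po")
  df$medications <- vapply(seq_len(n), function(i) {
    k <- sample(0:3, 1)
    if (k == 0) NA_character_ else paste(sample(meds_pool, k), collapse = ";")
  }, character(1))
  dx_pool <- c("N17.9", "T50.9", "J06.9", "I10", "K29.7", "A09", "R51",
               "L27.0", "N18.5")
  df$diagnosis_codes <- vapply(seq_len(n), function(i) {
    k <- sample(0:2, 1)
    if (k == 0) NA_character_ else paste(sample(dx_pool, k), collapse = ";")
  }, character(1))
  df
}

# Brute-force reference screen: a scalar per-record interpreter of the
# declarative rules with its own parsing, independent of the vectorised
# engine path.
oracle_fired <- function(record, set) {
  cutoff <- attr(set, "adult_age_cutoff")
  lab_col <- c(inr = "inr", glucose = "glucose_mgdl", wbc = "wbc",
               anc = "anc", platelet = "platelet",
               hemoglobin = "hemoglobin_gdl", alt = "alt_ul",
               sodium = "sodium_meql", potassium = "potassium_meql")
  toks <- function(x) {
    if (is.na(x)) return(character())
    out <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    out[nzchar(out)]
  }
  meds <- lapply(toks(record$medications), function(tok) {
    tok <- tolower(tok)
    route <- "unknown"; pct <- NA_real_
    if (grepl("/", tok, fixed = TRUE)) {
      route <- sub("^.*/", "", tok)
      tok <- sub("/[^/]*$", "", tok)
    }
    if (grepl("@", tok, fixed = TRUE)) {
      pct <- as.numeric(sub("^.*@", "", tok))
      tok <- sub("@.*$", "", tok)
    }
    list(ing = trimws(tok), pct = pct, route = route)
  })
  symptoms <- tolower(toks(record$symptom_terms))
  dx <- toupper(toks(record$diagnosis_codes))
  main_dx <- if (length(dx)) dx[[1]] else NA_character_
  thr <- function(domain, analyte, comp, cut) {
    val <- if (domain == "vital") record[[analyte]]
           else record[[lab_col[[analyte]]]]
    if (is.na(val)) return(FALSE)
    if (comp == "<") val < cut else val > cut
  }
  med_hit <- function(ings, pcts = NULL, route = NULL) {
    any(vapply(meds, function(m) {
      ok <- m$ing %in% ings
      if (!is.null(pcts)) ok <- ok && !is.na(m$pct) && m$pct %in% pcts
      if (!is.null(route)) ok <- ok && m$route %in% route
      ok
    }, logical(1)))
  }
  fired <- character()
  for (i in seq_len(nrow(set))) {
    p <- set$params[[i]]
    hit <- switch(set$kind[i],
      keyword = any(symptoms %in% p$terms),
      vital_threshold = thr("vital", p$analyte, p$comparator, p$cutoff),
      lab_threshold = thr("lab", p$analyte, p$comparator, p$cutoff),
      compound_threshold = any(vapply(p$clauses, function(cl) {
        thr(cl$domain, cl$analyte, cl$comparator, cl$cutoff)
      }, logical(1))),
      medication_list = med_hit(p$ingredients, p$concentration_pct, p$route),
      medication_conditional = med_hit(p$target) && !med_hit(p$forbidden),
      code_list = !is.na(main_dx) &&
        any(vapply(p$codes, function(cd) startsWith(main_dx, cd), logical(1)))
    )
    if (set$adult_only[i]) hit <- hit && !is.na(record$age) &&
        record$age >= cutoff
    if (isTRUE(hit)) fired <- c(fired, set$trigger_id[i])
  }
  fired
}

# a flag_summary built directly from a flagged indicator, for tests that
# exercise sampling/metrics without running the engine
fake_flag_summary <- function(visit_id, flagged,
                              fired = NULL) {
  if (is.null(fired)) {
    fired <- ifelse(flagged, "T1", "")
    fired <- lapply(fired, function(x) if (nzchar(x)) x else character())
  }
  per <- table(factor(unlist(fired), levels = sort(unique(unlist(fired)))))
  structure(
    list(
      results = tibble::tibble(visit_id = visit_id, fired = fired,
                               flagged = flagged),
      n_total = length(visit_id),
      n_flagged = sum(flagged),
      per_trigger_counts = tibble::tibble(
        trigger_id = names(per), n_fired = as.integer(per)
      )
    ),
    class = "flag_summary"
  )
}
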