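# Declarative trigger rules --------------------------------------------
#
# A trigger is a predicate over one ED-visit record. Seven predicate kinds
# cover the whole default tool:
#   keyword              any chief-complaint token in a term list
#   vital_threshold      one vital sign vs a strict cutoff
#   lab_threshold        one laboratory analyte vs a strict cutoff
#   compound_threshold   disjunction of threshold clauses (vital or lab)
#   medication_list      any listed ingredient ordered in the ED, with
#                        optional concentration and required route
#   medication_conditional  target ingredient present, forbidden co-order absent
#   code_list            main discharge diagnosis in a code set
# All comparators are strict (< or >): boundary values never fire.

PREDICATE_KINDS <- c("keyword", "vital_threshold", "lab_threshold",
                     "compound_threshold", "medication_list",
                     "medication_conditional", "code_list")
TRIGGER_CATEGORIES <- c("symptom", "vital_sign", "laboratory",
                        "medication", "diagnosis_code")

new_trigger_set <- function(triggers, name, adult_age_cutoff = 18) {
  out <- tibble::as_tibble(triggers)
  structure(out,
            class = c("trigger_set", class(out)),
            set_name = name,
            adult_age_cutoff = adult_age_cutoff)
}

#' @export
print.trigger_set <- function(x, ...) {
  cat("<trigger_set> ", attr(x, "set_name"),
      " (", nrow(x), " triggers, adult cutoff ",
      attr(x, "adult_age_cutoff"), " y)\n", sep = "")
  NextMethod()
}

threshold_clause <- function(domain, analyte, comparator, cutoff, unit) {
  list(domain = domain, analyte = analyte, comparator = comparator,
       cutoff = cutoff, unit = unit)
}

trig <- function(trigger_id, category, label, kind, adult_only = FALSE, ...) {
  tibble::tibble(
    trigger_id = trigger_id, category = category, label = label,
    kind = kind, adult_only = adult_only,
    params = list(normalize_params(kind, list(...)))
  )
}

# coerce config-supplied params to canonical types so that a set written to
# disk and reloaded compares equal to one built in code
normalize_params <- function(kind, params) {
  chrfield <- function(x) as.character(unlist(x))
  switch(kind,
    keyword = list(terms = stringr::str_to_lower(chrfield(params$terms))),
    vital_threshold = ,
    lab_threshold = list(
      analyte = as.character(params$analyte),
      comparator = as.character(params$comparator),
      cutoff = as.numeric(params$cutoff),
      unit = as.character(params$unit)
    ),
    compound_threshold = list(
      clauses = purrr::map(params$clauses, function(cl) {
        threshold_clause(as.character(cl$domain), as.character(cl$analyte),
                         as.character(cl$comparator), as.numeric(cl$cutoff),
                         as.character(cl$unit))
      })
    ),
    medication_list = {
      pct <- as.numeric(unlist(params$concentration_pct))
      route <- as.character(unlist(params$route))
      list(
        ingredients = stringr::str_to_lower(chrfield(params$ingredients)),
        concentration_pct = if (length(pct) == 0) NULL else pct,
        route = if (length(route) == 0) NULL else route
      )
    },
    medication_conditional = list(
      target = stringr::str_to_lower(as.character(params$target)),
      forbidden = stringr::str_to_lower(as.character(params$forbidden))
    ),
    code_list = list(
      codes = toupper(chrfield(params$codes)),
      match = (params$match %||% "prefix")
    ),
    abort(paste0("unknown predicate kind '", kind, "'"))
  )
}

# Placeholder diagnosis-code lists. The published tool's diagnosis-code
# trigger draws on a 265-code list that is cited but not printed; these
# synthetic defaults are representative and meant to be replaced through
# the trigger-set config in any real deployment.
T27_DEFAULT_CODES <- c("N17", "N17.0", "N17.1", "N17.2", "N17.8", "N17.9")
T28_DEFAULT_CODES <- c(
  "D59.0", "D61.1", "D64.2", "E03.2", "E06.4", "E16.0", "E23.1", "E24.2",
  "E27.3", "G21.1", "G24.0", "G25.1", "G25.4", "G25.6", "G44.4", "G62.0",
  "G72.0", "I95.2", "J70.2", "J70.3", "J70.4", "K71", "L10.5", "L27.0",
  "L27.1", "M10.2", "M32.0", "M80.4", "M81.4", "M87.1", "N14.0", "N14.1",
  "N14.2", "R50.2", paste0("T", 36:50), "Y57.9"
)

#' The default DrEDTT trigger set
#'
#' Builds the 28-trigger drug-related ED visit trigger tool: four symptom
#' keyword triggers, three vital-sign thresholds, nine laboratory
#' thresholds, ten marker-medication triggers, and two diagnosis-code
#' triggers. Three triggers (T2 nausea/vomiting, T18 5-HT3 antagonists,
#' T22 antidiarrheals) apply only to adults (age >= 18 years). All
#' numeric comparators are strict, so boundary values (for example
#' INR = 4.0 exactly) do not fire.
#'
#' Keyword term lists and medication class memberships are a documented
#' dialect choice (the tool's categories name classes, not members) and the
#' diagnosis-code lists are synthetic placeholders; all are overridable via
#' [load_trigger_set()].
#'
#' @param adult_age_cutoff Age in years at and above which the adult-only
#'   triggers apply (default 18).
#' @return A `trigger_set`: a tibble with columns `trigger_id`, `category`,
#'   `label`, `kind`, `adult_only` and a `params` list-column.
#' @examples
#' dredtt_triggers()
#' @export
dredtt_triggers <- function(adult_age_cutoff = 18) {
  rows <- dplyr::bind_rows(
    trig("T1", "symptom", "\"rash\" analogue term", "keyword",
         terms = c("rash", "urticaria", "hives", "itching", "pruritus")),
    trig("T2", "symptom", "nausea or vomiting", "keyword", adult_only = TRUE,
         terms = c("nausea", "vomiting")),
    trig("T3", "symptom", "\"bleeding\" analogue term", "keyword",
         terms = c("bleeding", "hemorrhage", "melena", "hematochezia",
                   "epistaxis", "hematemesis")),
    trig("T4", "symptom", "palpitation", "keyword",
         terms = c("palpitation", "palpitations")),

    trig("T5", "vital_sign", "systolic blood pressure < 80 mmHg",
         "vital_threshold",
         analyte = "sbp", comparator = "<", cutoff = 80, unit = "mmHg"),
    trig("T6", "vital_sign", "SBP > 180 mmHg or DBP > 110 mmHg",
         "compound_threshold",
         clauses = list(
           threshold_clause("vital", "sbp", ">", 180, "mmHg"),
           threshold_clause("vital", "dbp", ">", 110, "mmHg")
         )),
    trig("T7", "vital_sign", "heart rate < 50 /min", "vital_threshold",
         analyte = "heart_rate", comparator = "<", cutoff = 50,
         unit = "beats/min"),

    trig("T8", "laboratory", "INR > 4", "lab_threshold",
         analyte = "inr", comparator = ">", cutoff = 4,
         unit = "dimensionless"),
    trig("T9", "laboratory", "blood glucose < 50 mg/dL", "lab_threshold",
         analyte = "glucose", comparator = "<", cutoff = 50, unit = "mg/dL"),
    trig("T10", "laboratory", "blood glucose > 300 mg/dL", "lab_threshold",
         analyte = "glucose", comparator = ">", cutoff = 300, unit = "mg/dL"),
    trig("T11", "laboratory", "WBC < 3000/mm3 or ANC < 1500/mm3",
         "compound_threshold",
         clauses = list(
           threshold_clause("lab", "wbc", "<", 3000, "cells/mm3"),
           threshold_clause("lab", "anc", "<", 1500, "cells/mm3")
         )),
    trig("T12", "laboratory", "platelet < 50,000/mm3", "lab_threshold",
         analyte = "platelet", comparator = "<", cutoff = 50000,
         unit = "cells/mm3"),
    trig("T13", "laboratory", "hemoglobin < 10 g/dL", "lab_threshold",
         analyte = "hemoglobin", comparator = "<", cutoff = 10, unit = "g/dL"),
    trig("T14", "laboratory", "ALT > 84 U/L", "lab_threshold",
         analyte = "alt", comparator = ">", cutoff = 84, unit = "U/L"),
    trig("T15", "laboratory", "serum sodium < 130 mEq/L", "lab_threshold",
         analyte = "sodium", comparator = "<", cutoff = 130, unit = "mEq/L"),
    trig("T16", "laboratory", "serum potassium > 6.0 mEq/L", "lab_threshold",
         analyte = "potassium", comparator = ">", cutoff = 6, unit = "mEq/L"),

    trig("T17", "medication", "chlorpheniramine or hydroxyzine",
         "medication_list",
         ingredients = c("chlorpheniramine", "hydroxyzine")),
    trig("T18", "medication", "5-HT3 antagonist", "medication_list",
         adult_only = TRUE,
         ingredients = c("ondansetron", "granisetron", "palonosetron",
                         "ramosetron")),
    trig("T19", "medication", "vitamin K", "medication_list",
         ingredients = c("vitamin k", "phytonadione")),
    trig("T20", "medication", "intravenous proton pump inhibitor",
         "medication_list",
         ingredients = c("pantoprazole", "esomeprazole", "lansoprazole",
                         "omeprazole"),
         route = "iv"),
    trig("T21", "medication", "10% or 50% dextrose", "medication_list",
         ingredients = "dextrose", concentration_pct = c(10, 50)),
    trig("T22", "medication", "loperamide, smectite or rifaximin",
         "medication_list", adult_only = TRUE,
         ingredients = c("loperamide", "smectite", "rifaximin")),
    trig("T23", "medication", "flumazenil without concomitant midazolam",
         "medication_conditional",
         target = "flumazenil", forbidden = "midazolam"),
    trig("T24", "medication", "dimenhydrinate", "medication_list",
         ingredients = "dimenhydrinate"),
    trig("T25", "medication", "3% sodium chloride", "medication_list",
         ingredients = "sodium chloride", concentration_pct = 3),
    trig("T26", "medication", "polystyrene sulfonate calcium",
         "medication_list",
         ingredients = c("polystyrene sulfonate calcium",
                         "calcium polystyrene sulfonate")),

    trig("T27", "diagnosis_code", "diagnosis codes of acute renal failure",
         "code_list", codes = T27_DEFAULT_CODES),
    trig("T28", "diagnosis_code", "diagnosis codes for drug-induced disease",
         "code_list", codes = T28_DEFAULT_CODES)
  )
  new_trigger_set(rows, name = "DrEDTT-28",
                  adult_age_cutoff = adult_age_cutoff)
}

#' Load a trigger set from a YAML or JSON config
#'
#' Entries in the config override or extend a base set by `trigger_id`;
#' fields (including individual `params` components) not given in an entry
#' are inherited from the base. A config may therefore retune a single
#' cutoff, swap a code list, or define an entirely new trigger. Supplying
#' `base = NULL` builds the set from the config alone.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config, or an equivalent
#'   already-parsed list with components `name`, `adult_age_cutoff`, and
#'   `triggers` (a list of entries).
#' @param base Trigger set to inherit from; default [dredtt_triggers()].
#' @return A validated `trigger_set`.
#' @export
load_trigger_set <- function(path, base = dredtt_triggers()) {
  cfg <- if (is.list(path)) {
    path
  } else if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }

  rows <- if (is.null(base)) {
    tibble::tibble(trigger_id = character(), category = character(),
                   label = character(), kind = character(),
                   adult_only = logical(), params = list())
  } else {
    tibble::as_tibble(base)
  }
  name <- cfg$name %||% (if (is.null(base)) "custom" else attr(base, "set_name"))
  cutoff <- cfg$adult_age_cutoff %||%
    (if (is.null(base)) 18 else attr(base, "adult_age_cutoff"))

  for (entry in cfg$triggers %||% list()) {
    id <- entry$trigger_id
    if (is.null(id)) abort("config entry without trigger_id")
    idx <- if (nrow(rows) > 0) which(rows$trigger_id == id) else integer()
    if (length(idx) == 1) {
      old <- rows[idx, ]
      kind <- entry$kind %||% old$kind
      params <- old$params[[1]]
      if (!identical(kind, old$kind)) params <- list()
      params <- utils::modifyList(params, entry$params %||% list())
      rows$kind[idx] <- kind
      rows$category[idx] <- entry$category %||% old$category
      rows$label[idx] <- entry$label %||% old$label
      rows$adult_only[idx] <- entry$adult_only %||% old$adult_only
      rows$params[[idx]] <- with_entry_context(id, normalize_params(kind, params))
    } else {
      for (req in c("kind", "category", "label")) {
        if (is.null(entry[[req]])) {
          abort(paste0("config entry '", id, "': missing field '", req, "'"))
        }
      }
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        trigger_id = id, category = entry$category, label = entry$label,
        kind = entry$kind, adult_only = entry$adult_only %||% FALSE,
        params = list(with_entry_context(
          id, normalize_params(entry$kind, entry$params %||% list())
        ))
      ))
    }
  }

  set <- new_trigger_set(rows, name = name, adult_age_cutoff = cutoff)
  findings <- validate_trigger_set(set)
  fatal <- findings[findings$severity == "error", , drop = FALSE]
  if (nrow(fatal) > 0) {
    abort(c("invalid trigger set",
            paste0(fatal$trigger_id, ": ", fatal$detail)))
  }
  set
}

with_entry_context <- function(id, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("config entry '", id, "': ", conditionMessage(e)))
  })
}

#' Serialize a trigger set to a config file
#'
#' Writes the full definition of every trigger so that
#' `load_trigger_set(path, base = NULL)` reproduces the set exactly.
#'
#' @param set A `trigger_set`.
#' @param path Output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_trigger_set <- function(set, path) {
  entries <- purrr::pmap(
    list(set$trigger_id, set$category, set$label, set$kind,
         set$adult_only, set$params),
    function(id, category, label, kind, adult_only, params) {
      list(trigger_id = id, category = category, label = label,
           kind = kind, adult_only = adult_only, params = params)
    }
  )
  cfg <- list(
    name = attr(set, "set_name"),
    adult_age_cutoff = attr(set, "adult_age_cutoff"),
    triggers = entries
  )
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Check a trigger set for structural problems
#'
#' Reports findings rather than raising: duplicate trigger ids, unknown
#' predicate kinds, non-strict comparators, empty term/ingredient/code
#' lists, unknown analytes, and (informationally) diagnosis codes shared
#' between code-list triggers. An empty result means the set is valid.
#'
#' @param set A `trigger_set`.
#' @return A tibble with columns `severity` (`"error"` or `"info"`),
#'   `trigger_id`, and `detail`; zero rows when nothing was found.
#' @export
validate_trigger_set <- function(set) {
  findings <- tibble::tibble(severity = character(), trigger_id = character(),
                             detail = character())
  add <- function(severity, id, detail) {
    findings <<- dplyr::bind_rows(findings, tibble::tibble(
      severity = severity, trigger_id = id, detail = detail))
  }

  dup <- unique(set$trigger_id[duplicated(set$trigger_id)])
  for (id in dup) add("error", id, "duplicate trigger_id")

  check_clause <- function(id, domain, analyte, comparator) {
    if (!comparator %in% c("<", ">")) {
      add("error", id, paste0("comparator must be strict (< or >), got '",
                              comparator, "'"))
    }
    known <- if (domain == "vital") VITAL_COLS else names(LAB_COLS)
    if (!analyte %in% known) {
      add("error", id, paste0("unknown ", domain, " analyte '", analyte, "'"))
    }
  }

  for (i in seq_len(nrow(set))) {
    id <- set$trigger_id[i]
    kind <- set$kind[i]
    p <- set$params[[i]]
    if (!kind %in% PREDICATE_KINDS) {
      add("error", id, paste0("unknown predicate kind '", kind, "'"))
      next
    }
    if (!set$category[i] %in% TRIGGER_CATEGORIES) {
      add("error", id, paste0("unknown category '", set$category[i], "'"))
    }
    switch(kind,
      keyword = if (length(p$terms) == 0) add("error", id, "empty term list"),
      vital_threshold = check_clause(id, "vital", p$analyte, p$comparator),
      lab_threshold = check_clause(id, "lab", p$analyte, p$comparator),
      compound_threshold = {
        if (length(p$clauses) == 0) add("error", id, "no clauses")
        for (cl in p$clauses) check_clause(id, cl$domain, cl$analyte,
                                           cl$comparator)
      },
      medication_list = if (length(p$ingredients) == 0) {
        add("error", id, "empty ingredient list")
      },
      medication_conditional = {
        if (!nzchar(p$target %||% "")) add("error", id, "missing target")
        if (!nzchar(p$forbidden %||% "")) add("error", id, "missing forbidden co-order")
      },
      code_list = if (length(p$codes) == 0) add("error", id, "empty code list")
    )
  }

  code_rows <- which(set$kind == "code_list")
  if (length(code_rows) > 1) {
    pairs <- utils::combn(code_rows, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      shared <- intersect(set$params[[a]]$codes, set$params[[b]]$codes)
      if (length(shared) > 0) {
        add("info", paste(set$trigger_id[a], set$trigger_id[b], sep = "+"),
            paste0("code lists share: ", paste(shared, collapse = ", ")))
      }
    }
  }
  findings
}
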