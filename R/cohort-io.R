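# Flat ED-visit cohort dialect ------------------------------------------
#
# One row per ED encounter. List-valued fields (symptom terms, medications,
# diagnosis codes, adjudication reasons) are semicolon-joined strings so a
# cohort round-trips bit-for-bit through CSV or JSON-lines. Laboratory
# column names carry the unit they must be expressed in (glucose_mgdl is
# mg/dL and nothing else); unit conversion is the caller's duty and is
# enforced at read time by the header check.

SEX_LEVELS <- c("female", "male", "unknown")
REASON_LEVELS <- c("traffic_accident", "trauma", "other")
CAUSALITY_LEVELS <- c("certain", "probable", "possible", "unlikely",
                      "unassessable", "none")
SEVERITY_LEVELS <- c("serious", "moderate", "mild", "none")
PREVENTABILITY_REASONS <- c("wrong_drug", "subtherapeutic_dose",
                            "supratherapeutic_dose", "nonadherence")
EXCLUSION_REASONS <- c("ed_administered_medication", "intentional_overdose")

VITAL_COLS <- c("sbp", "dbp", "heart_rate")
LAB_COLS <- c(
  inr = "inr", glucose = "glucose_mgdl", wbc = "wbc", anc = "anc",
  platelet = "platelet", hemoglobin = "hemoglobin_gdl", alt = "alt_ul",
  sodium = "sodium_meql", potassium = "potassium_meql"
)
LAB_UNITS <- c(
  inr = "dimensionless", glucose = "mg/dL", wbc = "cells/mm3",
  anc = "cells/mm3", platelet = "cells/mm3", hemoglobin = "g/dL",
  alt = "U/L", sodium = "mEq/L", potassium = "mEq/L"
)

COHORT_COLS <- c(
  "visit_id", "age", "sex", "visit_reason", "symptom_terms",
  VITAL_COLS, unname(LAB_COLS), "medications", "diagnosis_codes"
)
ADJUDICATION_COLS <- c("causality", "severity", "preventability_reasons",
                       "exclusion_reasons")

cohort_col_types <- function() {
  chr <- c("visit_id", "sex", "visit_reason", "symptom_terms",
           "medications", "diagnosis_codes", ADJUDICATION_COLS)
  types <- setNames(
    ifelse(c(COHORT_COLS, ADJUDICATION_COLS) %in% chr, "c", "d"),
    c(COHORT_COLS, ADJUDICATION_COLS)
  )
  types
}

#' Empty ED-visit cohort template
#'
#' Returns a zero-row tibble with every column of the cohort dialect
#' (including the optional adjudication columns), useful as a starting
#' point when assembling cohorts programmatically.
#'
#' @param n Number of blank rows to pre-allocate (default 0).
#' @return A tibble with the full cohort column set.
#' @export
new_cohort <- function(n = 0) {
  types <- cohort_col_types()
  cols <- purrr::imap(types, function(ty, nm) {
    if (ty == "c") rep(NA_character_, n) else rep(NA_real_, n)
  })
  tibble::as_tibble(cols)
}

check_cohort_header <- function(found) {
  missing <- setdiff(COHORT_COLS, found)
  extra <- setdiff(found, c(COHORT_COLS, ADJUDICATION_COLS))
  msgs <- character()
  # a lab analyte under a foreign unit suffix is the classic failure mode:
  # name the unit the dialect expects rather than just "unknown column"
  for (col in extra) {
    stem <- sub("_.*$", "", col)
    hit <- names(LAB_COLS)[names(LAB_COLS) == stem | LAB_COLS == stem]
    if (length(hit) == 1) {
      msgs <- c(msgs, paste0(
        "column '", col, "': analyte '", hit, "' must be expressed in ",
        LAB_UNITS[[hit]], " under the column name '", LAB_COLS[[hit]], "'"
      ))
    } else {
      msgs <- c(msgs, paste0("unknown column '", col, "'"))
    }
  }
  if (length(missing) > 0) {
    msgs <- c(msgs, paste0("missing required column(s): ",
                           paste(missing, collapse = ", ")))
  }
  if (length(msgs) > 0) {
    abort(c("cohort header does not match the dialect", msgs))
  }
  invisible(found)
}

#' Validate an ED-visit cohort
#'
#' Checks a cohort tibble against the dialect invariants: required columns
#' and types, unique non-missing `visit_id`, non-negative `age`, categorical
#' fields within their vocabularies, strictly positive vitals and labs with
#' `dbp <= sbp`, parseable medication tokens, and (when adjudication columns
#' are populated) legal causality/severity levels and reason tokens. All
#' problems are collected and reported together, each naming the offending
#' `visit_id` and field.
#'
#' @param cohort A cohort tibble in the dialect of [new_cohort()].
#' @return The cohort, invisibly, if valid; otherwise an error listing every
#'   record-level problem.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) abort("cohort must be a data frame")
  check_cohort_header(intersect(names(cohort), c(COHORT_COLS, ADJUDICATION_COLS)))
  cohort <- tibble::as_tibble(cohort)

  problems <- character()
  note <- function(ids, field, why) {
    if (length(ids) == 0) return()
    shown <- paste(head(ids, 5), collapse = ", ")
    if (length(ids) > 5) shown <- paste0(shown, ", ... (", length(ids), " records)")
    problems <<- c(problems, paste0(field, ": ", why, " [visit_id: ", shown, "]"))
  }
  id <- cohort$visit_id

  note(id[is.na(id) | !nzchar(id)], "visit_id", "missing or empty")
  dup <- id[duplicated(id) & !is.na(id)]
  note(unique(dup), "visit_id", "duplicated within cohort")
  note(id[is.na(cohort$age)], "age", "missing")
  note(id[!is.na(cohort$age) & cohort$age < 0], "age", "negative")
  note(id[!cohort$sex %in% SEX_LEVELS], "sex",
       paste0("must be one of ", paste(SEX_LEVELS, collapse = "/")))
  note(id[!cohort$visit_reason %in% REASON_LEVELS], "visit_reason",
       paste0("must be one of ", paste(REASON_LEVELS, collapse = "/")))

  for (v in VITAL_COLS) {
    bad <- !is.na(cohort[[v]]) & cohort[[v]] <= 0
    note(id[bad], v, "must be strictly positive when present")
  }
  both <- !is.na(cohort$sbp) & !is.na(cohort$dbp)
  note(id[both & cohort$dbp > cohort$sbp], "dbp", "exceeds sbp")
  for (lab in unname(LAB_COLS)) {
    bad <- !is.na(cohort[[lab]]) & cohort[[lab]] <= 0
    note(id[bad], lab, "must be strictly positive when present")
  }

  meds_long <- parse_medications_long(cohort$medications)
  note(unique(id[meds_long$row[!meds_long$ok]]), "medications",
       "unparseable token(s)")

  if ("causality" %in% names(cohort)) {
    has <- !is.na(cohort$causality)
    note(id[has & !cohort$causality %in% CAUSALITY_LEVELS], "causality",
         paste0("must be one of ", paste(CAUSALITY_LEVELS, collapse = "/")))
  }
  if ("severity" %in% names(cohort)) {
    has <- !is.na(cohort$severity)
    note(id[has & !cohort$severity %in% SEVERITY_LEVELS], "severity",
         paste0("must be one of ", paste(SEVERITY_LEVELS, collapse = "/")))
  }
  for (col in c("preventability_reasons", "exclusion_reasons")) {
    if (!col %in% names(cohort)) next
    allowed <- if (col == "preventability_reasons") PREVENTABILITY_REASONS else EXCLUSION_REASONS
    ok <- purrr::map_lgl(split_tokens(cohort[[col]]),
                         function(tok) all(tok %in% allowed))
    note(id[!ok], col,
         paste0("tokens must be within {", paste(allowed, collapse = ", "), "}"))
  }

  if (length(problems) > 0) {
    abort(c("cohort validation failed", problems))
  }
  invisible(cohort)
}

#' Read an ED-visit cohort
#'
#' Reads a cohort file in the package's flat dialect (see [new_cohort()] for
#' the column set) and validates every record. The header is checked against
#' the dialect's fixed unit system: a laboratory column declared under a
#' different unit (for example glucose in mmol/L) is a fatal error naming
#' the expected unit.
#'
#' @param path Path to the cohort file.
#' @param format `"csv"` or `"jsonl"`; guessed from the file extension when
#'   omitted.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, format = c("guess", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.jsonl$|\\.ndjson$", path)) "jsonl" else "csv"
  }
  if (!file.exists(path)) abort(paste0("no such cohort file: ", path))

  if (format == "csv") {
    header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
    check_cohort_header(header)
    types <- cohort_col_types()[header]
    cohort <- readr::read_csv(
      path,
      col_types = paste(types, collapse = ""),
      na = c("", "NA"), show_col_types = FALSE
    )
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- purrr::map(lines, function(l) {
      rec <- jsonlite::fromJSON(l, simplifyVector = TRUE)
      rec[purrr::map_lgl(rec, is.null)] <- NA
      tibble::as_tibble(rec)
    })
    cohort <- dplyr::bind_rows(rows)
    check_cohort_header(names(cohort))
    # jsonl carries no declared types; coerce to the dialect's
    types <- cohort_col_types()
    for (col in names(cohort)) {
      cohort[[col]] <- if (types[[col]] == "c") as.character(cohort[[col]])
                       else as.numeric(cohort[[col]])
    }
  }

  # absent optional adjudication columns are filled so downstream code can
  # rely on the full column set
  for (col in setdiff(ADJUDICATION_COLS, names(cohort))) {
    cohort[[col]] <- NA_character_
  }
  cohort <- cohort[, c(COHORT_COLS, ADJUDICATION_COLS)]
  validate_cohort(cohort)
  cohort
}

#' Write an ED-visit cohort
#'
#' @param cohort A validated cohort tibble.
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("guess", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.jsonl$|\\.ndjson$", path)) "jsonl" else "csv"
  }
  cohort <- validate_cohort(cohort)
  if (format == "csv") {
    readr::write_csv(cohort, path, na = "")
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (i in seq_len(nrow(cohort))) {
      writeLines(jsonlite::toJSON(as.list(cohort[i, ]), auto_unbox = TRUE,
                                  na = "null", digits = NA),
                 con)
    }
  }
  invisible(path)
}

#' Drop traffic-accident and trauma visits
#'
#' Restricts a cohort to medically motivated ED visits: records whose
#' `visit_reason` is `"other"` are retained in their original order, and
#' visits due to traffic accidents or trauma are removed. The per-reason
#' removal counts are attached as the `"removed"` attribute and always
#' satisfy `nrow(retained) + sum(removed) == nrow(cohort)`.
#'
#' @param cohort A validated cohort tibble with `visit_reason` populated.
#' @return The retained cohort tibble, with attribute `removed`
#'   (named integer vector over `traffic_accident` and `trauma`).
#' @export
exclude_nonmedical_visits <- function(cohort) {
  if (any(is.na(cohort$visit_reason))) {
    abort("visit_reason must be populated on every record")
  }
  removed <- c(
    traffic_accident = sum(cohort$visit_reason == "traffic_accident"),
    trauma = sum(cohort$visit_reason == "trauma")
  )
  kept <- dplyr::filter(cohort, .data$visit_reason == "other")
  attr(kept, "removed") <- removed
  kept
}

# flag report ------------------------------------------------------------

#' Write a per-visit flag report
#'
#' Emits one CSV row per visit (`visit_id`, `flagged`, semicolon-joined fired
#' trigger ids) followed by a footer block of per-trigger fire counts, each
#' footer line prefixed with `#`.
#'
#' @param summary A [flag_cohort()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flag_report <- function(summary, path) {
  stopifnot(inherits(summary, "flag_summary"))
  res <- summary$results
  body <- tibble::tibble(
    visit_id = res$visit_id,
    flagged = ifelse(res$flagged, "true", "false"),
    fired_triggers = join_tokens(res$fired)
  )
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) abort(paste0("cannot write report: ", path)))
  on.exit(close(con))
  writeLines("visit_id,flagged,fired_triggers", con)
  lines <- paste(body$visit_id, body$flagged,
                 dplyr::coalesce(body$fired_triggers, ""), sep = ",")
  writeLines(lines, con)
  counts <- summary$per_trigger_counts
  counts <- counts[counts$n_fired > 0, , drop = FALSE]
  if (nrow(counts) > 0) {
    writeLines(paste0("# ", counts$trigger_id, "=", counts$n_fired), con)
  }
  invisible(path)
}

#' Read back a flag report
#'
#' @param path Path written by [write_flag_report()].
#' @return A list with `results` (tibble: visit_id, flagged, fired
#'   list-column) and `per_trigger_counts` (tibble from the footer).
#' @export
read_flag_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  footer <- grepl("^#", lines)
  body <- lines[!footer][-1]
  parts <- stringr::str_split_fixed(body, stringr::fixed(","), 3)
  results <- tibble::tibble(
    visit_id = parts[, 1],
    flagged = parts[, 2] == "true",
    fired = split_tokens(parts[, 3])
  )
  foot <- stringr::str_match(lines[footer], "^#\\s*(\\S+)=(\\d+)$")
  counts <- tibble::tibble(
    trigger_id = foot[, 2],
    n_fired = as.integer(foot[, 3])
  )
  list(results = results, per_trigger_counts = counts)
}
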