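# Trigger engine --------------------------------------------------------
#
# Evaluation is total over valid records and conservative about missing
# data: a predicate whose datum is absent never fires. Adult-only triggers
# never fire below the set's adult age cutoff (age >= cutoff, fractional
# ages allowed). All evaluation is vectorised over the cohort; the
# per-record surface wraps the same path.

# parse the list-valued columns once per cohort
cohort_context <- function(cohort) {
  meds_long <- parse_medications_long(cohort$medications)
  if (!all(meds_long$ok)) {
    abort(paste0("unparseable medication token(s): ",
                 paste(head(unique(meds_long$token[!meds_long$ok]), 5),
                       collapse = ", ")))
  }
  main_dx <- trimws(stringr::str_extract(cohort$diagnosis_codes, "^[^;]+"))
  main_dx[!is.na(main_dx) & !nzchar(main_dx)] <- NA_character_
  list(
    tokens = split_tokens(stringr::str_to_lower(cohort$symptom_terms)),
    meds_long = meds_long,
    main_dx = toupper(main_dx)
  )
}

clause_fires <- function(cohort, cl) {
  col <- if (cl$domain == "vital") cl$analyte else LAB_COLS[[cl$analyte]]
  x <- cohort[[col]]
  !is.na(x) & compare_op(cl$comparator)(x, cl$cutoff)
}

medication_rows <- function(meds_long, ingredients, concentration_pct = NULL,
                            route = NULL) {
  hit <- meds_long$ingredient %in% ingredients
  if (!is.null(concentration_pct)) {
    hit <- hit & !is.na(meds_long$concentration_pct) &
      meds_long$concentration_pct %in% concentration_pct
  }
  if (!is.null(route)) hit <- hit & meds_long$route %in% route
  unique(meds_long$row[hit])
}

trigger_fires_vec <- function(cohort, ctx, kind, params, adult_only,
                              age_cutoff) {
  n <- nrow(cohort)
  out <- switch(kind,
    keyword = purrr::map_lgl(ctx$tokens,
                             function(tok) any(tok %in% params$terms)),
    vital_threshold = clause_fires(cohort, c(params, domain = "vital")),
    lab_threshold = clause_fires(cohort, c(params, domain = "lab")),
    compound_threshold = purrr::reduce(
      purrr::map(params$clauses, function(cl) clause_fires(cohort, cl)),
      `|`
    ),
    medication_list = {
      v <- rep(FALSE, n)
      v[medication_rows(ctx$meds_long, params$ingredients,
                        params$concentration_pct, params$route)] <- TRUE
      v
    },
    medication_conditional = {
      v <- rep(FALSE, n)
      v[medication_rows(ctx$meds_long, params$target)] <- TRUE
      w <- rep(FALSE, n)
      w[medication_rows(ctx$meds_long, params$forbidden)] <- TRUE
      v & !w
    },
    code_list = {
      dx <- ctx$main_dx
      hit <- if (identical(params$match, "exact")) {
        dx %in% params$codes
      } else {
        purrr::reduce(purrr::map(params$codes,
                                 function(cd) startsWith(dx, cd)), `|`)
      }
      !is.na(dx) & dplyr::coalesce(hit, FALSE)
    },
    abort(paste0("unknown predicate kind '", kind, "'"))
  )
  if (adult_only) {
    out <- out & !is.na(cohort$age) & cohort$age >= age_cutoff
  }
  out
}

#' Evaluate one trigger against one visit record
#'
#' Total over valid records: missing data required by the predicate means
#' no fire, and adult-only triggers never fire below `age_cutoff`. Keyword
#' matching is case-insensitive exact token membership; code-list matching
#' consults the main diagnosis (first code) only.
#'
#' @param record A one-row cohort tibble.
#' @param trigger A one-row slice of a `trigger_set`.
#' @param age_cutoff Adult age cutoff in years (default 18).
#' @return `TRUE` if the trigger fires.
#' @export
evaluate_predicate <- function(record, trigger, age_cutoff = 18) {
  stopifnot(is.data.frame(record), nrow(record) == 1,
            is.data.frame(trigger), nrow(trigger) == 1)
  ctx <- cohort_context(record)
  trigger_fires_vec(record, ctx, trigger$kind, trigger$params[[1]],
                    trigger$adult_only, age_cutoff)
}

#' Fire a trigger set against one visit
#'
#' @param record A one-row cohort tibble.
#' @param set A `trigger_set` (default [dredtt_triggers()]).
#' @return A list with `visit_id`, `fired` (character vector of trigger
#'   ids) and `flagged` (`TRUE` iff any trigger fired).
#' @export
fire_triggers <- function(record, set = dredtt_triggers()) {
  summary <- flag_cohort(record, set)
  res <- summary$results
  list(visit_id = res$visit_id[[1]], fired = res$fired[[1]],
       flagged = res$flagged[[1]])
}

#' Screen a cohort with a trigger set
#'
#' Applies every trigger to every record and aggregates. The result is
#' order-invariant in content and complete: `per_trigger_counts` includes
#' zero-count triggers.
#'
#' @param cohort A validated cohort tibble.
#' @param set A `trigger_set` (default [dredtt_triggers()]).
#' @return A `flag_summary`: list with `results` (tibble `visit_id`,
#'   `fired` list-column, `flagged`), `n_total`, `n_flagged`, and
#'   `per_trigger_counts` (tibble `trigger_id`, `n_fired`).
#' @examples
#' cohort <- new_cohort(2)
#' cohort$visit_id <- c("v1", "v2")
#' cohort$age <- c(70, 30)
#' cohort$sex <- c("female", "male")
#' cohort$visit_reason <- "other"
#' cohort$inr <- c(5.2, NA)
#' flag_cohort(cohort)$n_flagged
#' @export
flag_cohort <- function(cohort, set = dredtt_triggers()) {
  n <- nrow(cohort)
  age_cutoff <- attr(set, "adult_age_cutoff") %||% 18
  ctx <- cohort_context(cohort)

  fired_mat <- matrix(FALSE, nrow = n, ncol = nrow(set),
                      dimnames = list(NULL, set$trigger_id))
  for (i in seq_len(nrow(set))) {
    fired_mat[, i] <- trigger_fires_vec(cohort, ctx, set$kind[i],
                                        set$params[[i]], set$adult_only[i],
                                        age_cutoff)
  }

  fired <- vector("list", n)
  fired[] <- list(character())
  hits <- which(fired_mat, arr.ind = TRUE)
  if (nrow(hits) > 0) {
    by_row <- split(set$trigger_id[hits[, "col"]], hits[, "row"])
    fired[as.integer(names(by_row))] <- purrr::map(by_row, unname)
  }
  flagged <- rowSums(fired_mat) > 0

  structure(
    list(
      results = tibble::tibble(visit_id = cohort$visit_id, fired = fired,
                               flagged = flagged),
      n_total = n,
      n_flagged = sum(flagged),
      per_trigger_counts = tibble::tibble(
        trigger_id = set$trigger_id,
        n_fired = as.integer(colSums(fired_mat))
      )
    ),
    class = "flag_summary"
  )
}

#' @export
print.flag_summary <- function(x, ...) {
  rate <- if (x$n_total > 0) as_pct(x$n_flagged / x$n_total) else NA_real_
  cat("<flag_summary> ", x$n_flagged, "/", x$n_total,
      " visits flagged (", rate, "%)\n", sep = "")
  top <- dplyr::arrange(x$per_trigger_counts, dplyr::desc(.data$n_fired))
  top <- dplyr::filter(top, .data$n_fired > 0)
  if (nrow(top) > 0) {
    cat("top triggers: ",
        paste0(head(top$trigger_id, 5), " (", head(top$n_fired, 5), ")",
               collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @describeIn flag_cohort Per-visit results as a flat tibble
#'   (`fired` semicolon-joined).
#' @param x A `flag_summary`.
#' @param ... Unused.
#' @method tidy flag_summary
#' @export
tidy.flag_summary <- function(x, ...) {
  dplyr::mutate(
    x$results,
    n_fired = purrr::map_int(.data$fired, length),
    fired = join_tokens(.data$fired)
  )
}

#' @describeIn flag_cohort One-row cohort-level summary with the flag rate.
#' @method glance flag_summary
#' @export
glance.flag_summary <- function(x, ...) {
  tibble::tibble(
    n_total = x$n_total,
    n_flagged = x$n_flagged,
    flag_rate = ifelse(x$n_total > 0, x$n_flagged / x$n_total, NA_real_)
  )
}
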