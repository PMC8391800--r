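# Case adjudication -----------------------------------------------------
#
# The gold standard of a trigger-tool validation is human chart review:
# each reviewed visit carries a WHO-UMC causality level, a severity level
# (serious = hospitalization or death), Hallas-style preventability
# reasons, and exclusion reasons. This module encodes the case-definition
# logic only; no automated causality inference is attempted.

# WHO-UMC levels that can clear an inclusion floor, strongest first.
CAUSALITY_ORDER <- c(certain = 4, probable = 3, possible = 2, unlikely = 1,
                     unassessable = 0, none = 0)

causality_rank <- function(x) {
  unname(CAUSALITY_ORDER[match(x, names(CAUSALITY_ORDER))])
}

as_reason_list <- function(x) {
  if (is.list(x)) x else split_tokens(x)
}

#' Is an adjudicated visit a true ADE?
#'
#' A visit counts as a true adverse drug event when its causality level
#' clears the inclusion floor on the ordered WHO-UMC scale
#' (certain > probable > possible > unlikely) *and* no exclusion reason
#' applies. Exclusions (ADE due to an ED-administered medication;
#' intentional overdose) dominate: an excluded visit is never a true ADE
#' regardless of causality. `unassessable` and `none` never clear any
#' floor.
#'
#' The floor is an explicit parameter because the inclusion phrase
#' "higher-than-possible causality" admits two readings; the default
#' `"possible"` (possible-and-above) is the one consistent with the case
#' counts this tool was characterised with, and `"probable"` gives the
#' stricter reading.
#'
#' @param causality Character vector of WHO-UMC levels.
#' @param exclusion_reasons Semicolon-joined strings (or a list of
#'   character vectors) of exclusion reasons; empty/`NA` means none.
#' @param inclusion_floor One of `"certain"`, `"probable"`, `"possible"`,
#'   `"unlikely"`.
#' @return Logical vector.
#' @examples
#' is_true_ade("probable", NA)
#' is_true_ade("certain", "intentional_overdose")
#' @export
is_true_ade <- function(causality, exclusion_reasons = NA_character_,
                        inclusion_floor = c("possible", "probable",
                                            "certain", "unlikely")) {
  inclusion_floor <- match.arg(inclusion_floor)
  bad <- !is.na(causality) & !causality %in% names(CAUSALITY_ORDER)
  if (any(bad)) {
    abort(paste0("unknown causality level(s): ",
                 paste(unique(causality[bad]), collapse = ", ")))
  }
  excluded <- purrr::map_lgl(as_reason_list(exclusion_reasons),
                             function(x) length(x) > 0)
  rank <- causality_rank(causality)
  !is.na(causality) & rank >= CAUSALITY_ORDER[[inclusion_floor]] & !excluded
}

#' Classify adjudicated visits into case statuses
#'
#' Maps adjudication labels to the three case indicators used in
#' evaluation: true-ADE status (via [is_true_ade()]), serious status
#' (a true ADE with severity `"serious"`), and preventable status (a true
#' ADE with at least one Hallas preventability reason). Non-ADE visits are
#' never serious or preventable. A label with `unassessable` causality but
#' a non-`none` severity draws a validation warning.
#'
#' @param labels A tibble with columns `visit_id`, `causality`, `severity`,
#'   `preventability_reasons`, `exclusion_reasons` — a cohort tibble with
#'   adjudication columns works directly. Rows with missing `causality`
#'   (unreviewed visits) classify as non-cases.
#' @param inclusion_floor Passed to [is_true_ade()].
#' @return A tibble of case statuses: `visit_id`, `is_true_ade`,
#'   `is_serious`, `is_preventable`.
#' @export
classify_cases <- function(labels, inclusion_floor = "possible") {
  if ("status" %in% names(labels) && any(labels$status == "conflict")) {
    abort(c(
      "labels contain unresolved dual-review conflicts",
      paste0("visit_id: ",
             paste(head(labels$visit_id[labels$status == "conflict"], 5),
                   collapse = ", "))
    ))
  }
  severity <- dplyr::coalesce(labels$severity, "none")
  odd <- !is.na(labels$causality) & labels$causality == "unassessable" &
    severity != "none"
  if (any(odd)) {
    warn(paste0("unassessable causality with non-none severity for: ",
                paste(head(labels$visit_id[odd], 5), collapse = ", ")))
  }
  prevent <- purrr::map_lgl(as_reason_list(labels$preventability_reasons),
                            function(x) length(x) > 0)
  ade <- is_true_ade(labels$causality, labels$exclusion_reasons,
                     inclusion_floor)
  tibble::tibble(
    visit_id = labels$visit_id,
    is_true_ade = ade,
    is_serious = ade & severity == "serious",
    is_preventable = ade & prevent
  )
}

#' Count cases by status
#'
#' @param statuses A [classify_cases()] tibble.
#' @return A one-row tibble: `n_ade`, `n_serious`, `n_preventable`.
#' @export
summarize_cases <- function(statuses) {
  tibble::tibble(
    n_ade = sum(statuses$is_true_ade),
    n_serious = sum(statuses$is_serious),
    n_preventable = sum(statuses$is_preventable)
  )
}

#' Reconcile two reviewers' adjudications
#'
#' Joins the two label sets by `visit_id`. Visits where both reviewers
#' agree on every adjudication field pass through as `"resolved"`;
#' disagreements are marked `"conflict"` with both reviewers' values
#' retained and the resolved fields left missing — there is no automatic
#' tie-break, conflicts are for human consensus. Downstream
#' classification refuses label sets that still contain conflicts.
#'
#' @param labels_a,labels_b Tibbles of adjudication labels covering the
#'   same `visit_id` set (columns as in [classify_cases()]).
#' @return A tibble with `visit_id`, `status` (`resolved`/`conflict`), the
#'   four resolved adjudication columns (NA on conflict rows), and the
#'   per-reviewer values suffixed `_a`/`_b`.
#' @export
resolve_dual_review <- function(labels_a, labels_b) {
  cols <- c("causality", "severity", "preventability_reasons",
            "exclusion_reasons")
  if (!setequal(labels_a$visit_id, labels_b$visit_id) ||
      anyDuplicated(labels_a$visit_id) || anyDuplicated(labels_b$visit_id)) {
    abort("the two reviews must cover the same visit_id set exactly once each")
  }
  a <- dplyr::select(labels_a, "visit_id", dplyr::all_of(cols))
  b <- dplyr::select(labels_b, "visit_id", dplyr::all_of(cols))
  joined <- dplyr::inner_join(a, b, by = "visit_id",
                              suffix = c("_a", "_b"))
  same <- purrr::reduce(purrr::map(cols, function(cl) {
    va <- joined[[paste0(cl, "_a")]]
    vb <- joined[[paste0(cl, "_b")]]
    (is.na(va) & is.na(vb)) | (!is.na(va) & !is.na(vb) & va == vb)
  }), `&`)
  out <- joined
  out$status <- ifelse(same, "resolved", "conflict")
  for (cl in cols) {
    out[[cl]] <- ifelse(same, joined[[paste0(cl, "_a")]], NA_character_)
  }
  dplyr::select(out, "visit_id", "status", dplyr::all_of(cols),
                dplyr::ends_with("_a"), dplyr::ends_with("_b"))
}

#' Write the conflict rows of a dual review as a review queue
#'
#' @param resolution A [resolve_dual_review()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_review_queue <- function(resolution, path) {
  queue <- dplyr::filter(resolution, .data$status == "conflict")
  readr::write_csv(dplyr::select(queue, -"status",
                                 -dplyr::all_of(c("causality", "severity",
                                                  "preventability_reasons",
                                                  "exclusion_reasons"))),
                   path, na = "")
  invisible(path)
}
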