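#' Run the full validation pipeline on an adjudicated cohort
#'
#' One call from cohort to study metrics: screen with the trigger set,
#' draw the stratified review sample, classify the sampled visits from
#' their adjudication columns, and compute prevalence, overall and
#' per-trigger PPV, sensitivity and specificity for all cases and for the
#' serious and preventable subgroups, and the flagged-vs-unflagged ADE
#' composition comparison (share of serious and preventable ADEs among
#' flagged versus unflagged true ADEs, with a two-proportion test).
#'
#' Only sampled visits need adjudication columns; the cohort plays the
#' role of the e-CRF extract, the sample the role of the charts actually
#' reviewed.
#'
#' @param cohort A validated cohort tibble with adjudication columns
#'   populated on (at least) the visits that end up sampled.
#' @param set Trigger set (default [dredtt_triggers()]).
#' @param fraction Review sampling fraction (default 0.25).
#' @param seed Seed for the stratified draw.
#' @param inclusion_floor Causality floor for [is_true_ade()].
#' @param method,level Confidence-interval method and level.
#' @return A `dredtt_metrics` object; see [tidy.dredtt_metrics()] and
#'   [glance.dredtt_metrics()] for flat views.
#' @export
evaluate_cohort <- function(cohort, set = dredtt_triggers(),
                            fraction = 0.25, seed = 1L,
                            inclusion_floor = "possible",
                            method = CI_METHODS, level = 0.95) {
  method <- match.arg(method)
  summary <- flag_cohort(cohort, set)
  sample <- sample_for_review(summary, fraction, seed)
  ids <- c(sample$flagged_sample, sample$unflagged_sample)
  labels <- cohort[cohort$visit_id %in% ids, ]
  statuses <- classify_cases(labels, inclusion_floor)

  cms <- purrr::map(c("total", "serious", "preventable"),
                    function(w) confusion_matrix(sample, statuses, w))
  names(cms) <- c("total", "serious", "preventable")
  performance <- purrr::imap(cms, function(cm, w) {
    dplyr::mutate(sensitivity_specificity(cm, method, level),
                  which = w, .before = 1)
  })
  performance <- dplyr::bind_rows(performance)

  n_sampled <- length(ids)
  cm_total <- cms$total
  n_ade <- cm_total$tp + cm_total$fn

  # composition of flagged vs unflagged ADEs by subgroup
  composition <- dplyr::bind_rows(purrr::map(
    c("serious", "preventable"),
    function(w) {
      cm <- cms[[w]]
      test <- two_proportion_test(cm$tp, cm_total$tp, cm$fn, cm_total$fn)
      dplyr::mutate(test, subgroup = w,
                    n1 = cm_total$tp, n2 = cm_total$fn, .before = 1)
    }
  ))

  structure(
    list(
      n_total = summary$n_total,
      n_flagged = summary$n_flagged,
      flag_rate = prop_ci(summary$n_flagged, summary$n_total, method, level),
      sample_sizes = tibble::tibble(
        flagged = length(sample$flagged_sample),
        unflagged = length(sample$unflagged_sample)
      ),
      prevalence = prevalence(n_ade, n_sampled, method, level),
      ppv_overall = ppv(cm_total$tp, length(sample$flagged_sample),
                        method, level),
      ppv_per_trigger = per_trigger_ppv(summary, sample, statuses,
                                        method, level),
      performance = performance,
      composition = composition,
      confusion = dplyr::bind_rows(cms),
      fraction = fraction, seed = as.integer(seed),
      inclusion_floor = inclusion_floor, method = method, level = level
    ),
    class = "dredtt_metrics"
  )
}

#' @export
print.dredtt_metrics <- function(x, ...) {
  perf <- x$performance
  sens <- perf$estimate[perf$which == "total" & perf$metric == "sensitivity"]
  spec <- perf$estimate[perf$which == "total" & perf$metric == "specificity"]
  cat("<dredtt_metrics>\n")
  cat("  screened: ", x$n_flagged, "/", x$n_total, " flagged (",
      as_pct(x$n_flagged / x$n_total), "%)\n", sep = "")
  cat("  reviewed: ", x$sample_sizes$flagged, " flagged + ",
      x$sample_sizes$unflagged, " unflagged (fraction ", x$fraction,
      ")\n", sep = "")
  cat("  prevalence: ", as_pct(x$prevalence$estimate), "%  PPV: ",
      as_pct(x$ppv_overall$estimate), "%  sensitivity: ", as_pct(sens),
      "%  specificity: ", as_pct(spec), "%\n", sep = "")
  invisible(x)
}

#' Tidy a validation result
#'
#' @param x A [evaluate_cohort()] result.
#' @param ... Unused.
#' @return A long tibble of every proportion estimate (prevalence, PPV
#'   overall and per trigger, sensitivity and specificity per subgroup)
#'   with `metric`, `group`, `numerator`, `denominator`, `estimate`,
#'   `conf.low`, `conf.high`.
#' @method tidy dredtt_metrics
#' @export
tidy.dredtt_metrics <- function(x, ...) {
  keep <- c("numerator", "denominator", "estimate", "conf.low", "conf.high")
  rows <- dplyr::bind_rows(
    dplyr::tibble(metric = "flag_rate", group = "cohort",
                  x$flag_rate[keep]),
    dplyr::tibble(metric = "prevalence", group = "sample",
                  x$prevalence[keep]),
    dplyr::tibble(metric = "ppv", group = "overall",
                  x$ppv_overall[keep]),
    dplyr::tibble(metric = "ppv", group = x$ppv_per_trigger$trigger_id,
                  x$ppv_per_trigger[keep]),
    dplyr::tibble(metric = x$performance$metric, group = x$performance$which,
                  x$performance[keep])
  )
  tibble::as_tibble(rows)
}

#' Glance at a validation result
#'
#' @param x A [evaluate_cohort()] result.
#' @param ... Unused.
#' @return A one-row tibble of the headline numbers on the percentage
#'   scale (rounded half-up to one decimal, the convention for printed
#'   clinical tables).
#' @method glance dredtt_metrics
#' @export
glance.dredtt_metrics <- function(x, ...) {
  perf <- function(metric, which) {
    x$performance$estimate[x$performance$metric == metric &
                             x$performance$which == which]
  }
  tibble::tibble(
    n_total = x$n_total,
    n_flagged = x$n_flagged,
    n_reviewed = x$sample_sizes$flagged + x$sample_sizes$unflagged,
    n_ade = x$prevalence$numerator,
    flag_rate_pct = as_pct(x$flag_rate$estimate),
    prevalence_pct = as_pct(x$prevalence$estimate),
    ppv_pct = as_pct(x$ppv_overall$estimate),
    sensitivity_pct = as_pct(perf("sensitivity", "total")),
    specificity_pct = as_pct(perf("specificity", "total")),
    sensitivity_serious_pct = as_pct(perf("sensitivity", "serious")),
    specificity_serious_pct = as_pct(perf("specificity", "serious")),
    sensitivity_preventable_pct = as_pct(perf("sensitivity", "preventable")),
    specificity_preventable_pct = as_pct(perf("specificity", "preventable"))
  )
}
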