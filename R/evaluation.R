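# Validation statistics --------------------------------------------------
#
# A trigger tool is characterised against chart-review adjudication of a
# stratified random sample: PPV (review yield per flag), sensitivity and
# specificity overall and for the serious/preventable subgroups, and the
# ADE prevalence in the reviewed sample. All proportions carry binomial
# confidence intervals (Wilson score by default, chosen for its behaviour
# at the very small per-trigger denominators a 28-rule tool produces).

CI_METHODS <- c("wilson", "wald", "clopper_pearson")

#' Binomial proportion with confidence interval
#'
#' @param x Number of successes.
#' @param n Number of trials (> 0).
#' @param method `"wilson"` (default), `"wald"`, or `"clopper_pearson"`.
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `numerator`, `denominator`, `estimate`,
#'   `conf.low`, `conf.high`, `method`, `level`. Bounds are always within
#'   `[0, 1]` and bracket the point estimate.
#' @examples
#' prop_ci(745, 5317)
#' @export
prop_ci <- function(x, n, method = CI_METHODS, level = 0.95) {
  method <- match.arg(method)
  stopifnot(length(x) == 1, length(n) == 1)
  if (is.na(n) || n <= 0) abort("denominator must be positive")
  if (x < 0 || x > n) abort("numerator must lie in [0, denominator]")
  p <- x / n
  z <- qnorm(1 - (1 - level) / 2)
  ci <- switch(method,
    wilson = {
      denom <- 1 + z^2 / n
      center <- (p + z^2 / (2 * n)) / denom
      hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
      c(center - hw, center + hw)
    },
    wald = {
      hw <- z * sqrt(p * (1 - p) / n)
      pmin(pmax(c(p - hw, p + hw), 0), 1)
    },
    clopper_pearson = {
      a <- 1 - level
      low <- if (x == 0) 0 else qbeta(a / 2, x, n - x + 1)
      high <- if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x)
      c(low, high)
    }
  )
  tibble::tibble(
    numerator = x, denominator = n, estimate = p,
    conf.low = ci[1], conf.high = ci[2], method = method, level = level
  )
}

#' Stratified review sample
#'
#' Draws a simple random sample without replacement separately within the
#' flagged and unflagged strata of a screening result, mirroring how
#' trigger-tool validations sample charts for in-depth review. Stratum
#' sample sizes are `round-half-up(fraction * stratum size)`; the draw is
#' deterministic given `seed`.
#'
#' @param summary A [flag_cohort()] result.
#' @param fraction Sampling fraction in (0, 1] (default 0.25).
#' @param seed Integer seed controlling the draw.
#' @return A `review_sample`: list with `flagged_sample` and
#'   `unflagged_sample` (character vectors of visit ids), `fraction`,
#'   `seed`.
#' @export
sample_for_review <- function(summary, fraction = 0.25, seed = 1L) {
  stopifnot(inherits(summary, "flag_summary"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]")
  }
  flagged_ids <- summary$results$visit_id[summary$results$flagged]
  unflagged_ids <- summary$results$visit_id[!summary$results$flagged]
  k_f <- round_half_up(fraction * length(flagged_ids))
  k_u <- round_half_up(fraction * length(unflagged_ids))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  structure(
    list(
      flagged_sample = sample(flagged_ids, k_f),
      unflagged_sample = sample(unflagged_ids, k_u),
      fraction = fraction, seed = as.integer(seed)
    ),
    class = "review_sample"
  )
}

#' Cross-tabulate flagged status against case status
#'
#' Builds the 2x2 table of the review sample: rows are the screening
#' result (flagged / unflagged), columns the adjudicated case status. For
#' the `serious` and `preventable` subgroups the positive class is the
#' subgroup indicator and the negative class is *every other sampled
#' visit* — non-ADE visits plus ADE visits outside the subgroup — which is
#' the denominator convention that makes subgroup specificity comparable
#' across subgroups.
#'
#' @param sample A [sample_for_review()] result.
#' @param statuses A [classify_cases()] tibble covering every sampled
#'   visit.
#' @param which `"total"`, `"serious"`, or `"preventable"`.
#' @return A one-row tibble: `which`, `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(sample, statuses,
                             which = c("total", "serious", "preventable")) {
  which <- match.arg(which)
  ids <- c(sample$flagged_sample, sample$unflagged_sample)
  missing <- setdiff(ids, statuses$visit_id)
  if (length(missing) > 0) {
    abort(c("sampled visits without a case status",
            paste0("visit_id: ", paste(head(missing, 5), collapse = ", "),
                   if (length(missing) > 5)
                     paste0(" ... (", length(missing), " total)") else "")))
  }
  ind <- switch(which, total = statuses$is_true_ade,
                serious = statuses$is_serious,
                preventable = statuses$is_preventable)
  case <- setNames(ind, statuses$visit_id)
  tp <- sum(case[sample$flagged_sample])
  fn <- sum(case[sample$unflagged_sample])
  tibble::tibble(
    which = which,
    tp = tp,
    fp = length(sample$flagged_sample) - tp,
    fn = fn,
    tn = length(sample$unflagged_sample) - fn
  )
}

#' Sensitivity and specificity from a 2x2 table
#'
#' Sensitivity is the proportion of adjudicated cases that the tool
#' flagged, `tp / (tp + fn)`; specificity the proportion of non-cases
#' left unflagged, `tn / (fp + tn)`. A zero denominator is an error, not
#' a silent `NaN`.
#'
#' @param cm A [confusion_matrix()] row (or any list with `tp`, `fp`,
#'   `fn`, `tn`).
#' @param method,level Passed to [prop_ci()].
#' @return A two-row tibble (one per metric) in [prop_ci()] layout plus a
#'   `metric` column.
#' @export
sensitivity_specificity <- function(cm, method = CI_METHODS, level = 0.95) {
  method <- match.arg(method)
  if (cm$tp + cm$fn == 0) abort("sensitivity undefined: no cases in sample")
  if (cm$fp + cm$tn == 0) abort("specificity undefined: no non-cases in sample")
  dplyr::bind_rows(
    dplyr::mutate(prop_ci(cm$tp, cm$tp + cm$fn, method, level),
                  metric = "sensitivity", .before = 1),
    dplyr::mutate(prop_ci(cm$tn, cm$fp + cm$tn, method, level),
                  metric = "specificity", .before = 1)
  )
}

#' Positive predictive value
#'
#' The chart-review yield of the screen: confirmed cases among flagged
#' visits.
#'
#' @param confirmed Number of flagged visits confirmed as cases.
#' @param flagged Number of flagged visits reviewed (> 0).
#' @param method,level Passed to [prop_ci()].
#' @return A one-row tibble in [prop_ci()] layout with `metric = "ppv"`.
#' @examples
#' ppv(745, 5317)
#' @export
ppv <- function(confirmed, flagged, method = CI_METHODS, level = 0.95) {
  method <- match.arg(method)
  if (flagged <= 0) abort("ppv undefined: no flagged visits")
  dplyr::mutate(prop_ci(confirmed, flagged, method, level),
                metric = "ppv", .before = 1)
}

#' ADE prevalence in a reviewed sample
#'
#' @param n_ade Number of adjudicated true ADE visits.
#' @param n_sampled Number of reviewed visits (> 0).
#' @param method,level Passed to [prop_ci()].
#' @return A one-row tibble in [prop_ci()] layout with
#'   `metric = "prevalence"`.
#' @export
prevalence <- function(n_ade, n_sampled, method = CI_METHODS, level = 0.95) {
  method <- match.arg(method)
  if (n_sampled <= 0) abort("prevalence undefined: empty sample")
  dplyr::mutate(prop_ci(n_ade, n_sampled, method, level),
                metric = "prevalence", .before = 1)
}

#' Per-trigger positive predictive value
#'
#' For each trigger, the denominator is the number of sampled visits that
#' fired it and the numerator those confirmed as true ADEs; a visit firing
#' several triggers counts towards each of them, so denominators sum to
#' more than the number of distinct flagged visits. Triggers with no
#' sampled fires are omitted with a note.
#'
#' @param summary A [flag_cohort()] result.
#' @param sample A [sample_for_review()] result drawn from it.
#' @param statuses A [classify_cases()] tibble covering the sample.
#' @param method,level Passed to [prop_ci()].
#' @return A tibble with one row per trigger: `trigger_id`, `numerator`,
#'   `denominator`, `estimate`, `conf.low`, `conf.high`, `method`, `level`.
#' @export
per_trigger_ppv <- function(summary, sample, statuses,
                            method = CI_METHODS, level = 0.95) {
  method <- match.arg(method)
  res <- summary$results
  sampled <- res[res$visit_id %in% sample$flagged_sample, ]
  case <- setNames(statuses$is_true_ade, statuses$visit_id)
  long <- tidyr::unnest(
    tibble::tibble(visit_id = sampled$visit_id, trigger_id = sampled$fired),
    "trigger_id"
  )
  long$is_ade <- unname(case[long$visit_id])
  if (anyNA(long$is_ade)) {
    abort("sampled flagged visits without a case status")
  }
  per <- dplyr::summarise(
    dplyr::group_by(long, .data$trigger_id),
    numerator = sum(.data$is_ade), denominator = dplyr::n(),
    .groups = "drop"
  )
  silent <- setdiff(summary$per_trigger_counts$trigger_id, per$trigger_id)
  if (length(silent) > 0) {
    inform(paste0("no sampled fires for: ", paste(silent, collapse = ", "),
                  " (omitted from per-trigger PPV)"))
  }
  ci <- purrr::map2(per$numerator, per$denominator,
                    function(x, n) prop_ci(x, n, method, level)[, 3:7])
  out <- dplyr::bind_cols(per, dplyr::bind_rows(ci))
  dplyr::arrange(out, .data$trigger_id)
}

#' Compare two independent proportions
#'
#' Pearson chi-square on the 2x2 table without continuity correction,
#' optionally accompanied by Fisher's exact test for small cells.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @param fisher Also run Fisher's exact test (default `TRUE` when any
#'   expected cell is below 5).
#' @return A one-row tibble: `estimate1`, `estimate2`, `statistic`,
#'   `p.value`, `method`, and `p.value_fisher` when computed.
#' @examples
#' two_proportion_test(262, 745, 44, 214)
#' @export
two_proportion_test <- function(x1, n1, x2, n2, fisher = NULL) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    abort("degenerate 2x2 table: a margin is zero")
  }
  tab <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
  ct <- suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2),
                                          correct = FALSE))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (is.null(fisher)) fisher <- any(expected < 5)
  out <- tibble::tibble(
    estimate1 = x1 / n1, estimate2 = x2 / n2,
    statistic = unname(ct$statistic), p.value = ct$p.value,
    method = "pearson chi-square (no continuity correction)"
  )
  if (isTRUE(fisher)) {
    out$p.value_fisher <- stats::fisher.test(tab)$p.value
  }
  out
}
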