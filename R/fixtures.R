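# Deterministic benchmark cohorts ---------------------------------------
#
# Two fixtures reproduce, by construction, the published cross-tabulations
# the 28-trigger tool was validated against, so that every headline
# statistic of the pipeline can be recomputed end-to-end from records the
# engine actually screens. Both are fully deterministic (no RNG) and
# byte-identical across calls.

# largest-remainder apportionment of `total` across the weights
apportion <- function(weights, total) {
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

# deterministic stand-in for runif: the midpoint of the firing region
midpoint <- function(m, lo, hi) rep((lo + hi) / 2, m)

# build flagged records by assigning `counts[id]` visits to each trigger
# and materialising the firing field(s); all flagged visits are adults
materialize_flagged <- function(df, rows, counts) {
  mat <- trigger_materializers(midpoint)
  at <- rows[1] - 1
  for (id in names(counts)) {
    k <- counts[[id]]
    if (k == 0) next
    df <- mat[[id]](df, at + seq_len(k))
    at <- at + k
  }
  df
}

#' Deterministic multi-center screening cohort
#'
#' A 76,724-visit cohort over four hospitals (visit_id prefixes `A-` to
#' `D-`) with 3700 traffic-accident and 6460 trauma visits; after
#' exclusion, 66,564 medical visits remain of which exactly 21,268 fire
#' at least one trigger when screened with [dredtt_triggers()] — 4650 in
#' hospital A (of 16,280), 4441 in B (of 18,718), 6597 in C (of 18,420)
#' and 5580 in D (of 13,146), a 32.0% overall flag rate. Flagged visits
#' are allocated across the 28 triggers by largest remainder on the
#' default allocation weights; unflagged visits carry no flaggable
#' content.
#'
#' @return A validated cohort tibble.
#' @export
fixture_flagging_cohort <- function() {
  hospitals <- c(A = 16280, B = 18718, C = 18420, D = 13146)
  flagged <- c(A = 4650, B = 4441, C = 6597, D = 5580)
  excluded <- c(traffic_accident = 3700, trauma = 6460)
  excl_by_hosp <- apportion(hospitals, sum(excluded))

  pieces <- purrr::map(names(hospitals), function(h) {
    n_med <- hospitals[[h]]
    n_excl <- excl_by_hosp[[h]]
    n_fl <- flagged[[h]]
    n <- n_med + n_excl
    df <- new_cohort(n)
    df$visit_id <- sprintf("%s-%06d", h, seq_len(n))
    df$age <- 40
    df$sex <- rep_len(c("female", "male"), n)
    # excluded visits last so medical rows keep a stable prefix order
    n_traffic <- apportion(excluded, n_excl)[["traffic_accident"]]
    df$visit_reason <- c(rep("other", n_med),
                         rep("traffic_accident", n_traffic),
                         rep("trauma", n_excl - n_traffic))
    counts <- apportion(DEFAULT_TRIGGER_WEIGHTS, n_fl)
    materialize_flagged(df, seq_len(n_fl), counts)
  })
  validate_cohort(dplyr::bind_rows(pieces))
}

#' Deterministic adjudicated review cohort
#'
#' A 16,427-visit cohort representing a fully reviewed stratified sample:
#' 5317 visits fire at least one trigger under [dredtt_triggers()] and
#' 11,110 fire none. Adjudication columns encode exactly 745 flagged true
#' ADEs (262 serious, 129 preventable), 4572 flagged non-ADEs, 214
#' unflagged true ADEs (44 serious, 24 preventable) and 10,896 unflagged
#' non-ADEs, so the full metric set — 14.0% PPV, 77.7% sensitivity, 70.4%
#' specificity, 85.6%/68.6% for serious and 84.3%/68.1% for preventable
#' ADEs — is recomputable from the records.
#'
#' @return A list: `cohort` (validated cohort tibble) and `gold`
#'   ([classify_cases()]-style status tibble).
#' @export
fixture_review_cohort <- function() {
  n_flagged <- 5317
  n_unflagged <- 11110
  n <- n_flagged + n_unflagged
  df <- new_cohort(n)
  df$visit_id <- sprintf("R-%05d", seq_len(n))
  df$age <- 40
  df$sex <- rep_len(c("female", "male"), n)
  df$visit_reason <- "other"

  counts <- apportion(DEFAULT_TRIGGER_WEIGHTS, n_flagged)
  df <- materialize_flagged(df, seq_len(n_flagged), counts)

  flagged <- seq_len(n) <= n_flagged
  # ADE rows: spread through the flagged block so every high-volume
  # trigger sees both confirmed and refuted fires
  ade_flagged <- round(seq(1, n_flagged, length.out = 745))
  ade_unflagged <- n_flagged + round(seq(1, n_unflagged, length.out = 214))
  ade <- rep(FALSE, n)
  ade[c(ade_flagged, ade_unflagged)] <- TRUE
  serious <- rep(FALSE, n)
  serious[ade_flagged[seq_len(262)]] <- TRUE
  serious[ade_unflagged[seq_len(44)]] <- TRUE
  preventable <- rep(FALSE, n)
  preventable[ade_flagged[seq_len(129)]] <- TRUE
  preventable[ade_unflagged[seq_len(24)]] <- TRUE

  df$causality <- ifelse(ade, "probable", "unlikely")
  df$severity <- ifelse(ade, ifelse(serious, "serious", "moderate"), "none")
  df$preventability_reasons[preventable] <- "nonadherence"

  cohort <- validate_cohort(df)
  gold <- tibble::tibble(
    visit_id = df$visit_id,
    is_true_ade = ade,
    is_serious = serious,
    is_preventable = preventable
  )
  list(cohort = cohort, gold = gold)
}
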