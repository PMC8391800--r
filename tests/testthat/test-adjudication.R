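test_that("causality floor and exclusions gate true-ADE status", {
  expect_true(is_true_ade("probable", NA, "possible"))
  expect_true(is_true_ade("possible", NA, "possible"))
  expect_false(is_true_ade("unlikely", NA, "possible"))
  expect_false(is_true_ade("possible", NA, "probable"))
  expect_false(is_true_ade("unassessable", NA, "possible"))
  expect_false(is_true_ade("none", NA, "unlikely"))
  # exclusion dominates any causality level
  expect_false(is_true_ade("certain", "intentional_overdose"))
  expect_false(is_true_ade("certain", "ed_administered_medication"))
  expect_true(is_true_ade("certain", ""))
  expect_error(is_true_ade("maybe", NA), "unknown causality")
})

test_that("raising the inclusion floor never increases the case count", {
  set.seed(77)
  labels <- tibble::tibble(
    visit_id = sprintf("m%03d", 1:300),
    causality = sample(c("certain", "probable", "possible", "unlikely",
                         "unassessable", "none"), 300, TRUE),
    severity = sample(c("serious", "moderate", "mild", "none"), 300, TRUE,
                      prob = c(0.1, 0.2, 0.2, 0.5)),
    preventability_reasons = ifelse(runif(300) < 0.2, "nonadherence",
                                    NA_character_),
    exclusion_reasons = ifelse(runif(300) < 0.1, "intentional_overdose",
                               NA_character_)
  )
  labels$severity[labels$causality %in% c("none", "unassessable")] <- "none"
  labels$preventability_reasons[labels$causality == "none"] <- NA_character_
  floors <- c("unlikely", "possible", "probable", "certain")
  counts <- purrr::map_int(floors, function(fl) {
    summarize_cases(classify_cases(labels, fl))$n_ade
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("classification maps severity and preventability onto true ADEs only", {
  lab <- function(id, ...) {
    tibble::tibble(visit_id = id, causality = NA_character_,
                   severity = NA_character_,
                   preventability_reasons = NA_character_,
                   exclusion_reasons = NA_character_) |>
      dplyr::mutate(...)
  }
  st <- classify_cases(lab("c1", causality = "probable",
                           severity = "serious"))
  expect_equal(unlist(st[, -1]),
               c(is_true_ade = TRUE, is_serious = TRUE, is_preventable = FALSE))
  st2 <- classify_cases(lab("c2", causality = "certain", severity = "serious",
                            exclusion_reasons = "intentional_overdose"))
  expect_equal(unlist(st2[, -1]),
               c(is_true_ade = FALSE, is_serious = FALSE,
                 is_preventable = FALSE))
  st3 <- classify_cases(lab("c3", causality = "possible",
                            preventability_reasons = "nonadherence"))
  expect_true(st3$is_preventable)
  expect_warning(
    classify_cases(lab("c4", causality = "unassessable",
                       severity = "serious")),
    "unassessable"
  )
})

test_that("case counts aggregate exactly", {
  statuses <- tibble::tibble(
    visit_id = sprintf("s%02d", 1:10),
    is_true_ade = TRUE, is_serious = TRUE, is_preventable = FALSE
  )
  expect_equal(summarize_cases(statuses),
               tibble::tibble(n_ade = 10L, n_serious = 10L,
                              n_preventable = 0L))
  empty <- statuses[0, ]
  expect_equal(unlist(summarize_cases(empty)), c(n_ade = 0L, n_serious = 0L,
                                                 n_preventable = 0L))
})

test_that("dual review passes agreement through and flags discrepancies", {
  a <- tibble::tibble(
    visit_id = c("v1", "v2"),
    causality = c("probable", "probable"),
    severity = c("mild", "serious"),
    preventability_reasons = NA_character_,
    exclusion_reasons = NA_character_
  )
  b <- a
  res_same <- resolve_dual_review(a, b)
  expect_true(all(res_same$status == "resolved"))
  expect_equal(res_same$causality, a$causality)

  b$causality[2] <- "possible"
  res <- resolve_dual_review(a, b)
  expect_equal(res$status, c("resolved", "conflict"))
  expect_true(is.na(res$causality[2]))
  expect_error(classify_cases(res), "unresolved")

  path <- withr::local_tempfile(fileext = ".csv")
  write_review_queue(res, path)
  queue <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(queue$visit_id, "v2")

  b2 <- b[1, ]
  expect_error(resolve_dual_review(a, b2), "same visit_id")
})
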