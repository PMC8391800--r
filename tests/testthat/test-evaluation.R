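test_that("stratified sampling sizes use round-half-up and samples are disjoint", {
  fs <- fake_flag_summary(
    visit_id = sprintf("p%05d", 1:66564),
    flagged = c(rep(TRUE, 21268), rep(FALSE, 45296))
  )
  samp <- sample_for_review(fs, 0.25, seed = 42)
  expect_length(samp$flagged_sample, 5317)
  expect_length(samp$unflagged_sample, 11324)
  expect_length(intersect(samp$flagged_sample, samp$unflagged_sample), 0)
  expect_true(all(samp$flagged_sample %in% fs$results$visit_id[1:21268]))

  # deterministic given seed, different across seeds
  samp2 <- sample_for_review(fs, 0.25, seed = 42)
  expect_identical(samp$flagged_sample, samp2$flagged_sample)
  samp3 <- sample_for_review(fs, 0.25, seed = 43)
  expect_false(identical(samp$flagged_sample, samp3$flagged_sample))

  # odd stratum size: 0.25 * 10 = 2.5 rounds up to 3
  fs_odd <- fake_flag_summary(sprintf("q%02d", 1:20),
                              c(rep(TRUE, 10), rep(FALSE, 10)))
  expect_length(sample_for_review(fs_odd, 0.25, 1)$flagged_sample, 3)

  whole <- sample_for_review(fs_odd, 1.0, 1)
  expect_setequal(c(whole$flagged_sample, whole$unflagged_sample),
                  fs_odd$results$visit_id)
  expect_error(sample_for_review(fs_odd, 0), "fraction")
  expect_error(sample_for_review(fs_odd, 1.2), "fraction")
})

test_that("sampling does not disturb the global RNG stream", {
  fs <- fake_flag_summary(sprintf("r%02d", 1:20),
                          rep(c(TRUE, FALSE), 10))
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(sample_for_review(fs, 0.5, seed = 99))
  expect_identical(runif(1), before)
})

test_that("confusion matrices reproduce the benchmark cross-tabulation", {
  n_f <- 5317; n_u <- 11110
  ids <- sprintf("t%05d", seq_len(n_f + n_u))
  flagged <- seq_along(ids) <= n_f
  statuses <- tibble::tibble(
    visit_id = ids,
    is_true_ade = c(seq_len(n_f) <= 745, seq_len(n_u) <= 214),
    is_serious = c(seq_len(n_f) <= 262, seq_len(n_u) <= 44),
    is_preventable = c(seq_len(n_f) <= 129, seq_len(n_u) <= 24)
  )
  samp <- structure(list(flagged_sample = ids[flagged],
                         unflagged_sample = ids[!flagged],
                         fraction = 1, seed = 1L),
                    class = "review_sample")
  cm <- confusion_matrix(samp, statuses, "total")
  expect_equal(unlist(cm[, -1]),
               c(tp = 745L, fp = 4572L, fn = 214L, tn = 10896L))
  cm_s <- confusion_matrix(samp, statuses, "serious")
  expect_equal(c(cm_s$tp, cm_s$fn), c(262L, 44L))
  # subgroup negatives include non-subgroup ADEs
  expect_equal(cm_s$fp + cm_s$tn, n_f + n_u - 306L)

  ss <- sensitivity_specificity(cm)
  expect_equal(round_half_up(100 * ss$estimate[ss$metric == "sensitivity"], 1),
               77.7)
  expect_equal(round_half_up(100 * ss$estimate[ss$metric == "specificity"], 1),
               70.4)
  ss_s <- sensitivity_specificity(cm_s)
  expect_equal(round_half_up(100 * ss_s$estimate, 1), c(85.6, 68.6))
  cm_p <- confusion_matrix(samp, statuses, "preventable")
  ss_p <- sensitivity_specificity(cm_p)
  expect_equal(round_half_up(100 * ss_p$estimate, 1), c(84.3, 68.1))

  expect_error(confusion_matrix(
    structure(list(flagged_sample = "ghost", unflagged_sample = character(),
                   fraction = 1, seed = 1L), class = "review_sample"),
    statuses), "without a case status")
})

test_that("degenerate 2x2 tables raise instead of returning NaN", {
  all_neg <- list(tp = 0, fp = 0, fn = 0, tn = 10)
  expect_error(sensitivity_specificity(all_neg), "sensitivity undefined")
  perfect <- list(tp = 5, fp = 0, fn = 0, tn = 5)
  ss <- sensitivity_specificity(perfect)
  expect_equal(ss$estimate, c(1, 1))
  expect_error(ppv(0, 0), "no flagged")
  expect_error(prevalence(1, 0), "empty sample")
})

test_that("headline proportions match their printed values", {
  expect_equal(round_half_up(100 * ppv(745, 5317)$estimate, 1), 14.0)
  expect_equal(round_half_up(100 * prevalence(959, 16641)$estimate, 1), 5.8)
  expect_equal(round_half_up(100 * prevalence(333, 4067)$estimate, 1), 8.2)
  zero <- ppv(0, 100)
  expect_equal(zero$estimate, 0)
  expect_equal(zero$conf.low, 0)
  expect_gt(zero$conf.high, 0)
})

test_that("Wilson and Clopper-Pearson intervals match independent oracles", {
  # frozen against the closed-form score interval computed by hand
  w <- prop_ci(6, 10, "wilson")
  expect_equal(w$estimate, 0.6)
  expect_equal(w$conf.low, 0.312674, tolerance = 1e-5)
  expect_equal(w$conf.high, 0.831820, tolerance = 1e-5)
  # exact interval vs stats::binom.test across sizes and extremes
  for (case in list(c(6, 10), c(0, 6), c(6, 6), c(745, 5317), c(1, 500))) {
    cp <- prop_ci(case[1], case[2], "clopper_pearson")
    bt <- stats::binom.test(case[1], case[2])$conf.int
    expect_equal(c(cp$conf.low, cp$conf.high), as.numeric(bt),
                 tolerance = 1e-8)
  }
  expect_error(prop_ci(5, 0), "positive")
  expect_error(prop_ci(11, 10), "numerator")
})

test_that("interval bounds always bracket the point estimate", {
  grid <- expand.grid(x = c(0, 1, 3, 6, 25), n = c(6, 50, 500))
  grid <- grid[grid$x <= grid$n, ]
  for (m in c("wilson", "wald", "clopper_pearson")) {
    for (i in seq_len(nrow(grid))) {
      ci <- prop_ci(grid$x[i], grid$n[i], m)
      expect_true(ci$conf.low >= 0 && ci$conf.high <= 1)
      expect_true(ci$conf.low <= ci$estimate + 1e-12)
      expect_true(ci$conf.high >= ci$estimate - 1e-12)
    }
  }
})

test_that("exact coverage of Wilson and Clopper-Pearson stays near nominal", {
  # enumeration over the binomial support is the brute-force oracle:
  # coverage(p) = sum_k dbinom(k) * [p in CI(k, n)]
  p <- 0.14  # the tool's overall PPV scale
  for (n in c(6, 50, 500)) {
    k <- 0:n
    covers <- function(method) {
      purrr::map_lgl(k, function(kk) {
        ci <- prop_ci(kk, n, method)
        ci$conf.low <= p && p <= ci$conf.high
      })
    }
    cov_w <- sum(dbinom(k, n, p) * covers("wilson"))
    cov_cp <- sum(dbinom(k, n, p) * covers("clopper_pearson"))
    expect_gte(cov_w, 0.95 - 0.02)
    expect_gte(cov_cp, 0.95)
    expect_gte(cov_cp, cov_w - 1e-12)
  }
})

test_that("per-trigger PPV counts multi-fire visits in every trigger", {
  ids <- sprintf("x%02d", 1:12)
  fired <- c(
    rep(list("T25"), 6),           # six sampled visits fire T25
    rep(list(c("T8", "T19")), 4),  # multi-fire visits count in both
    rep(list(character()), 2)
  )
  flagged <- purrr::map_int(fired, length) > 0
  fs <- fake_flag_summary(ids, flagged, fired)
  samp <- structure(list(flagged_sample = ids[flagged],
                         unflagged_sample = ids[!flagged],
                         fraction = 1, seed = 1L), class = "review_sample")
  statuses <- tibble::tibble(
    visit_id = ids,
    is_true_ade = c(rep(c(TRUE, FALSE), c(4, 2)), rep(TRUE, 4),
                    rep(FALSE, 2)),
    is_serious = FALSE, is_preventable = FALSE
  )
  per <- suppressMessages(per_trigger_ppv(fs, samp, statuses))
  t25 <- per[per$trigger_id == "T25", ]
  expect_equal(c(t25$numerator, t25$denominator), c(4, 6))
  expect_equal(round_half_up(100 * t25$estimate, 1), 66.7)
  expect_equal(per$denominator[per$trigger_id == "T8"], 4)
  expect_equal(per$estimate[per$trigger_id == "T19"], 1)
  # denominators sum to total fires, not distinct flagged visits
  expect_equal(sum(per$denominator), 6 + 4 * 2)
  expect_equal(sum(purrr::map_int(fired, length)), sum(per$denominator))
})

test_that("two-proportion test agrees with a hand-built chi-square oracle", {
  chisq_oracle <- function(x1, n1, x2, n2) {
    tab <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - e)^2 / e)
    c(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  tt <- two_proportion_test(129, 745, 24, 214)
  expect_equal(round_half_up(100 * tt$estimate1, 1), 17.3)
  expect_equal(round_half_up(100 * tt$estimate2, 1), 11.2)
  o <- chisq_oracle(129, 745, 24, 214)
  expect_equal(tt$statistic, unname(o["stat"]), tolerance = 1e-10)
  expect_equal(tt$p.value, unname(o["p"]), tolerance = 1e-10)

  tt2 <- two_proportion_test(262, 745, 44, 214)
  expect_equal(round_half_up(100 * c(tt2$estimate1, tt2$estimate2), 1),
               c(35.2, 20.6))

  null <- two_proportion_test(30, 100, 60, 200)
  expect_equal(null$p.value, 1)
  expect_equal(null$statistic, 0)
  expect_error(two_proportion_test(0, 10, 0, 20), "degenerate")

  fish <- two_proportion_test(2, 6, 1, 8, fisher = TRUE)
  expect_true(!is.null(fish$p.value_fisher))
  expect_equal(fish$p.value_fisher,
               stats::fisher.test(rbind(c(2, 4), c(1, 7)))$p.value)
})
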