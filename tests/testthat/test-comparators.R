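toy_separated <- function() {
  tibble::tibble(subject_id = sprintf("P%02d", 1:10),
                 tsh = c(1, 1.5, 2, 2.2, 2.4, 5, 5.5, 6, 7, 8),
                 preterm = c(rep(0L, 5), rep(1L, 5)),
                 tpoab = NA_character_, uic = NA_character_, induced = 0L)
}

test_that("AUC is 1 for perfect separation and 1/2 without signal", {
  expect_equal(empirical_auc(toy_separated()), 1.0)
  co <- simulate_cohort(cohort_spec(n = 10000, p_below = 0.08,
                                    p_above = 0.08), seed = 17)
  expect_lt(abs(empirical_auc(co) - 0.5), 0.03)
})

test_that("AUC equals exhaustive Mann-Whitney pair enumeration, ties as 1/2", {
  co6 <- tibble::tibble(subject_id = letters[1:6],
                        tsh = c(1, 2, 2, 3, 4, 5),
                        preterm = c(0L, 0L, 1L, 0L, 1L, 1L),
                        tpoab = NA_character_, uic = NA_character_,
                        induced = 0L)
  expect_equal(empirical_auc(co6), auc_pair_oracle(co6))
  # the shared value 2 across classes contributes the half-count:
  # event at 2 wins 1 pair, halves 1, loses 1; events at 4 and 5 win all 3
  expect_equal(auc_pair_oracle(co6), (1.5 + 3 + 3) / 9)
})

test_that("AUC is invariant under strictly increasing marker transforms", {
  set.seed(23)
  co <- random_small_cohort(60, allow_ties = FALSE)
  base <- empirical_auc(co)
  expect_equal(empirical_auc(dplyr::mutate(co, tsh = exp(tsh))), base)
  expect_equal(empirical_auc(dplyr::mutate(co, tsh = rank(tsh))), base)
})

test_that("AUC matches the pROC reference on a random cohort", {
  skip_if_not_installed("pROC")
  co <- simulate_cohort(cohort_spec(n = 500), seed = 31)
  ref <- as.numeric(pROC::auc(pROC::roc(co$preterm, co$tsh, quiet = TRUE,
                                        direction = "<")))
  expect_equal(empirical_auc(co), ref)
})

test_that("the ROC curve has the required endpoints and bounded coordinates", {
  co <- simulate_cohort(cohort_spec(n = 300), seed = 3)
  rc <- roc_curve(co)
  expect_true(all(rc$sensitivity >= 0 & rc$sensitivity <= 1))
  expect_true(all(rc$specificity >= 0 & rc$specificity <= 1))
  expect_equal(rc$sensitivity[1], 1)
  expect_equal(rc$specificity[1], 0)
  expect_equal(rc$sensitivity[nrow(rc)], 0)
  expect_equal(rc$specificity[nrow(rc)], 1)
  expect_error(roc_curve(dplyr::mutate(co, preterm = 0L)), "both events")
})

test_that("Youden cutoff: perfect separation gives J = 1 at the smallest separating candidate", {
  y <- youden_cutoff(toy_separated())
  expect_equal(y$youden_j, 1)
  expect_equal(y$cutoff, 2.4)  # smallest candidate achieving J = 1
})

test_that("Youden's J is near 0 without signal", {
  co <- simulate_cohort(cohort_spec(n = 10000, p_below = 0.08,
                                    p_above = 0.08), seed = 19)
  expect_lt(youden_cutoff(co)$youden_j, 0.08)
})

test_that("predictive values reproduce the published contingency tables", {
  pv <- predictive_values(total_fixture(), 3.97)
  expect_equal(pv$ppv, 106 / 131)
  expect_equal(pv$one_minus_npv, 20 / 1407)
  sub <- fixture_cohort(dplyr::filter(preterm_tsh_counts(),
                                      population == "tpoab_neg_uic_sufficient"))
  expect_equal(predictive_values(sub, 3.92)$ppv, 28 / 39)
})

test_that("a one-sided dichotomization reports unavailable predictive values", {
  co <- simulate_cohort(cohort_spec(n = 100), seed = 5)
  pv <- predictive_values(co, max(co$tsh) + 1)
  expect_true(is.na(pv$ppv))
  expect_equal(pv$npv, mean(co$preterm == 0L))
})

test_that("PSI: perfect separation gives PSI = 1; a lone extreme event drags the argmax high", {
  p <- psi_cutoff(toy_separated())
  expect_equal(p$psi, 1)

  # mostly noise, but the single largest marker value is an event: the PSI
  # argmax chases the pure-PPV stratum at the top of the range
  drift <- tibble::tibble(
    subject_id = sprintf("D%02d", 1:41),
    tsh = c(seq(0.5, 4, length.out = 40), 9.2),
    preterm = c(rbinom(40, 1, 0) + rep(c(1L, 0L, 0L, 0L), 10), 1L),
    tpoab = NA_character_, uic = NA_character_, induced = 0L
  )
  res <- psi_cutoff(drift)
  oracle <- psi_oracle(drift)
  expect_equal(res$cutoff, oracle$cutoff)
  expect_gte(res$cutoff, 4)  # pushed to the top of the marker range
})

test_that("PSI is near 0 without signal", {
  co <- simulate_cohort(cohort_spec(n = 10000, p_below = 0.08,
                                    p_above = 0.08), seed = 29)
  expect_lt(psi_cutoff(co)$psi, 0.15)
})

test_that("PSI machinery is internally consistent with predictive_values", {
  set.seed(37)
  co <- random_small_cohort(25)
  res <- psi_cutoff(co)
  pv <- predictive_values(co, res$cutoff)
  expect_equal(res$psi, pv$ppv + pv$npv - 1)
  expect_equal(res$one_minus_npv, pv$one_minus_npv)
})

test_that("Youden and PSI match brute-force search on random small cohorts", {
  set.seed(53)
  for (rep in 1:40) {
    co <- random_small_cohort(sample(6:30, 1))
    yo <- youden_oracle(co)
    y <- youden_cutoff(co)
    expect_equal(y$cutoff, yo$cutoff)
    expect_equal(y$youden_j, yo$j)
    po <- psi_oracle(co)
    p <- psi_cutoff(co)
    expect_equal(p$cutoff, po$cutoff)
    expect_equal(p$psi, po$psi)
  }
})

test_that("bootstrap CI matches an independent direct-loop implementation at the same seed", {
  co <- simulate_cohort(cohort_spec(n = 80), seed = 61)
  stat <- function(d) mean(d$tsh)
  res <- bootstrap_ci(co, stat, B = 400, seed = 99)

  set.seed(99)
  reps <- numeric(400)
  for (b in 1:400) {
    idx <- sample.int(80, 80, replace = TRUE)
    reps[b] <- mean(co$tsh[idx])
  }
  expect_equal(res$lower, unname(quantile(reps, 0.025)))
  expect_equal(res$upper, unname(quantile(reps, 0.975)))
  expect_equal(res$point, mean(co$tsh))
})

test_that("bootstrap edge cases: degenerate collapse, B = 2 min/max, invalid B", {
  co <- tibble::tibble(subject_id = c("a", "b"), tsh = c(2, 2),
                       preterm = c(0L, 1L), tpoab = NA_character_,
                       uic = NA_character_, induced = 0L)
  res <- bootstrap_ci(co, function(d) 7, B = 50, seed = 1)
  expect_equal(res$lower, 7)
  expect_equal(res$upper, 7)

  co2 <- simulate_cohort(cohort_spec(n = 30), seed = 3)
  two <- bootstrap_ci(co2, function(d) mean(d$tsh), B = 2, seed = 5)
  set.seed(5)
  r <- c(mean(co2$tsh[sample.int(30, 30, replace = TRUE)]),
         mean(co2$tsh[sample.int(30, 30, replace = TRUE)]))
  expect_equal(two$lower, unname(quantile(r, 0.025)))
  expect_equal(two$upper, unname(quantile(r, 0.975)))

  expect_error(bootstrap_ci(co2, "auc", B = 1), "at least 2")
  expect_error(bootstrap_ci(co2, "ppv_at", B = 10), "needs a `cutoff`")
})

test_that("replicates with undefined statistics are dropped and counted", {
  # 29 non-events and one event: many resamples are single-class, where the
  # Youden cutoff is undefined
  co <- tibble::tibble(subject_id = sprintf("U%02d", 1:30),
                       tsh = runif(30, 1, 3),
                       preterm = c(rep(0L, 29), 1L),
                       tpoab = NA_character_, uic = NA_character_,
                       induced = 0L)
  res <- bootstrap_ci(co, "youden_cutoff", B = 200, seed = 8)
  expect_gt(res$n_dropped, 0)
  expect_lt(res$n_dropped, 200)
})
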