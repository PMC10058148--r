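test_that("the step response probability is inclusive below the cutoff", {
  expect_equal(step_response_prob(2.0, 3.97, 0.08, 0.84), 0.08)
  expect_equal(step_response_prob(3.97, 3.97, 0.08, 0.84), 0.08)
  expect_equal(step_response_prob(3.97 + 1e-12, 3.97, 0.08, 0.84), 0.84)
  expect_equal(step_response_prob(c(1, 5), 3.97, 0.08, 0.84), c(0.08, 0.84))
})

test_that("sufficient statistics reproduce the published dichotomized margins", {
  st <- sufficient_stats(total_fixture(), 3.97)
  expect_identical(st$n_below, 1407L)
  expect_identical(st$events_below, 20L)
  expect_identical(st$n_above, 131L)
  expect_identical(st$events_above, 106L)
})

test_that("sufficient statistics conserve margins at extreme cutoffs", {
  co <- simulate_cohort(cohort_spec(n = 200), seed = 5)
  lo <- sufficient_stats(co, min(co$tsh) - 1)
  expect_identical(lo$n_below, 0L)
  expect_identical(lo$n_above, 200L)
  hi <- sufficient_stats(co, Inf)
  expect_identical(hi$n_below, 200L)
  expect_identical(hi$events_below, sum(co$preterm))
  expect_identical(hi$events_above, 0L)
  expect_error(sufficient_stats(co[0, ], 1), "empty")
})

test_that("the step log likelihood equals the per-record Bernoulli sum", {
  set.seed(31)
  co <- random_small_cohort(50, allow_ties = FALSE)
  cp <- 2.5; p1 <- 0.07; p2 <- 0.6
  direct <- sum(log(ifelse(co$preterm == 1L,
                           step_response_prob(co$tsh, cp, p1, p2),
                           1 - step_response_prob(co$tsh, cp, p1, p2))))
  expect_equal(step_loglik(sufficient_stats(co, cp), p1, p2), direct)
})

test_that("the log likelihood is maximized at the stratum MLEs", {
  st <- tibble::tibble(n_below = 1407L, events_below = 20L,
                       n_above = 131L, events_above = 106L)
  grid <- expand.grid(p1 = seq(0.002, 0.2, by = 0.001),
                      p2 = seq(0.5, 0.95, by = 0.001))
  ll <- mapply(function(a, b) step_loglik(st, a, b), grid$p1, grid$p2)
  best <- grid[which.max(ll), ]
  expect_equal(best$p1, 20 / 1407, tolerance = 0.05)
  expect_equal(best$p2, 106 / 131, tolerance = 0.01)
})

test_that("degenerate likelihood inputs follow the contract", {
  zero <- tibble::tibble(n_below = 0L, events_below = 0L,
                         n_above = 0L, events_above = 0L)
  expect_identical(step_loglik(zero, 0.3, 0.6), 0)
  st <- tibble::tibble(n_below = 5L, events_below = 2L,
                       n_above = 3L, events_above = 1L)
  expect_identical(step_loglik(st, 0, 0.5), -Inf)
  expect_identical(step_loglik(st, 0.5, 1), -Inf)
  empty_above <- tibble::tibble(n_below = 5L, events_below = 2L,
                                n_above = 0L, events_above = 0L)
  expect_true(is.finite(step_loglik(empty_above, 0.4, 0.999)))
})

test_that("the log likelihood depends on the cohort only through its sufficient statistics", {
  set.seed(77)
  co <- random_small_cohort(40)
  shuffled <- co[sample.int(40), ]
  for (cp in c(1, 2.5, 4)) {
    expect_equal(step_loglik(sufficient_stats(co, cp), 0.1, 0.5),
                 step_loglik(sufficient_stats(shuffled, cp), 0.1, 0.5))
  }
})

test_that("the log prior enforces its support and the -log(p2) term", {
  pr <- prior_spec()
  base <- list(cp1 = 5, cp2 = 3, w = 0.5, p_below = 0.1, p_above = 0.5)
  expect_true(is.finite(step_log_prior(base, pr)))
  expect_identical(step_log_prior(modifyList(base, list(p_below = 0.5, p_above = 0.3)), pr), -Inf)
  expect_identical(step_log_prior(modifyList(base, list(cp2 = 1.5)), pr), -Inf)
  expect_identical(step_log_prior(modifyList(base, list(cp1 = 12)), pr), -Inf)
  d <- step_log_prior(modifyList(base, list(p_above = 0.25)), pr) -
    step_log_prior(base, pr)
  expect_equal(d, log(0.5) - log(0.25))
})

test_that("every retained draw satisfies the support constraints", {
  co <- simulate_cohort(cohort_spec(n = 400), seed = 8)
  fit <- fit_step_cutoff(co, config = mcmc_config(burn_in = 1000,
                                                  n_keep = 4000), seed = 6)
  d <- fit$draws
  expect_true(all(d$p1 > 0 & d$p1 < d$p2 & d$p2 < 1))
  expect_true(all(d$cp1 > 0 & d$cp1 < 10))
  expect_true(all(d$cp2 > 2 & d$cp2 < 4))
  expect_true(all(d$w > 0 & d$w < 1))
  expect_equal(d$cp, d$w * d$cp1 + (1 - d$w) * d$cp2, tolerance = 1e-12)
})

test_that("single-class cohorts are rejected with an explanatory error", {
  co <- simulate_cohort(cohort_spec(n = 50, p_below = 0.2, p_above = 0.7),
                        seed = 1)
  co$preterm <- 0L
  expect_error(fit_step_cutoff(co), "events and non-events")
  co$preterm <- 1L
  expect_error(fit_step_cutoff(co), "events and non-events")
})

test_that("fits are reproducible under the master seed", {
  co <- simulate_cohort(cohort_spec(n = 200), seed = 4)
  cfg <- mcmc_config(burn_in = 500, n_keep = 1000)
  f1 <- fit_step_cutoff(co, config = cfg, seed = 11)
  f2 <- fit_step_cutoff(co, config = cfg, seed = 11)
  f3 <- fit_step_cutoff(co, config = cfg, seed = 12)
  expect_identical(f1$draws, f2$draws)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("p1 and p2 track their truncated-Beta full conditionals (probability integral transform)", {
  # a cohort with a wide empty gap pins the cutoff to one plateau, so the
  # dichotomized counts are constant across draws and the full conditionals
  # are known exactly: p1 ~ Beta(s1+1, n1-s1+1) on (0, p2),
  # p2 ~ Beta(s2, n2-s2+1) on (p1, 1)
  below <- tibble::tibble(tsh = seq(0.2, 2.0, length.out = 120),
                          preterm = rep(c(1L, 0L, 0L, 0L), 30))
  above <- tibble::tibble(tsh = seq(6.0, 9.5, length.out = 40),
                          preterm = rep(c(1L, 1L, 1L, 0L), 10))
  co <- dplyr::bind_rows(below, above)
  co$subject_id <- sprintf("G%03d", seq_len(nrow(co)))
  fit <- fit_step_cutoff(co, config = mcmc_config(burn_in = 2000,
                                                  n_keep = 20000), seed = 3)
  in_gap <- fit$draws$cp > 2.0 & fit$draws$cp < 6.0
  expect_gt(mean(in_gap), 0.95)   # cutoff essentially pinned to the gap
  d <- fit$draws[in_gap, ]
  n1 <- 120L; s1 <- 30L; n2 <- 40L; s2 <- 30L
  u1 <- pbeta(d$p1, s1 + 1, n1 - s1 + 1) / pbeta(d$p2, s1 + 1, n1 - s1 + 1)
  lo <- pbeta(d$p1, s2, n2 - s2 + 1)
  u2 <- (pbeta(d$p2, s2, n2 - s2 + 1) - lo) / (1 - lo)
  # marginally Uniform(0,1) if the conditionals are right (draws are
  # autocorrelated, so compare moments, not an exact KS level)
  expect_lt(abs(mean(u1) - 0.5), 0.02)
  expect_lt(abs(var(u1) - 1 / 12), 0.01)
  expect_lt(abs(mean(u2) - 0.5), 0.02)
  expect_lt(abs(var(u2) - 1 / 12), 0.01)
})

test_that("PSRF is 1 for copied chains, near 1 for iid chains, large for disjoint chains", {
  base <- tibble::tibble(chain = 1L, iter = 1:500, cp = rnorm(500),
                         p1 = runif(500), p2 = runif(500) + 1)
  copy <- dplyr::mutate(base, chain = 2L)
  gr <- gelman_rubin(dplyr::bind_rows(base, copy))
  expect_true(all(abs(gr$psrf - 1) < 0.01))

  set.seed(15)
  iid <- dplyr::bind_rows(
    tibble::tibble(chain = 1L, iter = 1:10000, cp = rnorm(10000),
                   p1 = runif(10000), p2 = runif(10000)),
    tibble::tibble(chain = 2L, iter = 1:10000, cp = rnorm(10000),
                   p1 = runif(10000), p2 = runif(10000))
  )
  gr2 <- gelman_rubin(iid)
  expect_true(all(gr2$psrf > 0.99 & gr2$psrf < 1.05))

  apart <- dplyr::bind_rows(
    tibble::tibble(chain = 1L, iter = 1:1000, cp = rnorm(1000, 0, 1),
                   p1 = runif(1000), p2 = runif(1000)),
    tibble::tibble(chain = 2L, iter = 1:1000, cp = rnorm(1000, 10, 1),
                   p1 = runif(1000), p2 = runif(1000))
  )
  gr3 <- gelman_rubin(apart, parameters = "cp")
  expect_gt(gr3$psrf, 5)   # B/W ratio makes this >> 1.2

  expect_error(gelman_rubin(base), "two chains")
})

test_that("constant chains return PSRF 1 via the degenerate-variance guard", {
  flat <- dplyr::bind_rows(
    tibble::tibble(chain = 1L, iter = 1:100, cp = 2, p1 = 0.1, p2 = 0.5),
    tibble::tibble(chain = 2L, iter = 1:100, cp = 2, p1 = 0.1, p2 = 0.5)
  )
  expect_identical(gelman_rubin(flat)$psrf, rep(1, 3))
})

test_that("PSRF agrees with the coda reference implementation", {
  skip_if_not_installed("coda")
  as_mcmc_list <- function(d) {
    coda::mcmc.list(coda::mcmc(matrix(d$cp[d$chain == 1], ncol = 1)),
                    coda::mcmc(matrix(d$cp[d$chain == 2], ncol = 1)))
  }
  # stationary well-mixed chains: formulation variants coincide near 1
  set.seed(44)
  d <- dplyr::bind_rows(
    tibble::tibble(chain = 1L, iter = 1:5000, cp = rnorm(5000)),
    tibble::tibble(chain = 2L, iter = 1:5000, cp = rnorm(5000))
  )
  ours <- gelman_rubin(d, parameters = "cp")$psrf
  ref <- unname(coda::gelman.diag(as_mcmc_list(d),
                                  autoburnin = FALSE)$psrf[1, 1])
  expect_equal(ours, ref, tolerance = 0.005)

  # diverged chains: both implementations flag them far above 1.2 (the
  # degrees-of-freedom correction makes the exact values differ here)
  d2 <- dplyr::mutate(d, cp = cp + ifelse(chain == 2L, 4, 0))
  ours2 <- gelman_rubin(d2, parameters = "cp")$psrf
  ref2 <- unname(coda::gelman.diag(as_mcmc_list(d2),
                                   autoburnin = FALSE)$psrf[1, 1])
  expect_gt(ours2, 1.2)
  expect_gt(ref2, 1.2)
})

test_that("posterior summaries are exact for constant chains and calibrated for uniform draws", {
  fit <- structure(list(
    draws = dplyr::bind_rows(
      tibble::tibble(chain = 1L, iter = 1:50, cp = 3.2, p1 = 0.1, p2 = 0.7,
                     cp1 = 5, cp2 = 3, w = 0.5),
      tibble::tibble(chain = 2L, iter = 1:50, cp = 3.2, p1 = 0.1, p2 = 0.7,
                     cp1 = 5, cp2 = 3, w = 0.5)),
    diagnostics = NULL, config = mcmc_config(n_chains = 2),
    data = list(n = 10, events = 2)), class = "stepcut_fit")
  s <- posterior_summary(fit)
  cp_row <- s[s$parameter == "cp", ]
  expect_equal(cp_row$mean, 3.2)
  expect_equal(cp_row$median, 3.2)
  expect_equal(cp_row$lower, 3.2)
  expect_equal(cp_row$upper, 3.2)
  expect_identical(s$label[s$parameter == "p2"], "PPV")
  expect_identical(s$label[s$parameter == "p1"], "1-NPV")

  set.seed(2)
  u <- runif(100000)
  fit$draws <- tibble::tibble(chain = 1L, iter = seq_along(u), cp = u,
                              p1 = u / 3, p2 = u / 2 + 0.5, cp1 = u, cp2 = u,
                              w = u)
  fit$config <- mcmc_config(n_chains = 1)
  s2 <- posterior_summary(fit)
  expect_equal(s2$lower[s2$parameter == "cp"], 0.025, tolerance = 0.01)
  expect_equal(s2$upper[s2$parameter == "cp"], 0.975, tolerance = 0.01)
})
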