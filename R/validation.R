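#' Random 70/30 (or other) split of a cohort
#'
#' Uniform random split without replacement; the training side gets
#' `floor(train_fraction * n)` subjects.
#'
#' @param cohort Cohort tibble with unique `subject_id`.
#' @param train_fraction Fraction assigned to training (default 0.7).
#' @param seed Integer seed.
#' @return A list with `train_ids`, `validation_ids`, `train_fraction`,
#'   `seed`; the id sets are disjoint and jointly exhaustive.
#' @export
split_sample <- function(cohort, train_fraction = 0.7, seed = 1L) {
  n <- nrow(cohort)
  if (n < 2) abort("need at least two subjects to split.")
  n_train <- floor(train_fraction * n)
  if (n_train < 1 || n_train >= n) {
    abort("`train_fraction` leaves an empty training or validation side.")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  train_idx <- sample.int(n, n_train)
  list(train_ids = cohort$subject_id[sort(train_idx)],
       validation_ids = cohort$subject_id[sort(setdiff(seq_len(n), train_idx))],
       train_fraction = train_fraction, seed = as.integer(seed))
}

#' Bayesian logistic regression on the dichotomized marker
#'
#' Fits `logit P(Y = 1) = b0 + b1 * I(marker > cutoff)` with independent
#' Normal(0, `prior_sd`^2) priors by random-walk Metropolis.  When an
#' indicator level contains a single outcome class (separation), the fit
#' proceeds — the prior keeps that level's estimate finite — and the result
#' carries a `separation` flag.
#'
#' @param cohort Training cohort (both outcome classes present).
#' @param cutoff Dichotomization point (inclusive below = indicator 0).
#' @param prior_sd Prior standard deviation of both coefficients.
#' @param config An [mcmc_config()]; `proposal_scales` uses its first two
#'   entries.
#' @param seed Integer seed.
#' @return A `stepcut_logit` object with `$draws` (tibble `chain`, `iter`,
#'   `b0`, `b1`), `$coef` (posterior means), `$separation`, `$cutoff`.
#' @export
fit_bayes_logistic <- function(cohort, cutoff, prior_sd = 10,
                               config = mcmc_config(burn_in = 2000L,
                                                    n_keep = 8000L),
                               seed = 1L) {
  check_two_classes(cohort)
  ind <- as.integer(cohort$tsh > cutoff)
  n0 <- sum(ind == 0L); s0 <- sum(cohort$preterm[ind == 0L])
  n1 <- sum(ind == 1L); s1 <- sum(cohort$preterm[ind == 1L])
  separation <- (n0 > 0 && (s0 == 0 || s0 == n0)) ||
    (n1 > 0 && (s1 == 0 || s1 == n1)) || n0 == 0 || n1 == 0

  chain_seeds <- derive_seeds(seed, config$n_chains)
  scales <- rep_len(as.numeric(config$proposal_scales), 2)
  chains <- purrr::map(seq_len(config$n_chains), function(ch) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(chain_seeds[ch])
    res <- logistic_mcmc_chain(n0, s0, n1, s1, prior_sd,
                               config$burn_in, config$n_keep, config$thin,
                               scales)
    draws <- tibble::as_tibble(as.data.frame(res$draws))
    names(draws) <- c("b0", "b1")
    draws$chain <- ch
    draws$iter <- seq_len(nrow(draws))
    draws[, c("chain", "iter", "b0", "b1")]
  })
  draws <- dplyr::bind_rows(chains)
  structure(list(draws = draws,
                 coef = c(b0 = mean(draws$b0), b1 = mean(draws$b1)),
                 separation = separation,
                 cutoff = cutoff, prior_sd = prior_sd,
                 counts = c(n0 = n0, s0 = s0, n1 = n1, s1 = s1),
                 seeds = list(master = seed, chains = chain_seeds)),
            class = "stepcut_logit")
}

#' Predict event probabilities from a fitted dichotomized logistic model
#'
#' Uses posterior-mean coefficients; predictions take at most two distinct
#' values, one per indicator level.
#'
#' @param object A `stepcut_logit`.
#' @param newdata Cohort tibble.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.stepcut_logit <- function(object, newdata, ...) {
  ind <- as.numeric(newdata$tsh > object$cutoff)
  plogis(object$coef["b0"] + object$coef["b1"] * ind)
}

#' Cross-validated AUC of the dichotomized logistic model
#'
#' Stratified k-fold cross-validation: folds balance events so each holds
#' roughly `events / k` of them.  For each fold the Bayesian logistic model
#' is fitted on the complement at the fixed `cutoff`, the held-out subjects
#' are scored, and the fold AUC is the Mann-Whitney AUC of those scores.
#' The cross-validated AUC is the arithmetic mean of fold AUCs; its
#' percentile-bootstrap CI resamples the pooled held-out
#' (prediction, outcome) pairs.
#'
#' @param cohort Cohort tibble.
#' @param cutoff Fixed dichotomization point (e.g. a training-set estimate).
#' @param k Number of folds (default 10; `k = n` is not supported).
#' @param seed Integer seed (folding, chains and bootstrap all derive from
#'   it).
#' @param prior_sd,config Passed to [fit_bayes_logistic()].
#' @param B Bootstrap replicates for the CI.
#' @return A `stepcut_cv` object: `$fold_auc`, `$cv_auc`, `$ci`, `$pooled`
#'   (held-out predictions), `$k`, `$seed`.
#' @export
cv_auc <- function(cohort, cutoff, k = 10L, seed = 1L, prior_sd = 10,
                   config = mcmc_config(burn_in = 1000L, n_keep = 4000L,
                                        n_chains = 1L),
                   B = 1000L) {
  check_two_classes(cohort)
  if (k < 2) abort("`k` must be at least 2.")
  if (k >= nrow(cohort)) abort("`k = n` (leave-one-out) is not supported.")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # stratified fold labels: events and non-events dealt out separately
  fold <- integer(nrow(cohort))
  for (cls in c(0L, 1L)) {
    idx <- which(cohort$preterm == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  for (f in seq_len(k)) {
    held <- cohort$preterm[fold == f]
    if (length(unique(held)) < 2) {
      abort(paste0("fold ", f, " lacks one outcome class even after ",
                   "stratification; lower `k`."))
    }
  }

  pooled <- vector("list", k)
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    train <- cohort[fold != f, ]
    test <- cohort[fold == f, ]
    fit <- fit_bayes_logistic(train, cutoff, prior_sd = prior_sd,
                              config = config,
                              seed = derive_seeds(seed, k + 1)[f])
    pred <- predict(fit, test)
    fold_auc[f] <- pred_auc(pred, test$preterm)
    pooled[[f]] <- tibble::tibble(prediction = as.numeric(pred),
                                  outcome = test$preterm, fold = f)
  }
  pooled <- dplyr::bind_rows(pooled)

  boot <- purrr::map_dbl(seq_len(B), function(b) {
    idx <- sample.int(nrow(pooled), nrow(pooled), replace = TRUE)
    d <- pooled[idx, ]
    if (length(unique(d$outcome)) < 2) return(NA_real_)
    pred_auc(d$prediction, d$outcome)
  })
  boot <- boot[!is.na(boot)]
  ci <- unname(quantile(boot, c(0.025, 0.975)))

  structure(list(fold_auc = fold_auc, cv_auc = mean(fold_auc),
                 ci = ci, pooled = pooled, k = as.integer(k),
                 seed = as.integer(seed), B = as.integer(B)),
            class = "stepcut_cv")
}

# Mann-Whitney AUC of arbitrary scores against a binary outcome
pred_auc <- function(score, outcome) {
  r <- rank(score)
  n1 <- sum(outcome == 1L)
  n0 <- sum(outcome == 0L)
  (sum(r[outcome == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
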