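#' Empirical ROC curve
#'
#' Sensitivity and specificity across all distinct observed marker values,
#' using the same dichotomization convention as the Bayesian model: a test
#' is positive when the marker exceeds the cutoff (the boundary is inclusive
#' below, i.e. negative).  A leading `-Inf` candidate supplies the
#' (sensitivity 1, specificity 0) endpoint; the largest observed value gives
#' (0, 1).
#'
#' @param cohort Cohort tibble with `tsh` and `preterm`.
#' @return A `stepcut_roc` tibble: `cutoff`, `sensitivity`, `specificity`,
#'   with the Mann-Whitney AUC as attribute `auc`.
#' @export
roc_curve <- function(cohort) {
  check_two_classes(cohort)
  cum <- cumulative_counts(cohort)
  n_event <- cum$S
  n_non <- cum$n - cum$S
  curve <- tibble::tibble(
    cutoff = c(-Inf, cum$values),
    sensitivity = c(1, (n_event - cum$events_below) / n_event),
    specificity = c(0, (cum$n_below - cum$events_below) / n_non)
  )
  structure(curve, auc = empirical_auc(cohort),
            class = c("stepcut_roc", class(curve)))
}

# per distinct marker value: how many records (and events) lie at or below it
cumulative_counts <- function(cohort) {
  ord <- order(cohort$tsh)
  x <- cohort$tsh[ord]
  y <- cohort$preterm[ord]
  values <- unique(x)
  idx <- findInterval(values, x)      # last position <= each distinct value
  list(values = values, n_below = idx, events_below = cumsum(y)[idx],
       n = length(x), S = sum(y))
}

#' Empirical AUC by the Mann-Whitney identity
#'
#' The probability that a randomly chosen event outranks a randomly chosen
#' non-event on the marker, counting ties as 1/2.  Invariant under strictly
#' increasing transforms of the marker.
#'
#' @param cohort Cohort tibble.
#' @return AUC in \[0, 1\].
#' @export
empirical_auc <- function(cohort) {
  check_two_classes(cohort)
  r <- rank(cohort$tsh)           # average ranks handle ties as 1/2
  n1 <- sum(cohort$preterm == 1L)
  n0 <- sum(cohort$preterm == 0L)
  (sum(r[cohort$preterm == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-index optimal cutoff
#'
#' Maximizes J = sensitivity + specificity − 1 over all distinct observed
#' marker values (dichotomized as <= c versus > c).  Ties in J are broken
#' toward the smallest cutoff.
#'
#' @param cohort Cohort tibble.
#' @return One-row tibble: `cutoff`, `youden_j`, `sensitivity`,
#'   `specificity`.
#' @export
youden_cutoff <- function(cohort) {
  check_two_classes(cohort)
  curve <- roc_curve(cohort)
  curve <- curve[is.finite(curve$cutoff), ]
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j >= max(j) - 1e-12)[1]   # smallest cutoff among ties
  tibble::tibble(cutoff = curve$cutoff[best], youden_j = j[best],
                 sensitivity = curve$sensitivity[best],
                 specificity = curve$specificity[best])
}

#' Predictive values at a cutoff
#'
#' PPV = events above / subjects above; NPV = non-events below / subjects
#' below.  A side with no subjects yields `NA` (reported as unavailable,
#' never silently 0/0).
#'
#' @param cohort Cohort tibble.
#' @param cutoff Cutoff (inclusive below).
#' @return One-row tibble: `cutoff`, `ppv`, `npv`, `one_minus_npv`, plus the
#'   dichotomized counts.
#' @export
#' @examples
#' counts <- dplyr::filter(preterm_tsh_counts(), population == "total")
#' predictive_values(fixture_cohort(counts), cutoff = 3.97)
predictive_values <- function(cohort, cutoff) {
  st <- sufficient_stats(cohort, cutoff)
  ppv <- if (st$n_above > 0) st$events_above / st$n_above else NA_real_
  npv <- if (st$n_below > 0) {
    (st$n_below - st$events_below) / st$n_below
  } else NA_real_
  dplyr::mutate(st, ppv = ppv, npv = npv, one_minus_npv = 1 - npv)
}

#' Predictive-summary-index optimal cutoff
#'
#' Maximizes PSI = PPV + NPV − 1 over all distinct observed marker values at
#' which both strata are non-empty; candidates where either predictive value
#' is undefined are excluded rather than scored 0.  Ties break toward the
#' smallest cutoff.  Unlike the Youden index, the PSI is driven by
#' predictive values and is known to drift toward extreme cutoffs when a few
#' extreme marker values are all events.
#'
#' @param cohort Cohort tibble.
#' @return One-row tibble: `cutoff`, `psi`, `ppv`, `npv`, `one_minus_npv`.
#' @export
psi_cutoff <- function(cohort) {
  check_two_classes(cohort)
  cum <- cumulative_counts(cohort)
  n_above <- cum$n - cum$n_below
  admissible <- cum$n_below > 0 & n_above > 0
  ppv <- (cum$S - cum$events_below) / n_above
  npv <- (cum$n_below - cum$events_below) / cum$n_below
  vals <- tibble::tibble(cutoff = cum$values, psi = ppv + npv - 1,
                         ppv = ppv, npv = npv)[admissible, ]
  if (nrow(vals) == 0) {
    abort("no admissible candidate cutoff: every dichotomization leaves a stratum empty.")
  }
  best <- which(vals$psi >= max(vals$psi) - 1e-12)[1]
  dplyr::mutate(vals[best, ], one_minus_npv = 1 - .data$npv)
}

#' Percentile bootstrap confidence interval for a cutoff statistic
#'
#' Non-stratified case resampling of whole records, B replicates, percentile
#' 2.5/97.5 interval.  Replicates where the statistic is undefined (for
#' example a single-class resample) are dropped and counted.
#'
#' @param cohort Cohort tibble.
#' @param statistic Either a function `cohort -> scalar`, or one of
#'   `"youden_cutoff"`, `"psi_cutoff"`, `"auc"`, `"ppv_at"`, `"npv_at"`,
#'   `"one_minus_npv_at"` (the `_at` forms need `cutoff`).
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param cutoff Cutoff for the `_at` statistics.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `statistic`, `point`, `lower`, `upper`, `B`,
#'   `n_dropped`, `seed`, `method`.
#' @export
bootstrap_ci <- function(cohort, statistic, B = 1000L, seed = 1L,
                         cutoff = NULL, level = 0.95) {
  if (B < 2) abort("`B` must be at least 2.")
  fn <- resolve_statistic(statistic, cutoff)
  name <- if (is.character(statistic)) statistic else "custom"

  point <- fn(cohort)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(cohort)
  reps <- purrr::map_dbl(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(fn(cohort[idx, ]), error = function(e) NA_real_)
  })
  ok <- reps[!is.na(reps)]
  if (length(ok) == 0) {
    abort("the statistic was undefined in every bootstrap replicate.")
  }
  alpha <- (1 - level) / 2
  qs <- unname(quantile(ok, c(alpha, 1 - alpha), type = 7))
  tibble::tibble(statistic = name, point = point,
                 lower = qs[1], upper = qs[2],
                 B = as.integer(B), n_dropped = sum(is.na(reps)),
                 seed = as.integer(seed), method = "percentile")
}

resolve_statistic <- function(statistic, cutoff) {
  if (is.function(statistic)) return(statistic)
  if (!is.character(statistic) || length(statistic) != 1) {
    abort("`statistic` must be a function or a statistic name.")
  }
  needs_cutoff <- c("ppv_at", "npv_at", "one_minus_npv_at")
  if (statistic %in% needs_cutoff && is.null(cutoff)) {
    abort(sprintf("statistic \"%s\" needs a `cutoff`.", statistic))
  }
  switch(statistic,
    youden_cutoff = function(d) youden_cutoff(d)$cutoff,
    psi_cutoff = function(d) psi_cutoff(d)$cutoff,
    auc = empirical_auc,
    ppv_at = function(d) predictive_values(d, cutoff)$ppv,
    npv_at = function(d) predictive_values(d, cutoff)$npv,
    one_minus_npv_at = function(d) predictive_values(d, cutoff)$one_minus_npv,
    abort(sprintf("unknown statistic \"%s\".", statistic))
  )
}

check_two_classes <- function(cohort) {
  if (nrow(cohort) == 0 || length(unique(cohort$preterm)) < 2) {
    abort("this estimator needs a cohort with both events and non-events.")
  }
  invisible(cohort)
}
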