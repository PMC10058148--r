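# Independent brute-force oracles used across tests. These deliberately use
# naive loops and direct definitions, never the package's vectorized paths.

# AUC by exhaustive enumeration of event/non-event pairs, ties as 1/2
auc_pair_oracle <- function(cohort) {
  ev <- cohort$tsh[cohort$preterm == 1L]
  nv <- cohort$tsh[cohort$preterm == 0L]
  total <- 0
  for (a in ev) {
    for (b in nv) {
      total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(ev) * length(nv))
}

# Youden by direct loop over every distinct observed value (<= c negative)
youden_oracle <- function(cohort) {
  cand <- sort(unique(cohort$tsh))
  n1 <- sum(cohort$preterm == 1L)
  n0 <- sum(cohort$preterm == 0L)
  best_j <- -Inf
  best_c <- NA_real_
  for (cc in cand) {
    sens <- sum(cohort$tsh > cc & cohort$preterm == 1L) / n1
    spec <- sum(cohort$tsh <= cc & cohort$preterm == 0L) / n0
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_c <- cc
    }
  }
  list(cutoff = best_c, j = best_j)
}

# PSI by direct loop; candidates with an empty stratum are skipped
psi_oracle <- function(cohort) {
  cand <- sort(unique(cohort$tsh))
  best_psi <- -Inf
  best_c <- NA_real_
  for (cc in cand) {
    nb <- sum(cohort$tsh <= cc)
    na_ <- sum(cohort$tsh > cc)
    if (nb == 0 || na_ == 0) next
    ppv <- sum(cohort$tsh > cc & cohort$preterm == 1L) / na_
    npv <- sum(cohort$tsh <= cc & cohort$preterm == 0L) / nb
    psi <- ppv + npv - 1
    if (psi > best_psi + 1e-12) {
      best_psi <- psi
      best_c <- cc
    }
  }
  list(cutoff = best_c, psi = best_psi)
}

# random small cohort guaranteed to contain both outcome classes
random_small_cohort <- function(n, allow_ties = TRUE) {
  x <- if (allow_ties) sample(seq(0.5, 5, by = 0.5), n, replace = TRUE)
  else runif(n, 0.3, 6)
  y <- rbinom(n, 1L, 0.4)
  if (sum(y) == 0) y[sample.int(n, 1)] <- 1L
  if (sum(y) == n) y[sample.int(n, 1)] <- 0L
  tibble::tibble(subject_id = sprintf("T%03d", seq_len(n)),
                 tsh = x, preterm = as.integer(y),
                 tpoab = NA_character_, uic = NA_character_, induced = 0L)
}

total_fixture <- function(seed = 1L) {
  counts <- dplyr::filter(preterm_tsh_counts(), population == "total")
  fixture_cohort(counts, seed = seed)
}
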