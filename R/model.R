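#' Prior specification for the step-function cutoff model
#'
#' The cutoff prior is a robust weighted sum of a non-informative and an
#' informative uniform component, `cp = w * cp1 + (1 - w) * cp2`, with
#' `cp1 ~ U(cp1_bounds)`, `cp2 ~ U(cp2_bounds)` and `w ~ U(w_bounds)`.  The
#' informative support defaults to (2, 4) mIU/L — bracketing the older
#' first-trimester TSH reference limit of 2.5 and the revised limit of
#' 4.0 — and the non-informative support to (0, 10).  The response
#' probabilities use the ordered uniforms `p2 ~ U(0, 1)` and
#' `p1 | p2 ~ U(0, p2)`, which encodes PPV > 1 − NPV.
#'
#' @param cp1_bounds Support of the non-informative cutoff component.
#' @param cp2_bounds Support of the informative cutoff component.
#' @param w_bounds Support of the mixing weight (within \[0, 1\]).
#' @return A `stepcut_prior` list.
#' @export
prior_spec <- function(cp1_bounds = c(0, 10),
                       cp2_bounds = c(2, 4),
                       w_bounds = c(0, 1)) {
  for (b in list(cp1_bounds, cp2_bounds, w_bounds)) {
    if (length(b) != 2 || !is.numeric(b) || b[1] >= b[2]) {
      abort("prior bounds must be non-degenerate numeric intervals (lo < hi).")
    }
  }
  if (w_bounds[1] < 0 || w_bounds[2] > 1) {
    abort("`w_bounds` must lie within [0, 1].")
  }
  structure(list(cp1_bounds = cp1_bounds, cp2_bounds = cp2_bounds,
                 w_bounds = w_bounds),
            class = "stepcut_prior")
}

#' MCMC configuration
#'
#' Defaults match the analysis settings of the motivating study: two chains,
#' 10,000 burn-in iterations and 50,000 retained iterations per chain.
#'
#' @param n_chains Number of chains (>= 2 when diagnostics are wanted).
#' @param burn_in Burn-in iterations discarded per chain.
#' @param n_keep Retained iterations per chain.
#' @param thin Thinning interval.
#' @param proposal_scales Initial random-walk scales for the logit-scale
#'   updates of `cp1`, `cp2`, `w`; adapted during burn-in only.
#' @return A `stepcut_mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 2L, burn_in = 10000L, n_keep = 50000L,
                        thin = 1L, proposal_scales = c(1, 1, 1)) {
  if (n_chains < 1) abort("`n_chains` must be >= 1.")
  if (burn_in < 1 || n_keep < 1 || thin < 1) {
    abort("`burn_in`, `n_keep` and `thin` must be positive.")
  }
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 n_keep = as.integer(n_keep),
                 thin = as.integer(thin),
                 proposal_scales = proposal_scales),
            class = "stepcut_mcmc_config")
}

#' Step-function response probability
#'
#' The model's event probability as a function of the marker: `p_below`
#' (equal to 1 − NPV) when `x <= cutoff` — the boundary is inclusive
#' below — and `p_above` (the PPV) when `x > cutoff`.
#'
#' @param x Marker values (vectorized).
#' @param cutoff Cutoff value.
#' @param p_below,p_above Event probabilities on either side.
#' @return Numeric vector of probabilities.
#' @export
#' @examples
#' step_response_prob(c(2, 3.97, 4.5), cutoff = 3.97,
#'                    p_below = 0.08, p_above = 0.84)
step_response_prob <- function(x, cutoff, p_below, p_above) {
  ifelse(x <= cutoff, p_below, p_above)
}

#' Dichotomize a cohort at a cutoff
#'
#' The step model's sufficient statistics: counts and event counts at or
#' below versus above the cutoff.  Margins are conserved —
#' `n_below + n_above` equals the cohort size and
#' `events_below + events_above` the total events.
#'
#' @param cohort A cohort tibble with columns `tsh` and `preterm`.
#' @param cutoff Cutoff value (inclusive below).
#' @return One-row tibble: `cutoff`, `n_below`, `events_below`, `n_above`,
#'   `events_above`.
#' @export
sufficient_stats <- function(cohort, cutoff) {
  if (nrow(cohort) == 0) abort("cannot dichotomize an empty cohort.")
  below <- cohort$tsh <= cutoff
  tibble::tibble(
    cutoff = cutoff,
    n_below = sum(below),
    events_below = sum(cohort$preterm[below]),
    n_above = sum(!below),
    events_above = sum(cohort$preterm[!below])
  )
}

#' Step-model Bernoulli log likelihood from sufficient statistics
#'
#' `events_below * log(p_below) + (n_below - events_below) *
#' log(1 - p_below)` plus the same for the above-cutoff stratum.  An empty
#' stratum contributes 0; a probability at 0 or 1 facing a non-zero count
#' returns `-Inf` (by contract, not an error).
#'
#' @param stats A one-row tibble from [sufficient_stats()], or any list with
#'   fields `n_below`, `events_below`, `n_above`, `events_above`.
#' @param p_below,p_above Stratum event probabilities.
#' @return Log likelihood (scalar).
#' @export
step_loglik <- function(stats, p_below, p_above) {
  term <- function(s, f, p) {
    out <- 0
    if (s > 0) out <- out + if (p <= 0) -Inf else s * log(p)
    if (f > 0) out <- out + if (p >= 1) -Inf else f * log1p(-p)
    out
  }
  term(stats$events_below, stats$n_below - stats$events_below, p_below) +
    term(stats$events_above, stats$n_above - stats$events_above, p_above)
}

#' Log prior density of a step-model state
#'
#' Joint log density of `(cp1, cp2, w, p2, p1)` under the weighted-sum
#' cutoff prior and the ordered uniforms on the response probabilities:
#' constant (minus the log prior volume) minus `log(p_above)` on the support,
#' `-Inf` outside it.  The cutoff itself is the deterministic function
#' `w * cp1 + (1 - w) * cp2` and carries no extra density.
#'
#' @param params List with fields `cp1`, `cp2`, `w`, `p_below`, `p_above`.
#' @param prior A [prior_spec()].
#' @return Log density (scalar).
#' @export
step_log_prior <- function(params, prior = prior_spec()) {
  inside <- function(x, b) x > b[1] && x < b[2]
  ok <- inside(params$cp1, prior$cp1_bounds) &&
    inside(params$cp2, prior$cp2_bounds) &&
    inside(params$w, prior$w_bounds) &&
    params$p_above > 0 && params$p_above < 1 &&
    params$p_below > 0 && params$p_below < params$p_above
  if (!ok) return(-Inf)
  vol <- diff(prior$cp1_bounds) * diff(prior$cp2_bounds) *
    diff(prior$w_bounds)
  -log(vol) - log(params$p_above)
}

#' Fit the Bayesian step-function cutoff model
#'
#' Samples the posterior of `(cp, p1, p2, cp1, cp2, w)` by
#' Metropolis-within-Gibbs: `p1` and `p2` are drawn exactly from their
#' truncated-Beta full conditionals — `p1 | ... ~ Beta(s1 + 1, n1 - s1 + 1)`
#' truncated to `(0, p2)` and `p2 | ... ~ Beta(s2, n2 - s2 + 1)` truncated to
#' `(p1, 1)` — while `cp1`, `cp2` and `w` get random-walk Metropolis updates
#' on the logit scale (with the Jacobian), proposal scales adapted during
#' burn-in only so detailed balance holds for the retained draws.
#'
#' @param cohort A cohort tibble with at least one event and one non-event.
#' @param prior A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param seed Master integer seed; per-chain seeds are derived from it.
#' @return A `stepcut_fit` object: `$draws` (tibble with columns `chain`,
#'   `iter`, `cp`, `p1`, `p2`, `cp1`, `cp2`, `w`), `$acceptance`,
#'   `$diagnostics` (per-parameter PSRF when >= 2 chains), `$seeds`,
#'   `$data` (sufficient marker/outcome summary), `$prior`, `$config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n = 300), seed = 7)
#' fit <- fit_step_cutoff(cohort,
#'                        config = mcmc_config(burn_in = 500, n_keep = 1000))
#' glance(fit)
fit_step_cutoff <- function(cohort, prior = prior_spec(),
                            config = mcmc_config(), seed = 1L) {
  events <- sum(cohort$preterm)
  if (nrow(cohort) == 0 || events == 0 || events == nrow(cohort)) {
    abort(paste0("the cohort must contain both events and non-events; ",
                 "an all-event or event-free cohort leaves the step model ",
                 "unidentified."))
  }
  ord <- order(cohort$tsh)
  xs <- cohort$tsh[ord]
  cum_events <- cumsum(cohort$preterm[ord])

  chain_seeds <- derive_seeds(seed, config$n_chains)
  chains <- purrr::map(seq_len(config$n_chains), function(ch) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(chain_seeds[ch])
    res <- step_mcmc_chain(
      xs, as.integer(cum_events),
      prior$cp1_bounds[1], prior$cp1_bounds[2],
      prior$cp2_bounds[1], prior$cp2_bounds[2],
      config$burn_in, config$n_keep, config$thin,
      as.numeric(config$proposal_scales)
    )
    draws <- tibble::as_tibble(as.data.frame(res$draws))
    names(draws) <- c("cp", "p1", "p2", "cp1", "cp2", "w")
    draws$chain <- ch
    draws$iter <- seq_len(nrow(draws))
    list(draws = draws[, c("chain", "iter", "cp", "p1", "p2",
                           "cp1", "cp2", "w")],
         acceptance = res$acceptance)
  })

  draws <- dplyr::bind_rows(purrr::map(chains, "draws"))
  acceptance <- tibble::tibble(
    chain = seq_len(config$n_chains),
    cp1 = purrr::map_dbl(chains, ~ .x$acceptance[1]),
    cp2 = purrr::map_dbl(chains, ~ .x$acceptance[2]),
    w = purrr::map_dbl(chains, ~ .x$acceptance[3])
  )

  fit <- structure(
    list(draws = draws,
         acceptance = acceptance,
         seeds = list(master = seed, chains = chain_seeds),
         data = list(n = nrow(cohort), events = events),
         prior = prior, config = config,
         psrf_variant = "Gelman-Rubin 1992, sqrt form"),
    class = "stepcut_fit"
  )
  fit$diagnostics <- if (config$n_chains >= 2) gelman_rubin(fit) else NULL
  fit
}

derive_seeds <- function(master, k) {
  (abs(as.integer(master)) + 7919L * seq_len(k)) %% 2147483549L
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The 1992 formulation: with m chains of length n,
#' `W` the mean within-chain variance and `B/n` the variance of chain means,
#' the pooled variance estimate is `V = (n-1)/n W + B/n`, and
#' `PSRF = sqrt((m+1)/m * V/W - (n-1)/(m*n))`.  Chains with (numerically)
#' zero between- and within-variance return 1.
#'
#' @param fit A `stepcut_fit`, or a draws tibble with a `chain` column.
#' @param parameters Which columns to diagnose.
#' @return Tibble with columns `parameter`, `psrf`, plus a `variant`
#'   attribute naming the formulation.
#' @export
gelman_rubin <- function(fit, parameters = c("cp", "p1", "p2")) {
  draws <- if (inherits(fit, "stepcut_fit")) fit$draws else fit
  m <- length(unique(draws$chain))
  if (m < 2) abort("PSRF requires at least two chains.")
  lens <- table(draws$chain)
  if (length(unique(as.integer(lens))) != 1) {
    abort("chains must have equal length.")
  }
  n <- as.integer(lens[1])
  psrf <- purrr::map_dbl(parameters, function(p) {
    by_chain <- split(draws[[p]], draws$chain)
    means <- purrr::map_dbl(by_chain, mean)
    W <- mean(purrr::map_dbl(by_chain, var))
    B_over_n <- var(means)           # = B/n in the usual notation
    if (!is.finite(W) || (W < 1e-300 && B_over_n < 1e-300)) return(1)
    V <- (n - 1) / n * W + B_over_n
    val <- (m + 1) / m * V / W - (n - 1) / (m * n)
    sqrt(max(val, 0))
  })
  out <- tibble::tibble(parameter = parameters, psrf = psrf)
  attr(out, "variant") <- "Gelman-Rubin 1992, sqrt form"
  out
}

#' Posterior summaries of a fitted cutoff model
#'
#' Pooled-across-chains posterior mean, median and equal-tailed 95% credible
#' interval for each parameter.  `p2` is additionally labelled PPV and `p1`
#' 1 − NPV, the model's clinical reading of the two response probabilities.
#'
#' @param fit A `stepcut_fit`.
#' @param level Credible level (default 0.95, equal-tailed).
#' @return Tibble: `parameter`, `label`, `mean`, `median`, `lower`, `upper`,
#'   `psrf` (NA for single-chain fits).
#' @export
posterior_summary <- function(fit, level = 0.95) {
  draws <- fit$draws
  alpha <- (1 - level) / 2
  labels <- c(cp = "cutoff", p1 = "1-NPV", p2 = "PPV",
              cp1 = "cp1 (non-informative)", cp2 = "cp2 (informative)",
              w = "weight")
  pars <- names(labels)
  psrf <- if (!is.null(fit$diagnostics)) {
    all_d <- gelman_rubin(fit, parameters = pars)
    setNames(all_d$psrf, all_d$parameter)
  } else setNames(rep(NA_real_, length(pars)), pars)
  purrr::map_dfr(pars, function(p) {
    v <- draws[[p]]
    tibble::tibble(
      parameter = p,
      label = labels[[p]],
      mean = mean(v),
      median = median(v),
      lower = unname(quantile(v, alpha)),
      upper = unname(quantile(v, 1 - alpha)),
      psrf = unname(psrf[p])
    )
  })
}

#' Prior-predictive importance-sampling oracle for the posterior
#'
#' An independent route to the same posterior used to validate the MCMC
#' sampler: draw `(cp1, cp2, w, p2, p1)` from the prior `n_draws` times,
#' weight each draw by its likelihood, and report weighted means, medians and
#' equal-tailed 95% intervals.  Practical for small cohorts (the weights
#' degenerate as n grows); a low effective sample size triggers a warning.
#'
#' @param cohort Cohort tibble.
#' @param prior A [prior_spec()].
#' @param n_draws Number of prior draws.
#' @param seed Integer seed.
#' @param ess_floor Warn when the effective sample size falls below this.
#' @return Tibble like [posterior_summary()] (without `psrf`), plus
#'   attributes `ess` and `n_draws`.
#' @export
posterior_oracle <- function(cohort, prior = prior_spec(),
                             n_draws = 1e6, seed = 1L, ess_floor = 500) {
  if (nrow(cohort) == 0) abort("empty cohort.")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  cp1 <- runif(n_draws, prior$cp1_bounds[1], prior$cp1_bounds[2])
  cp2 <- runif(n_draws, prior$cp2_bounds[1], prior$cp2_bounds[2])
  w <- runif(n_draws, prior$w_bounds[1], prior$w_bounds[2])
  p2 <- runif(n_draws)
  p1 <- runif(n_draws) * p2
  cp <- w * cp1 + (1 - w) * cp2

  ord <- order(cohort$tsh)
  xs <- cohort$tsh[ord]
  cum <- cumsum(cohort$preterm[ord])
  n <- length(xs)
  S <- cum[n]
  idx <- findInterval(cp, xs)              # number of xs <= cp
  s1 <- ifelse(idx > 0, cum[pmax(idx, 1)], 0)
  n1 <- idx
  ll <- s1 * log(p1) + (n1 - s1) * log1p(-p1) +
    (S - s1) * log(p2) + (n - n1 - (S - s1)) * log1p(-p2)
  lw <- ll - max(ll)
  wts <- exp(lw)
  wts <- wts / sum(wts)
  ess <- 1 / sum(wts^2)
  if (ess < ess_floor) {
    warn(sprintf(
      "importance-sampling effective sample size is low (%.0f < %.0f); oracle summaries may be unstable.",
      ess, ess_floor))
  }

  wq <- function(v, probs) {
    o <- order(v)
    cw <- cumsum(wts[o])
    v[o][purrr::map_int(probs, ~ which(cw >= .x)[1])]
  }
  pars <- list(cp = cp, p1 = p1, p2 = p2, cp1 = cp1, cp2 = cp2, w = w)
  labels <- c(cp = "cutoff", p1 = "1-NPV", p2 = "PPV",
              cp1 = "cp1 (non-informative)", cp2 = "cp2 (informative)",
              w = "weight")
  out <- purrr::map_dfr(names(pars), function(p) {
    v <- pars[[p]]
    q <- wq(v, c(0.025, 0.5, 0.975))
    tibble::tibble(parameter = p, label = labels[[p]],
                   mean = sum(wts * v), median = q[2],
                   lower = q[1], upper = q[3])
  })
  attr(out, "ess") <- ess
  attr(out, "n_draws") <- n_draws
  out
}
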