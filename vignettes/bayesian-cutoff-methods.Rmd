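---
title: "Bayesian step-function cutoff estimation: model, priors, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian step-function cutoff estimation: model, priors, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepcut)
library(dplyr)
```

## The problem

Clinicians screening pregnant women for subclinical hypothyroidism need a
thyrotropin (TSH) threshold above which the risk of preterm birth rises enough
to justify intervention (levothyroxine). ROC-based cutoffs optimize
sensitivity and specificity, which describe the test, not the patient: what a
clinician acts on is the probability of preterm birth *given* the patient's
TSH side of the threshold — the positive predictive value (PPV) and
1 − negative predictive value (1 − NPV). `stepcut` estimates the threshold in
exactly those terms.

## The model

For marker values $x_i > 0$ (TSH, mIU/L) and binary outcomes
$y_i \in \{0, 1\}$ (preterm birth), the outcome follows a step function of
the marker:

$$
y_i \mid x_i \sim \mathrm{Bernoulli}\big(p(x_i)\big), \qquad
p(x) = \begin{cases} p_1 & x \le c_p \\ p_2 & x > c_p. \end{cases}
$$

The boundary is inclusive below: a subject exactly at the cutoff belongs to
the low-risk stratum. By construction $p_2 = \mathrm{PPV}$ and
$p_1 = 1 - \mathrm{NPV}$ of the dichotomized test, so the posterior speaks
the clinician's language directly.

**Priors.** The response probabilities use ordered uniforms,
$p_2 \sim U(0,1)$ and $p_1 \mid p_2 \sim U(0, p_2)$, encoding
$\mathrm{PPV} > 1 - \mathrm{NPV}$ (the marker must not be anti-predictive).
The cutoff gets a robust weighted sum of two uniform components,

$$
c_p = w\,c_{p1} + (1-w)\,c_{p2}, \quad
c_{p1} \sim U(0, 10), \quad c_{p2} \sim U(2, 4), \quad w \sim U(0, 1),
$$

an informative part spanning the old (2.5 mIU/L) and revised (4.0 mIU/L)
first-trimester TSH reference limits, and a non-informative part covering the
plausible assay range, mixed continuously so prior-data conflict cannot pin
the estimate to either component. We implement the weighted sum literally as
the displayed hierarchy — $c_p$ is a deterministic function of
$(c_{p1}, c_{p2}, w)$ carrying no extra density — rather than as a
two-component mixture density; the robust-mixture reading of the same
construction is available by pinning `w_bounds` at either extreme via
`prior_spec()`. The induced marginal prior on $c_p$ is smooth, supported on
$(0, 10)$, and concentrates mildly over $(2, 4)$.

**Identifiability.** The likelihood depends on $c_p$ only through the
dichotomized counts, so it is constant between adjacent order statistics of
the marker. Within such a plateau the posterior is shaped by the prior alone.
This is honest, not a defect: the data genuinely cannot distinguish cutoffs
that classify every subject identically, and credible intervals correctly
reflect that plateau width. Tests assert this likelihood-constancy
explicitly.

## Sampling

`fit_step_cutoff()` runs Metropolis-within-Gibbs (compiled, one pass per
iteration over nothing larger than a binary search into the sorted marker):

* $p_1$ is drawn exactly from its full conditional,
  $\mathrm{Beta}(s_1 + 1,\; n_1 - s_1 + 1)$ truncated to $(0, p_2)$, by
  inverse-CDF; $s_1$ of $n_1$ below-cutoff subjects had events.
* $p_2$ likewise from $\mathrm{Beta}(s_2,\; n_2 - s_2 + 1)$ truncated to
  $(p_1, 1)$ when $s_2 \ge 1$. When a proposed cutoff leaves the upper
  stratum without events ($s_2 = 0$), that Beta's first shape parameter is
  zero, so the draw falls back to an exact independence-Metropolis step
  against the conditional density $x^{-1}(1-x)^{n_2}$ on $(p_1, 1)$. An
  empty stratum contributes nothing to the likelihood and the proposal is
  evaluated normally — the priors keep the model proper.
* $c_{p1}$, $c_{p2}$ and $w$ get random-walk Metropolis updates on logit
  scales (with the Jacobian), one at a time. Proposal scales adapt toward
  ~44% acceptance during burn-in only and are frozen afterwards, so the
  retained draws come from a fixed, detailed-balance-preserving kernel.

Defaults mirror the motivating analysis: two chains, 10,000 burn-in
iterations, 50,000 retained. One master seed derives per-chain seeds
deterministically; all seeds are recorded in the fit object.

**Diagnostics.** `gelman_rubin()` implements the 1992 potential scale
reduction factor in its square-root form with the $(m+1)/m$ and finite-$n$
corrections (the variant name travels with the output as an attribute; the
degrees-of-freedom-corrected variant in coda agrees for well-mixed chains
and both flag divergence). A degenerate-variance guard returns 1 for
constant chains. The conventional acceptance band $[0.9, 1.2]$ is reported
as such — most formulations bound PSRF below by 1, and the band's lower edge
is a reporting convention, not a mathematical possibility we engineer for.

**The oracle.** `posterior_oracle()` reaches the same posterior by
prior-predictive importance sampling: draw the five primitives from the
prior, weight by the likelihood. It shares no code path with the sampler
beyond the likelihood definition and is the reference in the
oracle-equivalence tests (cutoff means within 0.05, probability means within
0.02 at $10^6$ draws on a 200-subject cohort). Its effective sample size
degrades as $n$ grows — the likelihood then occupies a vanishing corner of
the prior cube — so it warns below a configurable ESS floor and is a
small-cohort tool by design.

## Frequentist comparators

All comparators share the model's inclusive-below dichotomization and use
every distinct observed marker value as a candidate, with ties in the
objective broken toward the smallest cutoff (determinism; recorded in the
output):

* `empirical_auc()` is the Mann–Whitney pair probability (ties ½), hence
  invariant under strictly increasing marker transforms.
* `youden_cutoff()` maximizes sensitivity + specificity − 1.
* `psi_cutoff()` maximizes PPV + NPV − 1 (the predictive summary index).
  Candidates that empty a stratum are excluded rather than scored zero —
  treating an undefined predictive value as 0 would manufacture spurious
  argmaxes at the extremes. PSI is known to chase extreme cutoffs when a few
  extreme marker values are all events; a test constructs exactly that
  pathology.
* `bootstrap_ci()` does non-stratified case resampling with percentile
  2.5/97.5 intervals (B = 1000 default). Replicates where the statistic is
  undefined (e.g. a single-class resample) are dropped and counted in the
  output rather than imputed.

Both maximizers are verified against brute-force enumeration oracles on
hundreds of random small cohorts.

## Validation procedure

`split_sample()` makes a seeded 70/30 split (floor rule on the training
side). The cutoff is estimated on the training sample; a Bayesian logistic
regression on the above-cutoff indicator,
$\mathrm{logit}\, P(Y{=}1) = \beta_0 + \beta_1 \mathbf{1}(x > c)$, with
independent Normal(0, 10²) priors, is then cross-validated on the validation
sample. Folds are stratified by outcome — with ~8% event rates, unstratified
10-fold splits of a few hundred subjects would regularly produce eventless
folds. Predictions use posterior-mean coefficients: AUC depends only on the
ordering of predictions, which any monotone posterior summary preserves, so
nothing is lost relative to a full posterior-predictive average. The
cross-validated AUC is the mean of fold AUCs; its bootstrap CI resamples the
pooled held-out (prediction, outcome) pairs. The classical AUC on the same
validation data is reported beside it. Under separation the logistic fit
proceeds and flags that the prior determines the affected level.

Which data the original analysis fed each AUC is not reconstructable from
its description; the report states the package's choice (both AUCs on the
validation sample) in a `note` field, and the fold source is configurable.

## The synthetic generator

`cohort_spec()` defaults encode the reference study conditions: n = 1538;
log-normal TSH with median 1.6 mIU/L; outcomes from the step model with a
true cutoff at 4.0, event probability 0.014 below and 0.80 above (the
empirical stratum rates of the reference dichotomization), giving an overall
event rate near 8–9%; TPOAb positivity 5.1%; urinary iodine
sufficient/insufficient/missing at 31.9/38.6/29.5%; 17/126 of events flagged
induced. Two deliberate simplifications:

* A two-parameter log-normal cannot match the reference median (1.6) *and*
  both printed quartiles (0.9, 2.3), which are asymmetric on the log scale;
  the generator matches the median and the quartile ratio
  (`sdlog` ≈ 0.696 from the IQR). Consequently the simulated quartiles are
  ≈ (1.0, 2.6).
* Strata labels are drawn independently of the marker, although in real
  cohorts TPOAb-positive women have markedly higher TSH. Passing tests
  therefore demonstrate correctness of the estimators under the step-model
  assumptions, not robustness to marker–stratum correlation; a correlated
  generator would be the natural extension but has no published joint
  distribution to calibrate against.

Missing urinary-iodine status is generated as a label and never imputed,
matching the reference analysis. `fixture_cohort()` inverts a printed 2×2
dichotomized table into an exact cohort: marker values evenly spaced strictly
inside each side of the cutoff (no accidental ties at the boundary; a tie is
available on request to test the inclusive-below rule), outcome labels
shuffled within side under a fixed seed. Dichotomizing the fixture at its
cutoff reproduces the printed counts exactly, property-tested over random
tables.

## Numerical choices and degenerate inputs

* Point estimate: posterior mean (headline), median also reported; intervals
  are equal-tailed 2.5/97.5 quantiles.
* Contingency tables in `run_full_analysis()` dichotomize at the posterior
  mean rounded to 2 decimals, matching clinical reporting of such cutoffs.
* Probabilities clamped to `[1e-12, 1 - 1e-12]` inside the sampler guard
  against inverse-CDF underflow at extreme truncations.
* All-event or event-free cohorts are rejected up front (the step model is
  unidentified); populations that fail this inside the pipeline are skipped
  with a note while other populations complete.
* Empty-stratum likelihood contributions are zero by contract;
  probabilities at 0 or 1 against non-zero counts give −∞, never an error.
* `p1 = p2` generators are allowed (deliberate no-signal cohorts) though the
  prior itself enforces strict ordering.

## Problem sizes in the test-suite

The suite fits hundreds of models, so simulation sizes are chosen to keep
each check sharp but cheap: oracle equivalence at n = 200 with $10^6$ prior
draws; interval calibration over 100 replicate cohorts of n = 1500 with a
shortened chain (2,000 burn-in / 10,000 kept — ample for a 6-parameter model
whose conditionals mix in a handful of iterations); comparator oracles on
cohorts of n ≤ 30 where exhaustive enumeration is exact. The default
two-chain 10k/50k fit on n = 1538 runs in about a second.

## Known limitations

* The cutoff posterior between order statistics is prior-driven (see
  Identifiability); with sparse data above the cutoff the posterior mean can
  sit visibly above the last observed low-risk value.
* The importance-sampling oracle is unusable beyond a few thousand subjects.
* PSI's drift to extremes is reported faithfully, not corrected.
* The generator's independence of marker and strata understates subgroup
  differences seen in real thyroid cohorts.
* Reading SPSS files requires the optional foreign package and maps columns
  through a user-supplied mapping; value labels are not interpreted.
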