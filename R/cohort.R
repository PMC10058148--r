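#' Specify a synthetic biomarker cohort
#'
#' Defines the generating process for a synthetic pregnancy cohort: a
#' right-skewed (log-normal) biomarker, here thyrotropin (TSH, mIU/L), and a
#' binary outcome (preterm birth) drawn from a step function of the marker —
#' event probability `p_below` when the marker is at or below `true_cutoff`
#' and `p_above` when it exceeds it.  Strata labels (TPOAb status, urinary
#' iodine category) are assigned independently of the marker at the given
#' marginal fractions.
#'
#' The defaults emulate a population-based thyroid-and-pregnancy screening
#' cohort: n = 1538 subjects, TSH median 1.6 mIU/L with interquartile range
#' 0.9–2.3 (log-normal fit), a step at 4.0 mIU/L, TPOAb positivity 5.1%,
#' urinary iodine strata 31.9% / 38.6% / 29.5%
#' (sufficient / insufficient / missing), and roughly 13.5% of events
#' flagged as induced rather than spontaneous preterm births.
#'
#' @param n Cohort size (positive integer).
#' @param meanlog,sdlog Log-normal parameters of the marker distribution.
#'   The default `sdlog` is fitted so the quartiles match 0.9 and 2.3 when
#'   the median is 1.6.
#' @param true_cutoff Marker value at which the event probability steps up
#'   (mIU/L).
#' @param p_below,p_above Event probabilities at or below / above the cutoff;
#'   must satisfy `0 < p_below < p_above < 1` (the model's
#'   PPV > 1 − NPV ordering), or be equal for a deliberately signal-free
#'   cohort.
#' @param tpoab_pos Marginal fraction of TPOAb-positive subjects.
#' @param tpoab_missing Fraction with missing TPOAb status.
#' @param uic_sufficient,uic_insufficient,uic_missing Urinary-iodine strata
#'   fractions; must sum to 1.
#' @param induced_frac Fraction of events flagged as induced preterm births.
#' @return A `stepcut_spec` list, validated.
#' @export
#' @examples
#' spec <- cohort_spec(n = 500)
#' cohort <- simulate_cohort(spec, seed = 1)
cohort_spec <- function(n = 1538,
                        meanlog = log(1.6),
                        sdlog = (log(2.3) - log(0.9)) / (2 * qnorm(0.75)),
                        true_cutoff = 4.0,
                        p_below = 0.014,
                        p_above = 0.80,
                        tpoab_pos = 0.051,
                        tpoab_missing = 0,
                        uic_sufficient = 0.319,
                        uic_insufficient = 0.386,
                        uic_missing = 0.295,
                        induced_frac = 17 / 126) {
  spec <- list(
    n = n, meanlog = meanlog, sdlog = sdlog, true_cutoff = true_cutoff,
    p_below = p_below, p_above = p_above,
    tpoab_pos = tpoab_pos, tpoab_missing = tpoab_missing,
    uic_sufficient = uic_sufficient, uic_insufficient = uic_insufficient,
    uic_missing = uic_missing, induced_frac = induced_frac
  )
  validate_cohort_spec(spec)
  structure(spec, class = "stepcut_spec")
}

validate_cohort_spec <- function(spec) {
  if (!is.numeric(spec$n) || length(spec$n) != 1 || spec$n < 1 ||
      spec$n != round(spec$n)) {
    abort("`n` must be a positive integer (violated: n >= 1).")
  }
  if (spec$sdlog <= 0) abort("`sdlog` must be positive.")
  if (spec$true_cutoff <= 0) abort("`true_cutoff` must be positive.")
  for (p in c("p_below", "p_above", "tpoab_pos", "tpoab_missing",
              "uic_sufficient", "uic_insufficient", "uic_missing",
              "induced_frac")) {
    v <- spec[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must lie in [0, 1].", p))
    }
  }
  if (spec$p_below > spec$p_above) {
    abort(paste0("invalid event probabilities: p_below > p_above violates ",
                 "the ordering 0 < p_below <= p_above < 1."))
  }
  usum <- spec$uic_sufficient + spec$uic_insufficient + spec$uic_missing
  if (abs(usum - 1) > 1e-8) {
    abort("urinary-iodine fractions must sum to 1 (violated: sum == 1).")
  }
  if (spec$tpoab_pos + spec$tpoab_missing > 1) {
    abort("TPOAb fractions exceed 1.")
  }
  invisible(spec)
}

#' Generate a synthetic cohort from a specification
#'
#' Draws `n` marker values i.i.d. from the spec's log-normal distribution,
#' then draws each outcome from the step model: Bernoulli(`p_below`) when the
#' marker is at or below `true_cutoff` (the boundary is inclusive below) and
#' Bernoulli(`p_above`) otherwise.  Strata labels and the induced flag are
#' then attached with [attach_subgroups()].
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A tibble with columns `subject_id`, `tsh`, `preterm`, `tpoab`,
#'   `uic`, `induced`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  validate_cohort_spec(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  tsh <- rlnorm(spec$n, meanlog = spec$meanlog, sdlog = spec$sdlog)
  p <- ifelse(tsh <= spec$true_cutoff, spec$p_below, spec$p_above)
  preterm <- rbinom(spec$n, 1L, p)
  cohort <- tibble::tibble(
    subject_id = sprintf("S%05d", seq_len(spec$n)),
    tsh = tsh,
    preterm = as.integer(preterm),
    tpoab = NA_character_,
    uic = NA_character_,
    induced = NA_integer_
  )
  attach_subgroups(cohort, spec)
}

#' Attach (or overwrite) stratum labels on a cohort
#'
#' Assigns TPOAb status, urinary-iodine category and the induced-birth flag
#' by independent draws at the spec's marginal fractions.  Labels are drawn
#' independently of the marker; the induced flag is assigned only among
#' events (non-events get 0).  Uses the current RNG state, so call inside a
#' seeded context for reproducibility ([simulate_cohort()] does this).
#'
#' @param cohort A cohort tibble (see [simulate_cohort()]).
#' @param spec A [cohort_spec()] supplying the fractions.
#' @return The cohort with `tpoab`, `uic`, `induced` overwritten.
#' @export
attach_subgroups <- function(cohort, spec) {
  validate_cohort_spec(spec)
  n <- nrow(cohort)
  tp <- runif(n)
  tpoab <- dplyr::case_when(
    tp < spec$tpoab_pos ~ "positive",
    tp < spec$tpoab_pos + spec$tpoab_missing ~ NA_character_,
    TRUE ~ "negative"
  )
  uu <- runif(n)
  uic <- dplyr::case_when(
    uu < spec$uic_sufficient ~ "sufficient",
    uu < spec$uic_sufficient + spec$uic_insufficient ~ "insufficient",
    TRUE ~ NA_character_
  )
  induced <- integer(n)
  ev <- which(cohort$preterm == 1L)
  if (length(ev) > 0 && spec$induced_frac > 0) {
    induced[ev] <- as.integer(runif(length(ev)) < spec$induced_frac)
  }
  cohort$tpoab <- tpoab
  cohort$uic <- uic
  cohort$induced <- induced
  cohort
}

#' Published dichotomized TSH / preterm-birth frequency tables
#'
#' Contingency counts from a population-based pregnancy thyroid-screening
#' study (n = 1538), dichotomized at the study's model-estimated optimal TSH
#' cutoff per analysis population.  These printed counts serve as exact
#' fixtures: [fixture_cohort()] reconstructs a cohort whose dichotomization
#' reproduces them.
#'
#' @return A tibble with one row per population (`total`,
#'   `tpoab_neg_uic_sufficient`, `tpoab_pos_uic_insufficient`) and columns
#'   `cutoff`, `below_no`, `below_yes`, `above_no`, `above_yes`.
#' @export
#' @examples
#' preterm_tsh_counts()
preterm_tsh_counts <- function() {
  tibble::tribble(
    ~population,                 ~cutoff, ~below_no, ~below_yes, ~above_no, ~above_yes,
    "total",                      3.97,      1387L,        20L,       25L,      106L,
    "tpoab_neg_uic_sufficient",   3.92,       436L,         4L,       11L,       28L,
    "tpoab_pos_uic_insufficient", 4.00,        35L,         0L,        2L,        4L
  )
}

#' Reconstruct a cohort from dichotomized counts
#'
#' Inverse of [sufficient_stats()]: builds a cohort whose dichotomization at
#' `counts$cutoff` reproduces the given 2x2 counts exactly.  Marker values
#' are evenly spaced strictly inside each side of the cutoff — below-cutoff
#' records strictly within `(marker_range[1], cutoff)`, above-cutoff strictly
#' within `(cutoff, marker_range[2])` — so no record ties the cutoff unless
#' `tie_at_cutoff = TRUE`, which places the largest below-side marker exactly
#' at the cutoff.  Outcome labels are shuffled across positions within each
#' side (deterministically, given `seed`), matching the step model's
#' assumption that outcome and marker are independent within a side.
#'
#' @param counts One row of a counts tibble with columns `cutoff`,
#'   `below_no`, `below_yes`, `above_no`, `above_yes`
#'   (see [preterm_tsh_counts()]).
#' @param marker_range Length-2 numeric bracketing the cutoff.
#' @param seed Integer seed for the within-side label shuffle.
#' @param tie_at_cutoff Place one below-side marker exactly at the cutoff.
#' @return A cohort tibble.
#' @export
#' @examples
#' counts <- dplyr::filter(preterm_tsh_counts(), population == "total")
#' fx <- fixture_cohort(counts)
#' sufficient_stats(fx, 3.97)
fixture_cohort <- function(counts, marker_range = c(0.1, 10), seed = 1L,
                           tie_at_cutoff = FALSE) {
  stopifnot(nrow(counts) == 1)
  cutoff <- counts$cutoff
  nb <- counts$below_no + counts$below_yes
  na_ <- counts$above_no + counts$above_yes
  if (any(c(counts$below_no, counts$below_yes,
            counts$above_no, counts$above_yes) < 0)) {
    abort("counts must be non-negative.")
  }
  if (nb + na_ == 0) abort("empty cohort: all four counts are zero.")
  if (!(marker_range[1] < cutoff && cutoff < marker_range[2])) {
    abort("`marker_range` must bracket the cutoff.")
  }

  below_x <- if (nb > 0) {
    g <- seq(marker_range[1], cutoff, length.out = nb + 2L)
    g[seq(2L, nb + 1L)]
  } else numeric(0)
  if (tie_at_cutoff && nb > 0) below_x[nb] <- cutoff
  above_x <- if (na_ > 0) {
    g <- seq(cutoff, marker_range[2], length.out = na_ + 2L)
    g[seq(2L, na_ + 1L)]
  } else numeric(0)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  below_y <- sample(rep(c(0L, 1L), c(counts$below_no, counts$below_yes)))
  above_y <- sample(rep(c(0L, 1L), c(counts$above_no, counts$above_yes)))

  tibble::tibble(
    subject_id = sprintf("F%05d", seq_len(nb + na_)),
    tsh = c(below_x, above_x),
    preterm = c(below_y, above_y),
    tpoab = NA_character_,
    uic = NA_character_,
    induced = 0L
  )
}

#' Write / read a cohort as CSV
#'
#' The on-disk layout has header `subject_id, tsh, preterm, tpoab, uic,
#' induced`; missing categorical values are written as empty fields.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      tsh = readr::col_double(),
      preterm = readr::col_integer(),
      tpoab = readr::col_character(),
      uic = readr::col_character(),
      induced = readr::col_integer()
    ),
    na = c("", "NA")
  )
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
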