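#' Load a cohort from CSV (or SPSS .sav) with a column mapping
#'
#' Maps arbitrary source columns onto the canonical cohort layout
#' (`subject_id`, `tsh`, `preterm`, `tpoab`, `uic`, `induced`).  Rows with a
#' missing marker or outcome are dropped and counted (attribute
#' `n_dropped`); missing strata are retained as missing — no imputation.
#' Duplicate subject ids are rejected.
#'
#' @param path CSV file, or an SPSS `.sav` file (read via the foreign
#'   package) when the extension is `.sav`.
#' @param column_mapping Named character vector mapping canonical names to
#'   source columns, e.g. `c(tsh = "TSH_1st", preterm = "PTB")`.  Canonical
#'   names absent from the mapping are taken verbatim; of the canonical
#'   columns only `tsh` and `preterm` are required to exist.
#' @return Cohort tibble with attribute `n_dropped`.
#' @export
load_cohort <- function(path, column_mapping = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- if (grepl("\\.sav$", path, ignore.case = TRUE)) {
    if (!requireNamespace("foreign", quietly = TRUE)) {
      abort("reading .sav files requires the foreign package.")
    }
    tibble::as_tibble(foreign::read.spss(path, to.data.frame = TRUE,
                                         use.value.labels = FALSE))
  } else {
    readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  }

  canonical <- c("subject_id", "tsh", "preterm", "tpoab", "uic", "induced")
  mapping <- setNames(canonical, canonical)
  if (!is.null(column_mapping)) mapping[names(column_mapping)] <- column_mapping

  for (req in c("tsh", "preterm")) {
    if (!mapping[[req]] %in% names(raw)) {
      abort(sprintf("mapped column \"%s\" (for %s) is missing from %s.",
                    mapping[[req]], req, basename(path)))
    }
  }
  pick <- function(col) {
    if (mapping[[col]] %in% names(raw)) raw[[mapping[[col]]]] else NULL
  }
  cohort <- tibble::tibble(
    subject_id = pick("subject_id") %||% sprintf("R%05d", seq_len(nrow(raw))),
    tsh = as.numeric(pick("tsh")),
    preterm = as.integer(pick("preterm")),
    tpoab = as.character(pick("tpoab") %||% NA_character_),
    uic = as.character(pick("uic") %||% NA_character_),
    induced = as.integer(pick("induced") %||% NA_integer_)
  )
  keep <- complete.cases(cohort[, c("tsh", "preterm")])
  dropped <- sum(!keep)
  cohort <- cohort[keep, ]
  if (anyDuplicated(cohort$subject_id)) {
    abort("duplicate subject ids in the input.")
  }
  attr(cohort, "n_dropped") <- dropped
  cohort
}

#' The study's analysis populations
#'
#' Splits a cohort into the three analysis populations: everyone; TPOAb
#' negative with sufficient urinary iodine; TPOAb positive with insufficient
#' urinary iodine.  When categorical labels are absent but raw assays are
#' present (`tpoab_iu` in IU/mL, `muic_ugl` in ug/L), labels are derived
#' from the study thresholds: TPOAb < 50 IU/mL is negative (50 itself is
#' positive), and urinary iodine < 150 ug/L is insufficient (150 itself is
#' sufficient).
#'
#' @param cohort Cohort tibble; may carry `tpoab_iu` / `muic_ugl` columns.
#' @return Tibble with columns `population`, `n`, `events` and a `data`
#'   list-column of subcohorts.  Empty populations are retained with a note.
#' @export
define_populations <- function(cohort) {
  if (!("tpoab" %in% names(cohort)) || all(is.na(cohort$tpoab))) {
    if ("tpoab_iu" %in% names(cohort)) {
      cohort$tpoab <- ifelse(is.na(cohort$tpoab_iu), NA_character_,
                             ifelse(cohort$tpoab_iu < 50, "negative",
                                    "positive"))
    } else if (!("tpoab" %in% names(cohort))) cohort$tpoab <- NA_character_
  }
  if (!("uic" %in% names(cohort)) || all(is.na(cohort$uic))) {
    if ("muic_ugl" %in% names(cohort)) {
      cohort$uic <- ifelse(is.na(cohort$muic_ugl), NA_character_,
                           ifelse(cohort$muic_ugl < 150, "insufficient",
                                  "sufficient"))
    } else if (!("uic" %in% names(cohort))) cohort$uic <- NA_character_
  }
  subsets <- list(
    total = cohort,
    tpoab_neg_uic_sufficient = dplyr::filter(
      cohort, .data$tpoab == "negative" & .data$uic == "sufficient"),
    tpoab_pos_uic_insufficient = dplyr::filter(
      cohort, .data$tpoab == "positive" & .data$uic == "insufficient")
  )
  tibble::tibble(
    population = names(subsets),
    n = unname(purrr::map_int(subsets, nrow)),
    events = unname(purrr::map_int(subsets, ~ sum(.x$preterm, na.rm = TRUE))),
    data = unname(subsets)
  )
}

#' Table-1-style cohort description
#'
#' @param cohort Cohort tibble.
#' @return One-row tibble: size, events and event rate, marker
#'   median/quartiles, strata counts.
#' @export
describe_cohort <- function(cohort) {
  n <- nrow(cohort)
  if (n == 0) {
    return(tibble::tibble(n = 0L, events = 0L, event_rate = NA_real_,
                          tsh_median = NA_real_, tsh_q1 = NA_real_,
                          tsh_q3 = NA_real_,
                          tpoab_positive = 0L, tpoab_negative = 0L,
                          tpoab_missing = 0L, uic_sufficient = 0L,
                          uic_insufficient = 0L, uic_missing = 0L))
  }
  q <- unname(quantile(cohort$tsh, c(0.25, 0.5, 0.75)))
  tibble::tibble(
    n = n,
    events = sum(cohort$preterm),
    event_rate = sum(cohort$preterm) / n,
    tsh_median = q[2], tsh_q1 = q[1], tsh_q3 = q[3],
    tpoab_positive = sum(cohort$tpoab == "positive", na.rm = TRUE),
    tpoab_negative = sum(cohort$tpoab == "negative", na.rm = TRUE),
    tpoab_missing = sum(is.na(cohort$tpoab)),
    uic_sufficient = sum(cohort$uic == "sufficient", na.rm = TRUE),
    uic_insufficient = sum(cohort$uic == "insufficient", na.rm = TRUE),
    uic_missing = sum(is.na(cohort$uic))
  )
}

#' Configure a full analysis run
#'
#' @param prior A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param comparators Run Youden/PSI/ROC on the total population.
#' @param bootstrap_B Bootstrap replicates for comparator CIs (0 disables).
#' @param validate Run the 70/30 split + cross-validated AUC.
#' @param cv_k Folds for the cross-validated AUC.
#' @param sensitivity_priors Named list of alternate [prior_spec()]s to
#'   re-run; defaults bracket the prior's influence (shifted informative
#'   support, widened non-informative support, weight pinned near each
#'   extreme).
#' @param exclude_induced Also re-run with induced preterm births removed.
#' @param seed Master seed; every stage derives its own seed from it.
#' @return A `stepcut_analysis_config` list.
#' @export
analysis_config <- function(prior = prior_spec(),
                            mcmc = mcmc_config(),
                            comparators = TRUE,
                            bootstrap_B = 1000L,
                            validate = TRUE,
                            cv_k = 10L,
                            sensitivity_priors = default_sensitivity_priors(),
                            exclude_induced = TRUE,
                            seed = 1L) {
  structure(list(prior = prior, mcmc = mcmc, comparators = comparators,
                 bootstrap_B = as.integer(bootstrap_B),
                 validate = validate, cv_k = as.integer(cv_k),
                 sensitivity_priors = sensitivity_priors,
                 exclude_induced = exclude_induced,
                 seed = as.integer(seed)),
            class = "stepcut_analysis_config")
}

#' @rdname analysis_config
#' @export
default_sensitivity_priors <- function() {
  list(
    informative_shifted = prior_spec(cp2_bounds = c(2.5, 4.5)),
    noninformative_wide = prior_spec(cp1_bounds = c(0, 15)),
    weight_noninformative = prior_spec(w_bounds = c(1 - 1e-6, 1)),
    weight_informative = prior_spec(w_bounds = c(0, 1e-6))
  )
}

#' Read an analysis configuration from YAML
#'
#' Flat YAML with optional sections `prior` (`cp1_bounds`, `cp2_bounds`,
#' `w_bounds`), `mcmc` (`n_chains`, `burn_in`, `n_keep`, `thin`) and
#' top-level keys matching the arguments of [analysis_config()].
#'
#' @param path YAML file.
#' @return A `stepcut_analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  prior <- do.call(prior_spec, y$prior %||% list())
  mcmc <- do.call(mcmc_config, y$mcmc %||% list())
  args <- y[setdiff(names(y), c("prior", "mcmc"))]
  do.call(analysis_config, c(list(prior = prior, mcmc = mcmc), args))
}

#' Run the full cutoff analysis
#'
#' For each analysis population (see [define_populations()]): Bayesian fit
#' with posterior summaries and convergence diagnostics, the dichotomized
#' contingency table at the population's posterior-mean cutoff (rounded to
#' two decimals, matching how such cutoffs are reported clinically), and,
#' where enabled, the frequentist comparators on the total population,
#' split-sample validation with cross-validated AUC, and sensitivity
#' analyses (alternate priors; excluding induced preterm births).
#' Populations with too few events to fit are reported with a note rather
#' than failing the run.  The result is deterministic given the config's
#' master seed.
#'
#' @param cohort Cohort tibble.
#' @param config An [analysis_config()].
#' @return A `stepcut_report` list.
#' @export
run_full_analysis <- function(cohort, config = analysis_config()) {
  seed <- config$seed
  pops <- define_populations(cohort)

  fit_one <- function(data, pop_seed) {
    if (nrow(data) < 2 || sum(data$preterm) == 0 ||
        sum(data$preterm) == nrow(data)) {
      return(list(note = "skipped: needs both events and non-events"))
    }
    fit <- fit_step_cutoff(data, prior = config$prior, config = config$mcmc,
                           seed = pop_seed)
    summ <- posterior_summary(fit)
    cut <- round(summ$mean[summ$parameter == "cp"], 2)
    st <- sufficient_stats(data, cut)
    list(summary = summ, cutoff = cut,
         contingency = st,
         predictive = predictive_values(data, cut),
         diagnostics = fit$diagnostics,
         acceptance = fit$acceptance,
         seeds = fit$seeds)
  }

  pop_seeds <- derive_seeds(seed, nrow(pops) + 10L)
  bayes <- purrr::map2(pops$data, pop_seeds[seq_len(nrow(pops))], fit_one)
  names(bayes) <- pops$population

  comp <- NULL
  if (isTRUE(config$comparators)) {
    total <- pops$data[[1]]
    comp <- list(
      youden = youden_cutoff(total),
      psi = psi_cutoff(total),
      auc = empirical_auc(total)
    )
    if (config$bootstrap_B > 0) {
      comp$youden_ci <- bootstrap_ci(total, "youden_cutoff",
                                     B = config$bootstrap_B,
                                     seed = pop_seeds[nrow(pops) + 1L])
      comp$psi_ci <- bootstrap_ci(total, "psi_cutoff",
                                  B = config$bootstrap_B,
                                  seed = pop_seeds[nrow(pops) + 2L])
      comp$auc_ci <- bootstrap_ci(total, "auc", B = config$bootstrap_B,
                                  seed = pop_seeds[nrow(pops) + 3L])
    }
  }

  valid <- NULL
  if (isTRUE(config$validate)) {
    total <- pops$data[[1]]
    plan <- split_sample(total, 0.7, seed = pop_seeds[nrow(pops) + 4L])
    train <- total[total$subject_id %in% plan$train_ids, ]
    vdata <- total[total$subject_id %in% plan$validation_ids, ]
    tfit <- fit_step_cutoff(train, prior = config$prior,
                            config = config$mcmc,
                            seed = pop_seeds[nrow(pops) + 5L])
    tsum <- posterior_summary(tfit)
    tcut <- round(tsum$mean[tsum$parameter == "cp"], 2)
    cv <- cv_auc(vdata, tcut, k = config$cv_k,
                 seed = pop_seeds[nrow(pops) + 6L])
    full_fit <- fit_bayes_logistic(vdata, tcut,
                                   seed = pop_seeds[nrow(pops) + 7L])
    classical_auc <- pred_auc(predict(full_fit, vdata), vdata$preterm)
    valid <- list(
      train_cutoff = tcut,
      train_summary = tsum,
      split = list(n_train = nrow(train), n_validation = nrow(vdata),
                   seed = plan$seed),
      fold_auc = cv$fold_auc, cv_auc = cv$cv_auc, cv_auc_ci = cv$ci,
      classical_auc = classical_auc,
      note = paste0("cutoff estimated on the 70% training sample; ",
                    "cross-validated and classical AUC both computed on ",
                    "the 30% validation sample")
    )
  }

  sens <- list()
  if (length(config$sensitivity_priors) > 0) {
    total <- pops$data[[1]]
    base_cut <- bayes$total$cutoff
    sens$priors <- purrr::imap(config$sensitivity_priors, function(pr, nm) {
      f <- fit_step_cutoff(total, prior = pr, config = config$mcmc,
                           seed = pop_seeds[1])
      s <- posterior_summary(f)
      cut <- round(s$mean[s$parameter == "cp"], 2)
      tibble::tibble(prior = nm, cutoff = cut, delta = cut - base_cut)
    })
  }
  if (isTRUE(config$exclude_induced)) {
    total <- pops$data[[1]]
    kept <- total[is.na(total$induced) | total$induced == 0L |
                    total$preterm == 0L, ]
    if (sum(kept$preterm) > 0 && sum(kept$preterm) < nrow(kept)) {
      f <- fit_step_cutoff(kept, prior = config$prior, config = config$mcmc,
                           seed = pop_seeds[1])
      s <- posterior_summary(f)
      sens$exclude_induced <- list(
        n_excluded = nrow(total) - nrow(kept),
        cutoff = round(s$mean[s$parameter == "cp"], 2),
        delta = round(s$mean[s$parameter == "cp"], 2) - bayes$total$cutoff
      )
    }
  }

  structure(list(
    populations = pops[, c("population", "n", "events")],
    description = purrr::map(setNames(pops$data, pops$population),
                             describe_cohort),
    bayes = bayes,
    comparators = comp,
    validation = valid,
    sensitivity = sens,
    config = list(seed = seed,
                  mcmc = unclass(config$mcmc),
                  prior = unclass(config$prior))
  ), class = "stepcut_report")
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (the machine-readable report) and per-population
#' `contingency_<population>.csv` tables.
#'
#' @param report A `stepcut_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(report_to_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (pop in names(report$bayes)) {
    b <- report$bayes[[pop]]
    if (!is.null(b$contingency)) {
      readr::write_csv(b$contingency,
                       file.path(dir, paste0("contingency_", pop, ".csv")))
    }
  }
  invisible(dir)
}

report_to_list <- function(report) {
  simplify <- function(x) {
    if (inherits(x, "data.frame")) return(as.list(as.data.frame(x)))
    if (is.list(x)) return(purrr::map(x, simplify))
    x
  }
  simplify(unclass(report))
}
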