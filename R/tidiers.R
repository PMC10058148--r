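#' Tidy a fitted step-cutoff model
#'
#' One row per model parameter with posterior mean, median, equal-tailed 95%
#' credible bounds and PSRF (broom convention).
#'
#' @param x A `stepcut_fit`.
#' @param level Credible level.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.stepcut_fit <- function(x, level = 0.95, ...) {
  posterior_summary(x, level = level)
}

#' Glance at a fitted step-cutoff model
#'
#' @param x A `stepcut_fit`.
#' @param ... Unused.
#' @return One-row tibble: `cutoff`, `cutoff_lower`, `cutoff_upper`, `ppv`,
#'   `one_minus_npv`, `psrf_max`, `n`, `events`, `n_chains`, `n_draws`.
#' @export
glance.stepcut_fit <- function(x, ...) {
  s <- posterior_summary(x)
  row <- function(p, col) s[[col]][s$parameter == p]
  tibble::tibble(
    cutoff = row("cp", "mean"),
    cutoff_lower = row("cp", "lower"),
    cutoff_upper = row("cp", "upper"),
    ppv = row("p2", "mean"),
    one_minus_npv = row("p1", "mean"),
    psrf_max = if (is.null(x$diagnostics)) NA_real_ else max(x$diagnostics$psrf),
    n = x$data$n,
    events = x$data$events,
    n_chains = x$config$n_chains,
    n_draws = nrow(x$draws)
  )
}

#' @export
print.stepcut_fit <- function(x, ...) {
  g <- glance(x)
  cat("Bayesian step-function cutoff model\n")
  cat(sprintf("  n = %d subjects, %d events; %d chain(s) x %d draws\n",
              g$n, g$events, g$n_chains, x$config$n_keep))
  cat(sprintf("  cutoff (posterior mean): %.3f  [%.3f, %.3f] 95%% CrI\n",
              g$cutoff, g$cutoff_lower, g$cutoff_upper))
  cat(sprintf("  PPV: %.3f   1-NPV: %.3f\n", g$ppv, g$one_minus_npv))
  if (!is.na(g$psrf_max)) {
    cat(sprintf("  max PSRF (%s): %.3f\n", x$psrf_variant, g$psrf_max))
  }
  invisible(x)
}

#' Tidy a cross-validated AUC result
#'
#' @param x A `stepcut_cv`.
#' @param ... Unused.
#' @return Tibble with one row per fold.
#' @export
tidy.stepcut_cv <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$fold_auc), auc = x$fold_auc)
}

#' @export
glance.stepcut_cv <- function(x, ...) {
  tibble::tibble(cv_auc = x$cv_auc, ci_lower = x$ci[1], ci_upper = x$ci[2],
                 k = x$k, B = x$B, seed = x$seed)
}

#' @export
print.stepcut_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated AUC: %.3f  [%.3f, %.3f] 95%% CI\n",
              x$k, x$cv_auc, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Posterior density panels for a fitted cutoff model
#'
#' Density of the cutoff, 1 − NPV (`p1`) and PPV (`p2`) pooled across
#' chains, with a vertical line at each posterior median.
#'
#' @param object A `stepcut_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stepcut_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$draws, c("cp", "p1", "p2"),
                              names_to = "parameter", values_to = "value")
  labels <- c(cp = "cutoff (mIU/L)", p1 = "p1 = 1 - NPV", p2 = "p2 = PPV")
  long$parameter <- factor(labels[long$parameter], levels = unname(labels))
  med <- dplyr::summarise(dplyr::group_by(long, .data$parameter),
                          median = median(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80", colour = "grey30") +
    ggplot2::geom_vline(data = med,
                        ggplot2::aes(xintercept = .data$median),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Trace plot of the MCMC chains
#'
#' @param fit A `stepcut_fit`.
#' @param parameters Which parameters to show.
#' @return A ggplot.
#' @export
plot_trace <- function(fit, parameters = c("cp", "p1", "p2")) {
  long <- tidyr::pivot_longer(fit$draws, dplyr::all_of(parameters),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iter, y = .data$value,
                                     colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "iteration", y = NULL, colour = "chain") +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param object A `stepcut_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot annotated with the AUC.
#' @export
autoplot.stepcut_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = 1 - .data$specificity,
                                       y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::annotate("text", x = 0.75, y = 0.1,
                      label = sprintf("AUC = %.3f", attr(object, "auc"))) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Fold-AUC plot for cross-validation results
#'
#' @param object A `stepcut_cv`.
#' @param ... Unused.
#' @return A ggplot of per-fold AUCs with the cross-validated mean.
#' @export
autoplot.stepcut_cv <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fold, y = .data$auc)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$cv_auc, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = d$fold) +
    ggplot2::labs(x = "fold", y = "held-out AUC") +
    ggplot2::theme_minimal()
}
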