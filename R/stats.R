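#' Wilcoxon rank-sum (Mann-Whitney) comparison of two samples
#'
#' Thin, tidy wrapper around the exact / normal-approximation rank-sum test:
#' exact enumeration when both samples are small and tie-free, tie-corrected
#' normal approximation otherwise. `alternative = "a_less"` tests the
#' hypothesis that `a` is stochastically smaller than `b`.
#'
#' @param a,b Numeric vectors (nonempty).
#' @param alternative One of "two_sided", "a_less", "a_greater".
#' @return A one-row tibble (statistic, p_value, alternative, method).
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = c("two_sided", "a_less", "a_greater")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) abort("empty group in Wilcoxon test")
  alt <- switch(alternative,
    two_sided = "two.sided", a_less = "less", a_greater = "greater"
  )
  wt <- suppressWarnings(wilcox.test(a, b, alternative = alt, correct = TRUE))
  tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    alternative = alternative,
    method = wt$method
  )
}

#' Covariate-adjusted binomial GLM for per-gene proportions
#'
#' Models per-gene favorable/eligible read counts with a logit link,
#' adjusting the gbM-vs-UM class effect for gene length and expression:
#'
#' `cbind(favorable, eligible - favorable) ~ class + log10(length) +
#' log10(1 + expression)`
#'
#' The family is quasibinomial, so the dispersion is estimated and standard
#' errors are robust to overdispersion across genes. The class factor is
#' coded with gbM as the reference level, so the class coefficient is the
#' UM - gbM contrast on the link scale (positive = UM higher).
#'
#' @param data A data frame with columns `class_label` (values "gbM"/"UM"),
#'   `favorable_count`, `eligible_count`, `gene_length`, `expression_proxy`.
#' @return An object of class `prop_glm` wrapping the fit; supports
#'   [tidy()], [glance()] and [class_contrast()].
#' @export
fit_proportion_glm <- function(data) {
  data <- as_tibble(data) |>
    filter(
      .data$class_label %in% c("gbM", "UM"),
      !is.na(.data$favorable_count), !is.na(.data$eligible_count),
      .data$eligible_count > 0
    )
  n_per <- data |> count(.data$class_label)
  if (nrow(n_per) < 2 || any(n_per$n < 2)) {
    abort("need at least 2 genes in each of gbM and UM")
  }
  df <- data |>
    mutate(
      class = factor(.data$class_label, levels = c("gbM", "UM")),
      log_length = log10(.data$gene_length),
      log_expr = log10(1 + .data$expression_proxy)
    )
  drop_const <- c(
    if (dplyr::n_distinct(df$log_length) == 1) "log_length",
    if (dplyr::n_distinct(df$log_expr) == 1) "log_expr"
  )
  terms <- setdiff(c("class", "log_length", "log_expr"), drop_const)
  fml <- stats::as.formula(paste(
    "cbind(favorable_count, eligible_count - favorable_count) ~",
    paste(terms, collapse = " + ")
  ))
  fit <- glm(fml, family = quasibinomial("logit"), data = df)
  separated <- any(abs(coef(fit)) > 15, na.rm = TRUE)
  if (separated) {
    warn("possible complete separation: a coefficient estimate is effectively infinite")
  }
  structure(
    list(fit = fit, n_gbm = n_per$n[n_per$class_label == "gbM"],
         n_um = n_per$n[n_per$class_label == "UM"], separated = separated),
    class = "prop_glm"
  )
}

#' @export
print.prop_glm <- function(x, ...) {
  cat("<prop_glm> quasibinomial logit fit:",
      x$n_gbm, "gbM and", x$n_um, "UM genes\n")
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_proportion_glm
#' @param x A `prop_glm` object.
#' @param ... Unused.
#' @method tidy prop_glm
#' @export
tidy.prop_glm <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  est <- unname(sm[, "Estimate"])
  se <- unname(sm[, "Std. Error"])
  tibble(
    term = rownames(sm),
    estimate = est,
    std_error = se,
    statistic = est / se,
    p_value = 2 * pnorm(-abs(est / se))
  )
}

#' @rdname fit_proportion_glm
#' @method glance prop_glm
#' @export
glance.prop_glm <- function(x, ...) {
  tibble(
    n_gbm = x$n_gbm,
    n_um = x$n_um,
    dispersion = summary(x$fit)$dispersion,
    null_deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    df_residual = x$fit$df.residual,
    separated = x$separated
  )
}

#' Class contrast (UM - gbM) from a fitted proportion GLM
#'
#' @param fit A `prop_glm` from [fit_proportion_glm()].
#' @return A one-row tibble: contrast (UM - gbM, logit scale), estimate, SE,
#'   z_ratio = estimate/SE, and the two-sided p-value from the normal
#'   reference.
#' @export
class_contrast <- function(fit) {
  stopifnot(inherits(fit, "prop_glm"))
  td <- tidy(fit) |> filter(.data$term == "classUM")
  if (nrow(td) == 0) abort("fit has no class term")
  tibble(
    contrast = "UM - gbM",
    estimate = td$estimate,
    se = td$std_error,
    z_ratio = td$estimate / td$std_error,
    p_value = 2 * pnorm(-abs(td$estimate / td$std_error))
  )
}

#' Compare gbM vs UM genes on one metric
#'
#' Computes group means (mean of per-gene values, as the headline numbers are
#' reported, plus pooled favorable/eligible proportions when counts are
#' available), a Wilcoxon rank-sum test, and — for proportion metrics with
#' counts — the covariate-adjusted GLM class contrast.
#'
#' @param data A data frame with `class_label` ("gbM"/"UM"; other labels are
#'   dropped), the metric column, and for the GLM path `favorable_count`,
#'   `eligible_count`, `gene_length`, `expression_proxy`.
#' @param metric Name of the metric column (string).
#' @param alternative Wilcoxon alternative, phrased for the gbM group:
#'   "two_sided", "gbm_less" or "gbm_greater".
#' @param glm_adjust Fit the covariate-adjusted GLM (default: TRUE when count
#'   columns are present).
#' @return An object of class `gbmti_comparison`: a list with `summary` (a
#'   one-row tibble) and, when fitted, `fit` (the `prop_glm`).
#' @export
compare_groups <- function(data, metric,
                           alternative = c("two_sided", "gbm_less", "gbm_greater"),
                           glm_adjust = NULL) {
  alternative <- match.arg(alternative)
  data <- as_tibble(data) |>
    filter(.data$class_label %in% c("gbM", "UM"), !is.na(.data[[metric]]))
  a <- data |> filter(.data$class_label == "gbM") |> pull(metric)
  b <- data |> filter(.data$class_label == "UM") |> pull(metric)
  if (length(a) == 0 || length(b) == 0) {
    abort("a class group is empty after filtering")
  }
  wil <- wilcoxon_rank_sum(
    a, b,
    alternative = switch(alternative,
      two_sided = "two_sided", gbm_less = "a_less", gbm_greater = "a_greater"
    )
  )
  has_counts <- all(c(
    "favorable_count", "eligible_count", "gene_length", "expression_proxy"
  ) %in% names(data))
  if (is.null(glm_adjust)) glm_adjust <- has_counts
  if (glm_adjust && !has_counts) {
    abort("glm_adjust requires favorable/eligible counts and covariates")
  }

  summary_row <- tibble(
    metric = metric,
    n_gbm = length(a),
    n_um = length(b),
    mean_gbm = mean(a),
    mean_um = mean(b),
    pooled_gbm = if (has_counts) {
      sum(data$favorable_count[data$class_label == "gbM"]) /
        sum(data$eligible_count[data$class_label == "gbM"])
    } else {
      NA_real_
    },
    pooled_um = if (has_counts) {
      sum(data$favorable_count[data$class_label == "UM"]) /
        sum(data$eligible_count[data$class_label == "UM"])
    } else {
      NA_real_
    },
    wilcoxon_statistic = wil$statistic,
    wilcoxon_p = wil$p_value,
    wilcoxon_alternative = alternative
  )

  fit <- NULL
  if (glm_adjust) {
    fit <- fit_proportion_glm(data)
    cc <- class_contrast(fit)
    summary_row <- summary_row |>
      mutate(
        glm_contrast = cc$estimate,
        glm_se = cc$se,
        glm_z = cc$z_ratio,
        glm_p = cc$p_value
      )
  }

  structure(
    list(summary = summary_row, fit = fit, data = data, metric = metric),
    class = "gbmti_comparison"
  )
}

#' @export
print.gbmti_comparison <- function(x, ...) {
  cat("<gbmti_comparison>", x$metric, "- gbM vs UM\n")
  print(as.data.frame(x$summary))
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `gbmti_comparison`.
#' @param ... Unused.
#' @method tidy gbmti_comparison
#' @export
tidy.gbmti_comparison <- function(x, ...) x$summary

#' Boxplot of a per-gene metric by methylation class
#'
#' Mirrors the conventional presentation: gbM genes in red, UM in turquoise.
#'
#' @param data A data frame with `class_label` and the metric column.
#' @param metric Metric column name (string).
#' @param log_scale Log10-scale the y axis (useful for RPKM / ratios).
#' @return A ggplot object.
#' @export
plot_metric_by_class <- function(data, metric, log_scale = FALSE) {
  df <- as_tibble(data) |>
    filter(.data$class_label %in% c("gbM", "UM"), !is.na(.data[[metric]]))
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$class_label, y = .data[[metric]], fill = .data$class_label)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::scale_fill_manual(values = c(gbM = "#e41a1c", UM = "#40e0d0")) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_classic() +
    ggplot2::theme(legend.position = "none")
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' @method autoplot gbmti_comparison
#' @export
autoplot.gbmti_comparison <- function(object, ...) {
  plot_metric_by_class(object$data, object$metric)
}
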