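#' Group comparison tests
#'
#' Thin, uniform wrapper over the standard tests used for per-nucleus and
#' per-focus measurements: one-way ANOVA with Tukey or Dunnett post-hoc
#' comparisons, unpaired two-tailed Student's t-test, per-stratum multiple
#' t-tests (Welch, unadjusted by default), Mann-Whitney (Wilcoxon rank-sum),
#' and Fisher's exact test on a 2x2 count table.
#'
#' @param data Tibble with a numeric `value` column and a `group` column
#'   (>= 2 groups); for `multiple_ttest` additionally a `stratum` column;
#'   for `fisher_exact` pass a 2x2 count matrix instead.
#' @param design One of `"anova_tukey"`, `"anova_dunnett"`, `"ttest"`,
#'   `"multiple_ttest"`, `"mannwhitney"`, `"fisher_exact"`.
#' @param control Control group name for Dunnett comparisons (default: first
#'   group level).
#' @param p_adjust Adjustment for `multiple_ttest` p-values, a
#'   [stats::p.adjust()] method (default `"none"`).
#' @return A list of class `group_comparison`: `design`, `groups`
#'   (name, n, mean, sd, median), `test` (name), `statistic`, `p_value`,
#'   `posthoc` (tibble of pairs with adjusted p-values, when applicable).
#' @examples
#' d <- tibble::tibble(
#'   value = c(rnorm(10), rnorm(10, 2)),
#'   group = rep(c("a", "b"), each = 10)
#' )
#' group_compare(d, "ttest")$p_value
#' @export
group_compare <- function(data,
                          design = c(
                            "anova_tukey", "anova_dunnett", "ttest",
                            "multiple_ttest", "mannwhitney", "fisher_exact"
                          ),
                          control = NULL, p_adjust = "none") {
  design <- match.arg(design)

  if (design == "fisher_exact") {
    m <- as.matrix(data)
    stopifnot(all(dim(m) == c(2L, 2L)), all(m >= 0), all(m == floor(m)))
    ft <- stats::fisher.test(m)
    return(new_group_comparison(
      design,
      groups = tibble::tibble(
        name = c("row1", "row2"), n = rowSums(m),
        mean = NA_real_, sd = NA_real_, median = NA_real_
      ),
      test = "Fisher's exact test", statistic = unname(ft$estimate),
      p_value = ft$p.value, posthoc = NULL
    ))
  }

  stopifnot(all(c("value", "group") %in% names(data)))
  data$group <- factor(data$group)
  g <- levels(data$group)
  stopifnot(length(g) >= 2L)
  groups <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(data), name = .data$group),
    n = dplyr::n(), mean = mean(.data$value), sd = stats::sd(.data$value),
    median = stats::median(.data$value), .groups = "drop"
  )
  if (design %in% c("anova_tukey", "anova_dunnett", "ttest") &&
    any(groups$n < 2L)) {
    stop("every group needs n >= 2 for variance-based tests", call. = FALSE)
  }

  if (design == "ttest") {
    stopifnot(length(g) == 2L)
    tt <- stats::t.test(value ~ group, data = data, var.equal = TRUE)
    return(new_group_comparison(design, groups, "Student's t-test (unpaired, two-tailed)",
      statistic = unname(tt$statistic), p_value = tt$p.value, posthoc = NULL
    ))
  }
  if (design == "mannwhitney") {
    stopifnot(length(g) == 2L)
    wt <- stats::wilcox.test(value ~ group, data = data, exact = FALSE)
    return(new_group_comparison(design, groups, "Mann-Whitney test",
      statistic = unname(wt$statistic), p_value = wt$p.value, posthoc = NULL
    ))
  }
  if (design == "multiple_ttest") {
    stopifnot("stratum" %in% names(data), length(g) == 2L)
    strata <- split(tibble::as_tibble(data), data$stratum)
    ph <- dplyr::bind_rows(lapply(names(strata), function(s) {
      tt <- stats::t.test(value ~ group, data = strata[[s]]) # Welch
      tibble::tibble(
        comparison = s, estimate = unname(diff(rev(tt$estimate))),
        statistic = unname(tt$statistic), p_value = tt$p.value
      )
    }))
    ph$p_adjusted <- stats::p.adjust(ph$p_value, method = p_adjust)
    return(new_group_comparison(design, groups, "multiple t-tests (Welch)",
      statistic = NA_real_, p_value = min(ph$p_adjusted), posthoc = ph
    ))
  }

  fit <- stats::aov(value ~ group, data = data)
  an <- summary(fit)[[1L]]
  f_stat <- an[["F value"]][1L]
  p_global <- an[["Pr(>F)"]][1L]
  if (design == "anova_tukey") {
    tk <- stats::TukeyHSD(fit)$group
    ph <- tibble::tibble(
      comparison = rownames(tk), estimate = tk[, "diff"],
      p_adjusted = tk[, "p adj"]
    )
    test <- "one-way ANOVA (Tukey's multiple comparisons test)"
  } else {
    if (!is.null(control)) {
      data$group <- stats::relevel(data$group, ref = control)
      fit <- stats::aov(value ~ group, data = data)
    }
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    sm <- summary(gl)
    ph <- tibble::tibble(
      comparison = names(sm$test$coefficients),
      estimate = unname(sm$test$coefficients),
      p_adjusted = unname(sm$test$pvalues)
    )
    test <- "one-way ANOVA (Dunnett's multiple comparisons test)"
  }
  new_group_comparison(design, groups, test,
    statistic = f_stat,
    p_value = p_global, posthoc = ph
  )
}

new_group_comparison <- function(design, groups, test, statistic, p_value,
                                 posthoc) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(
    list(
      design = design, groups = groups, test = test,
      statistic = statistic, p_value = p_value, posthoc = posthoc
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$test, "\n", sep = "")
  print(x$groups)
  cat(sprintf("statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
  if (!is.null(x$posthoc)) {
    cat("post-hoc:\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' Fold-change summary of two group means
#'
#' The ratio of two group statistics, reported both raw and rounded half-up
#' to one decimal (the convention used for in-text fold statements such as
#' "2.3-fold fewer foci").
#'
#' @param numerator,denominator Group means (denominator > 0).
#' @return Tibble `fold_raw`, `fold_rounded`.
#' @examples
#' fold_summary(8.88, 3.89) # 2.28 -> 2.3
#' @export
fold_summary <- function(numerator, denominator) {
  stopifnot(is.finite(numerator), is.finite(denominator))
  if (denominator == 0) stop("denominator must be non-zero", call. = FALSE)
  raw <- numerator / denominator
  tibble::tibble(fold_raw = raw, fold_rounded = round_half_up(raw, 1L))
}

# round half away from zero (printed-fold convention), unlike base round()'s
# banker rounding
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
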