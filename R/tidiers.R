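#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a group comparison
#'
#' `tidy()` returns the post-hoc pairs (or the single test when no post-hoc
#' step exists) as one row per comparison; `glance()` returns a one-row
#' summary of the omnibus test.
#'
#' @param x A [group_compare()] result.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) {
  if (!is.null(x$posthoc)) {
    out <- x$posthoc
    out$test <- x$test
    return(out)
  }
  tibble::tibble(
    comparison = paste(x$groups$name, collapse = " vs "),
    statistic = x$statistic, p_value = x$p_value, test = x$test
  )
}

#' @rdname tidy.group_comparison
#' @exportS3Method generics::glance
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    test = x$test, statistic = x$statistic, p_value = x$p_value,
    n_groups = nrow(x$groups), n_total = sum(x$groups$n)
  )
}

#' Tidy a chromatome enrichment result
#'
#' `tidy()` pivots the per-condition columns into long format (one row per
#' protein x condition); `glance()` gives one row with the number of
#' proteins, the proteins selected per condition, and the size of the
#' `Luc&2Cneg` candidate region.
#'
#' @param x A [chromatome_enrichment()] result.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.chromatome_enrichment <- function(x, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(x),
    cols = -c("protein_id", "venn_region"),
    names_to = c(".value", "condition"),
    names_pattern = "(log2fc|avg_fold|selected)_(.*)"
  )
  long
}

#' @rdname tidy.chromatome_enrichment
#' @exportS3Method generics::glance
glance.chromatome_enrichment <- function(x, ...) {
  venn <- select_and_venn(x)
  tibble::tibble(
    n_proteins = nrow(x),
    n_selected_Luc = sum(x$selected_Luc),
    n_selected_2Cneg = sum(x$selected_2Cneg),
    n_selected_2Cpos = sum(x$selected_2Cpos),
    n_luc_2cneg_not_2cpos = venn$n[venn$venn_region == "Luc&2Cneg"]
  )
}

#' Tidy a replicate QC report
#'
#' One row per replicate pair with the Pearson correlation.
#'
#' @param x A [replicate_qc()] result.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.replicate_qc <- function(x, ...) x$correlations
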