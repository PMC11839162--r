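#' Per-protein condition means
#'
#' Aggregates PSM counts over replicates (mean by default, median optional)
#' for every protein x condition; proteins absent from a condition get a 0
#' mean so downstream ratios stay defined through the pseudocount.
#'
#' @param table A chromatome tibble (see [chromatome_table()]).
#' @param aggregate `"mean"` or `"median"` over replicates.
#' @return Wide tibble: `protein_id` plus one column per condition present.
#' @export
condition_means <- function(table, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  f <- if (aggregate == "mean") mean else stats::median
  long <- dplyr::summarise(
    dplyr::group_by(table, .data$protein_id, .data$condition),
    psm = f(.data$psm),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(long,
    names_from = "condition", values_from = "psm",
    values_fill = 0
  )
  wide
}

#' Log2 fold change of a capture condition over the no-capture control
#'
#' `log2((mean PSM in condition + pseudocount) / (mean PSM in minusEdU +
#' pseudocount))`; replicate means are taken first.
#'
#' @param table Chromatome tibble.
#' @param condition One of `Luc`, `2Cneg`, `2Cpos`.
#' @param pseudocount Added to both means (default 1).
#' @param control Control condition (default `minusEdU`).
#' @param aggregate Replicate aggregation, `"mean"` or `"median"`.
#' @return Tibble `protein_id`, `log2fc`.
#' @examples
#' tbl <- chromatome_table(data.frame(
#'   protein_id = "P1", condition = c("Luc", "minusEdU"),
#'   replicate = 1L, psm = c(8, 2)
#' ))
#' log2fc_to_control(tbl, "Luc")$log2fc # log2(9/3)
#' @export
log2fc_to_control <- function(table, condition, pseudocount = 1,
                              control = "minusEdU",
                              aggregate = "mean") {
  cm <- condition_means(table, aggregate)
  for (cnd in c(condition, control)) {
    if (!cnd %in% names(cm)) {
      stop("condition '", cnd, "' absent from the table", call. = FALSE)
    }
  }
  tibble::tibble(
    protein_id = cm$protein_id,
    log2fc = log2((cm[[condition]] + pseudocount) / (cm[[control]] + pseudocount))
  )
}

#' Pairwise linear enrichment between two conditions
#'
#' `(mean_A + pseudocount) / (mean_B + pseudocount)` per protein.
#'
#' @inheritParams log2fc_to_control
#' @param cond_a,cond_b Conditions to compare (A over B).
#' @return Tibble `protein_id`, `fold`.
#' @export
pairwise_enrichment <- function(table, cond_a, cond_b, pseudocount = 1,
                                aggregate = "mean") {
  cm <- condition_means(table, aggregate)
  for (cnd in c(cond_a, cond_b)) {
    if (!cnd %in% names(cm)) {
      stop("condition '", cnd, "' absent from the table", call. = FALSE)
    }
  }
  tibble::tibble(
    protein_id = cm$protein_id,
    fold = (cm[[cond_a]] + pseudocount) / (cm[[cond_b]] + pseudocount)
  )
}

#' Average enrichment of one condition against the others
#'
#' Summarizes the pairwise enrichments of `target` versus each condition in
#' `others` into a single fold per protein. The default is the arithmetic
#' mean of the linear pairwise folds: a protein strongly enriched against
#' one comparison condition remains above an FC cutoff even when it is flat
#' against another, which is the behaviour required of a
#' shared-between-two-conditions selection. A geometric-mean mode
#' (arithmetic in log space, scale-consistent for ratios) is provided for
#' comparison; the mode used is recorded in the `mode` attribute.
#'
#' @inheritParams log2fc_to_control
#' @param target Target condition.
#' @param others Character vector of comparison conditions (>= 1).
#' @param mode `"arithmetic"` or `"geometric"`.
#' @return Tibble `protein_id`, `avg_fold`.
#' @export
average_enrichment <- function(table, target, others, pseudocount = 1,
                               mode = c("arithmetic", "geometric"),
                               aggregate = "mean") {
  mode <- match.arg(mode)
  stopifnot(length(others) >= 1L)
  folds <- lapply(others, function(o) {
    pairwise_enrichment(table, target, o, pseudocount, aggregate)$fold
  })
  fm <- do.call(cbind, folds)
  avg <- if (mode == "geometric") {
    exp(rowMeans(log(fm)))
  } else {
    rowMeans(fm)
  }
  out <- tibble::tibble(
    protein_id = condition_means(table, aggregate)$protein_id,
    avg_fold = avg
  )
  attr(out, "mode") <- mode
  out
}

#' Full chromatome enrichment analysis
#'
#' For each capture condition (`Luc`, `2Cneg`, `2Cpos`) computes the log2
#' fold change to the no-capture control, the average enrichment against the
#' other two capture conditions, the FC-cutoff selection flag, and the Venn
#' region membership implied by the three flags.
#'
#' @param table Chromatome tibble with all four conditions.
#' @param config An [analysis_config()] (`fc_cutoff`, `pseudocount`).
#' @param mode Average-enrichment mode, see [average_enrichment()].
#' @param aggregate Replicate aggregation.
#' @return A tibble of class `chromatome_enrichment`: `protein_id`,
#'   `log2fc_<cond>`, `avg_fold_<cond>`, `selected_<cond>`, `venn_region`
#'   (e.g. `"Luc&2Cneg"`, `"none"`).
#' @export
chromatome_enrichment <- function(table, config = analysis_config(),
                                  mode = "arithmetic", aggregate = "mean") {
  mode <- match.arg(mode, c("arithmetic", "geometric"))
  validate_config(config)
  conds <- c("Luc", "2Cneg", "2Cpos")
  pc <- config$pseudocount
  cm <- condition_means(table, aggregate)
  for (cnd in c(conds, "minusEdU")) {
    if (!cnd %in% names(cm)) {
      stop("condition '", cnd, "' absent from the table", call. = FALSE)
    }
  }
  out <- tibble::tibble(protein_id = cm$protein_id)
  for (cnd in conds) {
    out[[paste0("log2fc_", cnd)]] <-
      log2((cm[[cnd]] + pc) / (cm[["minusEdU"]] + pc))
    pair <- vapply(setdiff(conds, cnd), function(o) {
      (cm[[cnd]] + pc) / (cm[[o]] + pc)
    }, numeric(nrow(cm)))
    out[[paste0("avg_fold_", cnd)]] <- if (mode == "geometric") {
      exp(rowMeans(log(pair)))
    } else {
      rowMeans(pair)
    }
    out[[paste0("selected_", cnd)]] <-
      out[[paste0("avg_fold_", cnd)]] >= config$fc_cutoff
  }
  out$venn_region <- venn_label(
    out$selected_Luc, out$selected_2Cneg, out$selected_2Cpos
  )
  class(out) <- c("chromatome_enrichment", class(out))
  out
}

venn_label <- function(luc, neg, pos) {
  lab <- character(length(luc))
  for (i in seq_along(luc)) {
    members <- c("Luc", "2Cneg", "2Cpos")[c(luc[i], neg[i], pos[i])]
    lab[i] <- if (length(members) == 0L) "none" else paste(members, collapse = "&")
  }
  factor(lab, levels = c(
    "none", "Luc", "2Cneg", "2Cpos",
    "Luc&2Cneg", "Luc&2Cpos", "2Cneg&2Cpos", "Luc&2Cneg&2Cpos"
  ))
}

#' Venn region decomposition of selected proteins
#'
#' Counts proteins in each of the 7 Venn regions of the three capture
#' conditions (plus the unselected remainder). The region
#' `"Luc&2Cneg"` — enriched in Luc and 2C-negative but not 2C-positive — is
#' the candidate set for chromocenter-maintenance factors.
#'
#' @param enrichment A [chromatome_enrichment()] result, or a tibble with
#'   `selected_Luc`, `selected_2Cneg`, `selected_2Cpos`.
#' @return Tibble `venn_region`, `n` covering all 8 labels; counts sum to the
#'   protein total.
#' @export
select_and_venn <- function(enrichment) {
  stopifnot(all(c("selected_Luc", "selected_2Cneg", "selected_2Cpos")
  %in% names(enrichment)))
  lab <- venn_label(
    enrichment$selected_Luc, enrichment$selected_2Cneg,
    enrichment$selected_2Cpos
  )
  out <- dplyr::count(tibble::tibble(venn_region = lab), .data$venn_region,
    .drop = FALSE
  )
  names(out)[2L] <- "n"
  out
}

#' Rank proteins by log2 fold change
#'
#' Descending by `log2fc_<condition>`, ties broken lexicographically by
#' `protein_id`; used e.g. for the top-50 chromatin-bound proteins of a
#' condition.
#'
#' @param enrichment A [chromatome_enrichment()] result.
#' @param condition Condition whose log2 fold change orders the list.
#' @param top_n Number of proteins to return; when larger than the table a
#'   warning is issued and the full ranking returned.
#' @return Tibble `rank`, `protein_id`, `log2fc`.
#' @export
rank_proteins <- function(enrichment, condition = "Luc", top_n = 50L) {
  col <- paste0("log2fc_", condition)
  stopifnot(col %in% names(enrichment))
  ord <- order(-enrichment[[col]], enrichment$protein_id)
  if (top_n > length(ord)) {
    warning("top_n exceeds the number of proteins; returning all", call. = FALSE)
    top_n <- length(ord)
  }
  idx <- ord[seq_len(top_n)]
  tibble::tibble(
    rank = seq_len(top_n),
    protein_id = enrichment$protein_id[idx],
    log2fc = enrichment[[col]][idx]
  )
}

#' Replicate quality control
#'
#' Pearson correlation of per-protein PSM counts between every pair of
#' replicates (across conditions), plus a flag for replicates whose total
#' PSM count falls below a configurable fraction of their condition's median
#' total — the signature of a failed capture that warrants exclusion.
#'
#' @param table Chromatome tibble.
#' @param low_total_fraction Flag replicates with total PSM below this
#'   fraction of the condition median (default 0.5).
#' @return A list of class `replicate_qc`: `correlations` (tibble
#'   `rep_a`, `rep_b`, `pearson_r`, `note`), `cor_matrix` (named matrix,
#'   unit diagonal), `flagged` (tibble `condition`, `replicate`,
#'   `total_psm`, `condition_median`, `reason`).
#' @export
replicate_qc <- function(table, low_total_fraction = 0.5) {
  key <- paste(table$condition, table$replicate, sep = "_r")
  reps <- unique(key)
  if (length(reps) < 2L) stop("need >= 2 replicates overall", call. = FALSE)
  wide <- tidyr::pivot_wider(
    tibble::tibble(
      protein_id = table$protein_id, rep = key,
      psm = as.numeric(table$psm)
    ),
    names_from = "rep", values_from = "psm", values_fill = 0
  )
  m <- as.matrix(wide[reps])
  cm <- matrix(NA_real_, length(reps), length(reps),
    dimnames = list(reps, reps)
  )
  pairs <- list()
  for (i in seq_along(reps)) {
    for (j in seq_along(reps)) {
      if (i == j) {
        cm[i, j] <- 1
        next
      }
      if (stats::sd(m[, i]) == 0 || stats::sd(m[, j]) == 0) {
        cm[i, j] <- NA_real_
      } else {
        cm[i, j] <- stats::cor(m[, i], m[, j])
      }
      if (j > i) {
        pairs[[length(pairs) + 1L]] <- tibble::tibble(
          rep_a = reps[i], rep_b = reps[j], pearson_r = cm[i, j],
          note = if (is.na(cm[i, j])) "zero-variance replicate" else NA_character_
        )
      }
    }
  }
  totals <- dplyr::summarise(
    dplyr::group_by(table, .data$condition, .data$replicate),
    total_psm = sum(.data$psm),
    .groups = "drop"
  )
  totals <- dplyr::mutate(
    dplyr::group_by(totals, .data$condition),
    condition_median = stats::median(.data$total_psm)
  )
  totals <- dplyr::ungroup(totals)
  flagged <- totals[totals$total_psm < low_total_fraction * totals$condition_median, ]
  flagged$reason <- sprintf(
    "total PSM %.0f below %.0f%% of condition median %.0f",
    flagged$total_psm, 100 * low_total_fraction, flagged$condition_median
  )
  structure(
    list(
      correlations = dplyr::bind_rows(pairs),
      cor_matrix = cm,
      flagged = flagged
    ),
    class = "replicate_qc"
  )
}

#' @export
print.replicate_qc <- function(x, ...) {
  cat("<replicate_qc> ", nrow(x$cor_matrix), " replicates\n", sep = "")
  print(round(x$cor_matrix, 3))
  if (nrow(x$flagged) > 0) {
    cat("flagged:\n")
    print(x$flagged)
  } else {
    cat("no replicates flagged\n")
  }
  invisible(x)
}
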