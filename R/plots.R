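#' Voronoi density map
#'
#' Renders the tessellation of one nucleus with the standard density colour
#' code: a yellow-to-blue gradient in log10 density between the clamping
#' bounds, and the largest polygons blacked out.
#'
#' @param tess A [voronoi_tessellate()] result (rendered with
#'   [render_density()] first if the `category` column is absent).
#' @param nucleus One nucleus id to draw (default: the first).
#' @param config An [analysis_config()], used when rendering is still needed.
#' @return A ggplot object.
#' @export
plot_density_map <- function(tess, nucleus = NULL, config = analysis_config()) {
  stopifnot(inherits(tess, "voronoi_tessellation"))
  if (!"category" %in% names(tess)) tess <- render_density(tess, config)
  nucleus <- nucleus %||% tess$nucleus_id[1L]
  sub <- tess[tess$nucleus_id == nucleus, ]
  df <- purrr::map2_dfr(sub$polygon, seq_len(nrow(sub)), function(p, i) {
    tibble::tibble(
      x = p[, 1L], y = p[, 2L], cell = i,
      fill_t = rep(sub$grade_t[i], nrow(p)),
      category = rep(as.character(sub$category[i]), nrow(p))
    )
  })
  df$fill_t[df$category == "black"] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, group = .data$cell)) +
    ggplot2::geom_polygon(ggplot2::aes(fill = .data$fill_t),
      colour = NA
    ) +
    ggplot2::scale_fill_gradient(
      low = "#2166ac", high = "#ffd700",
      na.value = "black", limits = c(0, 1), name = "density (log10 scale)"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (nm)", y = "y (nm)",
      title = paste("Voronoi density map,", nucleus)
    ) +
    ggplot2::theme_minimal()
}

#' Biaxial compaction plot
#'
#' Mean Voronoi density against GFP intensity score, one dot per nucleus,
#' coloured by 2C class — the plot used to read decompaction off the
#' reporter axis.
#'
#' @param records A [compaction_table()] result.
#' @param config An [analysis_config()] (threshold drawn as a dashed line).
#' @return A ggplot object.
#' @export
plot_compaction <- function(records, config = analysis_config()) {
  stopifnot(all(c("mean_density_nm2inv", "gfp_score", "two_c_class")
  %in% names(records)))
  ggplot2::ggplot(records, ggplot2::aes(
    x = .data$gfp_score, y = .data$mean_density_nm2inv,
    colour = .data$two_c_class
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(
      xintercept = config$gfp_threshold,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_colour_manual(
      values = c(`2Cneg` = "black", `2Cpos` = "#2ca25f"), name = NULL
    ) +
    ggplot2::labs(
      x = "GFP intensity score",
      y = expression("mean Voronoi density (nm"^-2 * ")")
    ) +
    ggplot2::theme_classic()
}

#' Ranked enrichment plot
#'
#' Top proteins of a condition by log2 fold change to the no-capture
#' control.
#'
#' @param enrichment A [chromatome_enrichment()] result.
#' @param condition Condition to rank.
#' @param top_n Number of proteins shown.
#' @return A ggplot object.
#' @export
plot_enrichment_rank <- function(enrichment, condition = "Luc", top_n = 50L) {
  rk <- rank_proteins(enrichment, condition, top_n)
  ggplot2::ggplot(rk, ggplot2::aes(
    x = .data$rank, y = .data$log2fc
  )) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = "rank", y = expression(log[2] ~ "FC to −EdU"),
      title = paste("Top", top_n, "chromatin-bound proteins,", condition)
    ) +
    ggplot2::theme_classic()
}

#' @rdname plot_density_map
#' @param object,... Passed through to the underlying plot function.
#' @exportS3Method ggplot2::autoplot
autoplot.voronoi_tessellation <- function(object, ...) {
  plot_density_map(object, ...)
}

#' @rdname plot_enrichment_rank
#' @param object,... Passed through.
#' @exportS3Method ggplot2::autoplot
autoplot.chromatome_enrichment <- function(object, ...) {
  plot_enrichment_rank(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
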