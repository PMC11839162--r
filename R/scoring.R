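#' Mean ADU intensity inside a nucleus mask
#'
#' Sums the fluorescence intensity (ADU counts) of all pixels inside the mask
#' and divides by the number of mask pixels.
#'
#' @param image A 2D numeric matrix (one channel), or an [image_stack()] with
#'   a single channel.
#' @param mask Logical matrix of the same shape, `TRUE` inside the nucleus.
#' @return Mean intensity (scalar).
#' @export
mean_adu <- function(image, mask) {
  img <- as_channel_matrix(image)
  stopifnot(is.logical(mask), all(dim(mask) == dim(img)))
  if (!any(mask)) stop("empty nucleus mask", call. = FALSE)
  sum(img[mask]) / sum(mask)
}

#' Measure mean ADU for every nucleus in a labelled field
#'
#' @param image A 2D matrix or single-channel [image_stack()].
#' @param labels Integer matrix; nucleus i labelled i, background 0.
#' @return Tibble with `nucleus_id` (`"n<i>"`) and `mean_adu`.
#' @export
measure_nuclei <- function(image, labels) {
  img <- as_channel_matrix(image)
  stopifnot(all(dim(labels) == dim(img)))
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) stop("no labelled nuclei in the field", call. = FALSE)
  tibble::tibble(
    nucleus_id = sprintf("n%d", ids),
    mean_adu = vapply(ids, function(i) mean(img[labels == i]), numeric(1))
  )
}

#' GFP intensity score by cohort min-max normalization
#'
#' Maps the distribution of per-nucleus mean GFP intensities of one imaging
#' batch onto \[0, 1\]: the dimmest nucleus scores 0, the brightest 1
#' (`(v - min) / (max - min)`). Scores are therefore comparable only within
#' a batch. A degenerate all-equal cohort (or a single nucleus) scores 0
#' everywhere.
#'
#' @param nuclei Tibble with a `mean_adu` column (e.g. from
#'   [measure_nuclei()]).
#' @return `nuclei` with a `gfp_score` column added.
#' @examples
#' normalize_scores(tibble::tibble(mean_adu = c(10, 20, 30)))$gfp_score
#' @export
normalize_scores <- function(nuclei) {
  stopifnot("mean_adu" %in% names(nuclei), nrow(nuclei) >= 1L)
  v <- nuclei$mean_adu
  stopifnot(all(is.finite(v)))
  rng <- range(v)
  nuclei$gfp_score <- if (rng[2L] > rng[1L]) {
    (v - rng[1L]) / (rng[2L] - rng[1L])
  } else {
    rep(0, length(v))
  }
  nuclei
}

#' Classify nuclei as 2C-positive or 2C-negative
#'
#' A nucleus is 2C-positive when its GFP intensity score strictly exceeds the
#' configured threshold (default 0.2); a score exactly at the threshold is
#' 2C-negative.
#'
#' @param gfp_score Numeric vector of scores in \[0, 1\].
#' @param config An [analysis_config()] (uses `gfp_threshold`).
#' @return Factor with levels `2Cneg`, `2Cpos`.
#' @export
classify_2c <- function(gfp_score, config = analysis_config()) {
  stopifnot(all(gfp_score >= 0 & gfp_score <= 1, na.rm = TRUE))
  factor(
    ifelse(gfp_score > config$gfp_threshold, "2Cpos", "2Cneg"),
    levels = c("2Cneg", "2Cpos")
  )
}

#' Score a whole GFP field
#'
#' Convenience wrapper: [measure_nuclei()], [normalize_scores()] and
#' [classify_2c()] in one call.
#'
#' @inheritParams measure_nuclei
#' @inheritParams classify_2c
#' @param batch_id Identifier stamped on the rows (scores are batch-relative).
#' @return Tibble `nucleus_id`, `mean_adu`, `gfp_score`, `two_c_class`,
#'   `batch_id`.
#' @export
score_gfp_field <- function(image, labels, config = analysis_config(),
                            batch_id = "batch1") {
  out <- normalize_scores(measure_nuclei(image, labels))
  out$two_c_class <- classify_2c(out$gfp_score, config)
  out$batch_id <- batch_id
  out
}

as_channel_matrix <- function(image) {
  if (inherits(image, "image_stack")) {
    stopifnot(length(image$channels) == 1L)
    image <- image$channels[[1L]]
  }
  stopifnot(is.numeric(image), length(dim(image)) == 2L)
  image
}
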