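#' Manders colocalization coefficients
#'
#' Computes both Manders overlap coefficients between two co-registered
#' channels within a nucleus mask: `m1` is the fraction of channel-1
#' intensity located in pixels where channel 2 exceeds its threshold,
#' `m2` the converse. Manders coefficients are used because they are
#' independent of the intensity of the overlapping pixels — scaling a
#' channel by a positive constant leaves its coefficient unchanged.
#'
#' With `auto_threshold = TRUE` the thresholds are set per channel by Otsu's
#' method on the masked pixels; otherwise they default to 0 (all strictly
#' positive signal counts). When a channel has zero total intensity inside
#' the mask its coefficient is undefined and returned as `NA` with the
#' reason in the `note` column.
#'
#' @param ch1,ch2 2D numeric matrices of identical shape.
#' @param mask Logical mask (default: whole field).
#' @param t1,t2 Channel thresholds (pixels strictly above are "positive").
#' @param auto_threshold Use per-channel Otsu within the mask.
#' @param nucleus_id Id stamped on the result row.
#' @return One-row tibble: `nucleus_id`, `m1`, `m2`, `t1`, `t2`, `note`.
#' @examples
#' a <- matrix(c(5, 5, 0, 0, 0, 0, 0, 0, 0), 3, 3)
#' b <- matrix(c(9, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3)
#' manders(a, b)$m1 # 0.5
#' @export
manders <- function(ch1, ch2, mask = NULL, t1 = 0, t2 = 0,
                    auto_threshold = FALSE, nucleus_id = "n1") {
  stopifnot(
    is.numeric(ch1), is.numeric(ch2),
    length(dim(ch1)) == 2L, all(dim(ch1) == dim(ch2)),
    t1 >= 0, t2 >= 0
  )
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ch1), ncol(ch1))
  stopifnot(is.logical(mask), all(dim(mask) == dim(ch1)), any(mask))
  if (auto_threshold) {
    t1 <- otsu_threshold(ch1[mask])
    t2 <- otsu_threshold(ch2[mask])
  }
  v1 <- ch1[mask]
  v2 <- ch2[mask]
  s1 <- sum(v1)
  s2 <- sum(v2)
  m1 <- if (s1 > 0) sum(v1[v2 > t2]) / s1 else NA_real_
  m2 <- if (s2 > 0) sum(v2[v1 > t1]) / s2 else NA_real_
  note <- if (s1 <= 0 && s2 <= 0) {
    "both channels empty in mask"
  } else if (s1 <= 0) {
    "channel 1 empty in mask"
  } else if (s2 <= 0) {
    "channel 2 empty in mask"
  } else {
    NA_character_
  }
  tibble::tibble(
    nucleus_id = nucleus_id, m1 = m1, m2 = m2,
    t1 = t1, t2 = t2, note = note
  )
}
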