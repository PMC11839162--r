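#' Read a localization table
#'
#' Localization tables hold one row per single-molecule localization with x-y
#' positions in nanometres, grouped per nucleus. Two dialects are supported:
#' `generic_csv` expects columns `x_nm` and `y_nm` already in nm;
#' `xy_pixels_csv` expects `x_px` and `y_px` in camera pixels, which are
#' converted to nm with `config$pixel_size_nm` (default 160 nm/px, the
#' effective pixel size of a 100x/16-um-pixel STORM setup). A `nucleus_id`
#' column is carried through if present and set to `"n1"` otherwise; optional
#' `frame` and `photons` columns are preserved.
#'
#' @param path CSV file path.
#' @param dialect `"generic_csv"` (nm coordinates) or `"xy_pixels_csv"`
#'   (pixel coordinates, converted on read).
#' @param config An [analysis_config()]; only `pixel_size_nm` is used.
#' @return A tibble with columns `nucleus_id`, `x_nm`, `y_nm` (plus any of
#'   `frame`, `photons`), in file row order.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write.csv(data.frame(x_nm = c(1, 2), y_nm = c(3, 4)), p, row.names = FALSE)
#' read_localizations(p)
#' @export
read_localizations <- function(path, dialect = c("generic_csv", "xy_pixels_csv"),
                               config = analysis_config()) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- switch(dialect,
    generic_csv = c("x_nm", "y_nm"),
    xy_pixels_csv = c("x_px", "y_px")
  )
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("localization file ", path, " lacks required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  for (cl in needed) {
    v <- raw[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0) {
        stop("non-numeric coordinate in column '", cl, "' at row ", bad[1L],
          call. = FALSE
        )
      }
      raw[[cl]] <- num
    }
  }
  if (dialect == "xy_pixels_csv") {
    raw$x_nm <- raw$x_px * config$pixel_size_nm
    raw$y_nm <- raw$y_px * config$pixel_size_nm
  }
  if (any(!is.finite(raw$x_nm)) || any(!is.finite(raw$y_nm))) {
    stop("non-finite coordinate at row ",
      which(!is.finite(raw$x_nm) | !is.finite(raw$y_nm))[1L],
      call. = FALSE
    )
  }
  if (is.null(raw$nucleus_id)) raw$nucleus_id <- "n1"
  keep <- intersect(
    c("nucleus_id", "x_nm", "y_nm", "frame", "photons"),
    names(raw)
  )
  tibble::as_tibble(raw[keep])
}

#' @rdname read_localizations
#' @param locs A localization tibble as returned by `read_localizations()`.
#' @export
write_localizations <- function(locs, path) {
  stopifnot(all(c("nucleus_id", "x_nm", "y_nm") %in% names(locs)))
  utils::write.csv(locs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Image stacks
#'
#' A minimal in-memory container for multichannel fluorescence images:
#' a named list of numeric arrays, one per channel, each either 2D `[y, x]`
#' or 3D `[y, x, z]`, all of identical shape, plus the physical pixel size in
#' micrometres. Pixels are stored as plain base-R arrays in row-major (y, x)
#' order with 1-based indices.
#'
#' @param channels Named list of 2D/3D numeric arrays of identical shape.
#' @param pixel_size_um Pixel size, um/px (> 0).
#' @return An `image_stack` object.
#' @export
image_stack <- function(channels, pixel_size_um) {
  stopifnot(
    is.list(channels), length(channels) >= 1L,
    !is.null(names(channels)), all(nzchar(names(channels))),
    is.numeric(pixel_size_um), pixel_size_um > 0
  )
  dims <- lapply(channels, function(ch) dim(ch) %||% length(ch))
  if (length(unique(lapply(dims, identity))) != 1L) {
    stop("all channels must have identical shapes", call. = FALSE)
  }
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1)))) {
    stop("pixel intensities must be non-negative", call. = FALSE)
  }
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(
    "<image_stack> ", length(x$channels), " channel(s) [",
    paste(d, collapse = " x "), "], ", x$pixel_size_um, " um/px\n",
    sep = ""
  )
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Read and write TIFF image stacks
#'
#' Integer pixel data round-trip losslessly (8 or 16 bit). Multi-channel
#' stacks are written one file per channel (`<stem>_<channel>.tif`); the
#' z-dimension maps to TIFF directories. Pixel size is not stored in the TIFF
#' and must be supplied on read.
#'
#' @param path TIFF path (single channel) or vector of paths matching
#'   `channel` names.
#' @param channel Channel name(s) for the file(s).
#' @param pixel_size_um Pixel size to attach, um/px.
#' @param stack An `image_stack` (for writing).
#' @param bits_per_sample 8 or 16.
#' @return `read_image()` returns an `image_stack`; `write_image()` the
#'   path(s), invisibly.
#' @export
read_image <- function(path, channel = "ch1", pixel_size_um = 0.1) {
  stopifnot(length(path) == length(channel), all(file.exists(path)))
  chs <- lapply(path, function(p) {
    sl <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    arr <- if (length(sl) == 1L) {
      sl[[1L]]
    } else {
      array(unlist(sl), dim = c(dim(sl[[1L]]), length(sl)))
    }
    storage.mode(arr) <- "double"
    arr
  })
  image_stack(stats::setNames(chs, channel), pixel_size_um)
}

#' @rdname read_image
#' @export
write_image <- function(stack, path, bits_per_sample = 16L) {
  stopifnot(inherits(stack, "image_stack"))
  if (!bits_per_sample %in% c(8L, 16L)) {
    stop("unsupported bit depth: ", bits_per_sample, " (use 8 or 16)",
      call. = FALSE
    )
  }
  if (length(path) == 1L && length(stack$channels) > 1L) {
    stem <- sub("\\.tiff?$", "", path)
    path <- sprintf("%s_%s.tif", stem, names(stack$channels))
  }
  stopifnot(length(path) == length(stack$channels))
  maxv <- 2^bits_per_sample - 1
  for (i in seq_along(path)) {
    ch <- stack$channels[[i]]
    if (any(ch > maxv) || any(ch != floor(ch))) {
      stop("channel '", names(stack$channels)[i],
        "' is not integer-valued in [0, ", maxv, "]; rescale before writing",
        call. = FALSE
      )
    }
    sl <- if (length(dim(ch)) == 3L) {
      lapply(seq_len(dim(ch)[3L]), function(k) ch[, , k] / maxv)
    } else {
      list(ch / maxv)
    }
    tiff::writeTIFF(sl, path[i], bits.per.sample = bits_per_sample)
  }
  invisible(path)
}

#' Read a chromatome PSM table
#'
#' Long-format CSV with columns `protein_id`, `condition`, `replicate`, `psm`
#' (peptide spectrum match counts). Conditions are restricted to the iPOTD
#' design: `minusEdU` (no-capture background control), `Luc` (luciferase
#' control population), `2Cneg` and `2Cpos` (MERVL-reporter-negative/-positive
#' sorted populations).
#'
#' @param path CSV path.
#' @return A validated tibble; see [chromatome_table()].
#' @export
read_chromatome <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  chromatome_table(raw)
}

#' @rdname read_chromatome
#' @param table A chromatome tibble.
#' @export
write_chromatome <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a chromatome PSM table
#'
#' @param x A data frame with columns `protein_id`, `condition`, `replicate`,
#'   `psm`.
#' @return A tibble with `condition` as a factor over the four design levels.
#' @export
chromatome_table <- function(x) {
  needed <- c("protein_id", "condition", "replicate", "psm")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("chromatome table lacks column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  bad_cond <- setdiff(unique(x$condition), chromatome_conditions())
  if (length(bad_cond) > 0) {
    stop("unknown condition label(s): ", paste(bad_cond, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(x$psm < 0)) stop("psm counts must be >= 0", call. = FALSE)
  key <- paste(x$protein_id, x$condition, x$replicate)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("duplicate (protein, condition, replicate) entries: ",
      paste(utils::head(dups, 5L), collapse = "; "),
      call. = FALSE
    )
  }
  out <- tibble::as_tibble(x[needed])
  out$condition <- factor(out$condition, levels = chromatome_conditions())
  out$replicate <- as.integer(out$replicate)
  out
}

#' @rdname chromatome_table
#' @export
chromatome_conditions <- function() c("minusEdU", "Luc", "2Cneg", "2Cpos")

`%||%` <- function(a, b) if (is.null(a)) b else a
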