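#' Maximum-intensity z-projection
#'
#' @param zstack 3D array `[y, x, z]`, a 2D matrix (returned unchanged), or a
#'   single-channel [image_stack()].
#' @return 2D matrix of per-pixel maxima over z.
#' @export
max_project <- function(zstack) {
  if (inherits(zstack, "image_stack")) {
    stopifnot(length(zstack$channels) == 1L)
    zstack <- zstack$channels[[1L]]
  }
  d <- dim(zstack)
  if (length(d) == 2L) {
    return(zstack)
  }
  stopifnot(length(d) == 3L, d[3L] >= 1L)
  apply(zstack, c(1L, 2L), max)
}

#' Gaussian blur
#'
#' Isotropic Gaussian filtering with sigma in pixels; `sigma_px = 0` is the
#' identity. Used with the default sigma of 0.5 px on the SMARCAD1 channel
#' before colocalization.
#'
#' @param image 2D numeric matrix.
#' @param sigma_px Gaussian sigma, pixels (>= 0).
#' @return Blurred matrix of the same shape.
#' @export
blur <- function(image, sigma_px) {
  stopifnot(is.numeric(image), length(dim(image)) == 2L, sigma_px >= 0)
  if (sigma_px == 0) {
    return(image)
  }
  # EBImage images are (x, y); transpose in and out
  out <- EBImage::gblur(t(image), sigma = sigma_px)
  t(as.matrix(out))
}

#' Segment bright foci inside a nucleus mask
#'
#' Thresholds the image within the mask (Otsu's method on the masked pixels,
#' or an absolute threshold), labels 8-connected components of
#' supra-threshold pixels inside the mask, and removes components smaller
#' than `min_area_px`. Labels are assigned in raster-scan order of each
#' component's first pixel, so the labelling is deterministic. An image with
#' no supra-threshold pixel yields an empty labelling, not an error.
#'
#' @param image 2D numeric matrix.
#' @param mask Logical nucleus mask, same shape.
#' @param method `"otsu"` or `"absolute"`.
#' @param threshold Absolute threshold (required when `method = "absolute"`);
#'   pixels strictly above it are foreground.
#' @param min_area_px Minimum component size in pixels (default 4).
#' @return Integer label matrix (0 = background) with the threshold used in
#'   the `threshold` attribute.
#' @export
segment_foci <- function(image, mask = NULL, method = c("otsu", "absolute"),
                         threshold = NULL, min_area_px = 4L) {
  method <- match.arg(method)
  stopifnot(is.numeric(image), length(dim(image)) == 2L)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  stopifnot(is.logical(mask), all(dim(mask) == dim(image)))
  if (!any(mask)) stop("empty nucleus mask", call. = FALSE)
  t_used <- switch(method,
    otsu = otsu_threshold(image[mask]),
    absolute = {
      if (is.null(threshold)) stop("method='absolute' needs a threshold", call. = FALSE)
      threshold
    }
  )
  fg <- image > t_used & mask
  labels <- label_components(fg, connectivity = 8L)
  if (min_area_px > 1L && max(labels) > 0L) {
    sizes <- tabulate(labels)
    small <- which(sizes < min_area_px)
    if (length(small) > 0) {
      labels[labels %in% small] <- 0L
      labels <- relabel_raster(labels)
    }
  }
  attr(labels, "threshold") <- t_used
  labels
}

# Otsu's threshold on a numeric sample: maximize between-class variance over
# 256 histogram bins spanning the sample range.
otsu_threshold <- function(v, n_bins = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (rng[1L] == rng[2L]) {
    return(rng[1L])
  }
  br <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  sigma_b <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  br[k + 1L]
}

# 8- or 4-connected component labelling via breadth-first flood fill over
# foreground pixels; labels follow raster-scan order of component seeds.
label_components <- function(fg, connectivity = 8L) {
  stopifnot(is.logical(fg), connectivity %in% c(4L, 8L))
  ny <- nrow(fg)
  nx <- ncol(fg)
  labels <- matrix(0L, ny, nx)
  offs <- if (connectivity == 8L) {
    cbind(
      dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
      dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    )
  } else {
    cbind(dy = c(-1L, 0L, 0L, 1L), dx = c(0L, -1L, 1L, 0L))
  }
  next_label <- 0L
  # raster scan: row-major order (rows = y), matching label determinism
  seeds <- which(fg, arr.ind = TRUE)
  seeds <- seeds[order(seeds[, 1L], seeds[, 2L]), , drop = FALSE]
  for (s in seq_len(nrow(seeds))) {
    sy <- seeds[s, 1L]
    sx <- seeds[s, 2L]
    if (labels[sy, sx] != 0L) next
    next_label <- next_label + 1L
    queue <- matrix(c(sy, sx), 1L, 2L)
    labels[sy, sx] <- next_label
    while (nrow(queue) > 0) {
      cur <- queue[nrow(queue), , drop = FALSE]
      queue <- queue[-nrow(queue), , drop = FALSE]
      ys <- cur[1L] + offs[, 1L]
      xs <- cur[2L] + offs[, 2L]
      ok <- ys >= 1L & ys <= ny & xs >= 1L & xs <= nx
      ys <- ys[ok]
      xs <- xs[ok]
      idx <- cbind(ys, xs)
      new <- fg[idx] & labels[idx] == 0L
      if (any(new)) {
        labels[idx[new, , drop = FALSE]] <- next_label
        queue <- rbind(queue, idx[new, , drop = FALSE])
      }
    }
  }
  labels
}

# compact labels to 1..k preserving raster-scan order of first occurrence
relabel_raster <- function(labels) {
  present <- labels[labels > 0L]
  if (length(present) == 0L) {
    return(labels)
  }
  lin <- as.vector(t(labels)) # row-major raster scan
  uniq <- unique(lin[lin > 0L])
  map <- integer(max(labels))
  map[uniq] <- seq_along(uniq)
  labels[labels > 0L] <- map[labels[labels > 0L]]
  labels
}

#' Per-focus measurements and per-nucleus counts
#'
#' @param labels Label matrix from [segment_foci()].
#' @param image Intensity image the labels were derived from.
#' @param pixel_size_um Pixel size, um/px.
#' @param nucleus_id Id stamped on the rows.
#' @return Tibble with one row per focus: `nucleus_id`, `focus_label`,
#'   `area_um2` (pixel count x pixel area), `mean_intensity`,
#'   `centroid_y_um`, `centroid_x_um`.
#' @export
foci_stats <- function(labels, image, pixel_size_um, nucleus_id = "n1") {
  stopifnot(all(dim(labels) == dim(image)), pixel_size_um > 0)
  k <- max(labels)
  if (k == 0L) {
    return(tibble::tibble(
      nucleus_id = character(), focus_label = integer(),
      area_um2 = numeric(), mean_intensity = numeric(),
      centroid_y_um = numeric(), centroid_x_um = numeric()
    ))
  }
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[idx]
  val <- image[idx]
  tibble::tibble(
    nucleus_id = nucleus_id,
    focus_label = seq_len(k),
    area_um2 = as.numeric(tabulate(lab, k)) * pixel_size_um^2,
    mean_intensity = as.numeric(tapply(val, lab, mean)),
    centroid_y_um = (as.numeric(tapply(idx[, 1L], lab, mean)) - 0.5) * pixel_size_um,
    centroid_x_um = (as.numeric(tapply(idx[, 2L], lab, mean)) - 0.5) * pixel_size_um
  )
}

#' @rdname foci_stats
#' @param foci A `foci_stats()` tibble (possibly several nuclei).
#' @return `foci_count()`: tibble `nucleus_id`, `n_foci`, `mean_area_um2`,
#'   `total_area_um2`.
#' @export
foci_count <- function(foci) {
  dplyr::summarise(
    dplyr::group_by(foci, .data$nucleus_id),
    n_foci = dplyr::n(),
    mean_area_um2 = mean(.data$area_um2),
    total_area_um2 = sum(.data$area_um2),
    .groups = "drop"
  )
}

#' Background-normalized nuclear intensity
#'
#' Mean intensity inside the nuclear mask divided by the mean intensity of a
#' mask-disjoint square background region (the average cytoplasmic signal),
#' as used for embryo blastomere quantification. The background box should be
#' about the size of the nucleus; a warning is issued when the area ratio
#' falls outside \[0.5, 2\].
#'
#' @param image 2D numeric matrix.
#' @param mask Logical nuclear mask.
#' @param background_box Either a logical matrix, or `c(y0, x0, side)` giving
#'   the top-left corner and side (pixels) of a square, or `NULL` to
#'   auto-place the nearest mask-disjoint square of equivalent area to the
#'   nucleus centroid.
#' @param nucleus_id Id stamped on the result.
#' @return Tibble row: `nucleus_id`, `raw_mean`, `background_mean`,
#'   `normalized`.
#' @export
normalized_nuclear_intensity <- function(image, mask, background_box = NULL,
                                         nucleus_id = "n1") {
  stopifnot(is.logical(mask), all(dim(mask) == dim(image)), any(mask))
  box <- resolve_background_box(background_box, mask)
  if (any(box & mask)) {
    stop("background box overlaps the nuclear mask", call. = FALSE)
  }
  ratio <- sum(box) / sum(mask)
  if (ratio < 0.5 || ratio > 2) {
    warning(sprintf(
      "background box area is %.2fx the mask area (recommended within [0.5, 2])",
      ratio
    ), call. = FALSE)
  }
  raw <- mean(image[mask])
  bg <- mean(image[box])
  if (bg <= 0) stop("background mean must be > 0", call. = FALSE)
  tibble::tibble(
    nucleus_id = nucleus_id, raw_mean = raw,
    background_mean = bg, normalized = raw / bg
  )
}

resolve_background_box <- function(background_box, mask) {
  ny <- nrow(mask)
  nx <- ncol(mask)
  if (is.matrix(background_box) && is.logical(background_box)) {
    stopifnot(all(dim(background_box) == dim(mask)), any(background_box))
    return(background_box)
  }
  if (is.numeric(background_box) && length(background_box) == 3L) {
    y0 <- background_box[1L]
    x0 <- background_box[2L]
    side <- background_box[3L]
    stopifnot(y0 >= 1, x0 >= 1, y0 + side - 1 <= ny, x0 + side - 1 <= nx)
    box <- matrix(FALSE, ny, nx)
    box[y0:(y0 + side - 1L), x0:(x0 + side - 1L)] <- TRUE
    return(box)
  }
  if (is.null(background_box)) {
    side <- max(2L, round(sqrt(sum(mask))))
    cen <- colMeans(which(mask, arr.ind = TRUE))
    best <- NULL
    best_d <- Inf
    for (y0 in seq_len(ny - side + 1L)) {
      for (x0 in seq_len(nx - side + 1L)) {
        if (any(mask[y0:(y0 + side - 1L), x0:(x0 + side - 1L)])) next
        d <- (y0 + (side - 1) / 2 - cen[1L])^2 + (x0 + (side - 1) / 2 - cen[2L])^2
        if (d < best_d) {
          best_d <- d
          best <- c(y0, x0)
        }
      }
    }
    if (is.null(best)) {
      stop("no mask-disjoint background box of matching size fits the field",
        call. = FALSE
      )
    }
    box <- matrix(FALSE, ny, nx)
    box[best[1L]:(best[1L] + side - 1L), best[2L]:(best[2L] + side - 1L)] <- TRUE
    return(box)
  }
  stop("background_box must be NULL, a logical matrix, or c(y0, x0, side)",
    call. = FALSE
  )
}
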