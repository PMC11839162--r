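#' Voronoi tessellation of localization coordinates
#'
#' Tessellates each nucleus's localizations and attaches the local density of
#' every retained cell, defined as the inverse of its polygon area (nm^-2).
#' High local density marks compact chromatin; the per-nucleus mean density
#' (see [mean_voronoi_density()]) summarizes global DNA compaction.
#'
#' Two boundary policies are offered because border cells of a raw Voronoi
#' diagram are unbounded:
#'
#' * `mode = "clip"` (default) intersects every cell — including unbounded
#'   ones — with `clip_region`, so retained areas sum exactly to the region
#'   area.
#' * `mode = "drop_boundary"` discards cells whose raw (unclipped) Voronoi
#'   region is unbounded, i.e. the cells of sites on the convex hull.
#'
#' Exact duplicate coordinates produce zero-area degenerate cells and are
#' removed before tessellation (a message reports how many); each retained
#' localization then owns exactly one cell.
#'
#' @param locs Localization tibble (`nucleus_id`, `x_nm`, `y_nm`), one or
#'   several nuclei. Needs >= 3 non-collinear points per nucleus.
#' @param clip_region Optional polygon, a two-column matrix of (x, y)
#'   vertices in nm containing all points of a nucleus; when `NULL` the
#'   convex hull of each nucleus's localizations is used. Ignored under
#'   `mode = "drop_boundary"`.
#' @param mode `"clip"` or `"drop_boundary"`.
#' @return A tibble of class `voronoi_tessellation`: one row per retained
#'   localization with `nucleus_id`, `loc_id` (row index within nucleus),
#'   `x_nm`, `y_nm`, `area_nm2`, `density_nm2inv`, `boundary_cell` (was the
#'   raw cell unbounded?) and a `polygon` list-column of vertex matrices.
#'   The clip-region area per nucleus is kept in the `clip_area_nm2`
#'   attribute.
#' @examples
#' pts <- tibble::tibble(
#'   nucleus_id = "n1",
#'   x_nm = c(25, 75, 25, 75), y_nm = c(25, 25, 75, 75)
#' )
#' sq <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
#' tes <- voronoi_tessellate(pts, clip_region = sq)
#' tes$area_nm2 # four cells of 2500 nm^2 each
#' @export
voronoi_tessellate <- function(locs, clip_region = NULL,
                               mode = c("clip", "drop_boundary")) {
  mode <- match.arg(mode)
  stopifnot(all(c("nucleus_id", "x_nm", "y_nm") %in% names(locs)))
  out <- vector("list", length(unique(locs$nucleus_id)))
  ids <- unique(locs$nucleus_id)
  areas <- stats::setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    sub <- locs[locs$nucleus_id == ids[i], ]
    res <- tryCatch(
      tessellate_one(sub, clip_region, mode),
      error = function(e) {
        stop("nucleus '", ids[i], "': ", conditionMessage(e), call. = FALSE)
      }
    )
    out[[i]] <- res$cells
    areas[i] <- res$clip_area
  }
  res <- dplyr::bind_rows(out)
  attr(res, "clip_area_nm2") <- areas
  attr(res, "mode") <- mode
  class(res) <- c("voronoi_tessellation", class(res))
  res
}

tessellate_one <- function(sub, clip_region, mode) {
  xy <- cbind(sub$x_nm, sub$y_nm)
  dup <- duplicated(xy)
  if (any(dup)) {
    message(sum(dup), " exact duplicate localization(s) removed before tessellation")
    sub <- sub[!dup, , drop = FALSE]
    xy <- xy[!dup, , drop = FALSE]
  }
  n <- nrow(xy)
  if (n < 3L) stop("needs >= 3 distinct localizations", call. = FALSE)
  cross <- (xy[, 1L] - xy[1L, 1L]) * (xy[2L, 2L] - xy[1L, 2L]) -
    (xy[, 2L] - xy[1L, 2L]) * (xy[2L, 1L] - xy[1L, 1L])
  if (all(abs(cross) < 1e-9)) {
    stop("all localizations are collinear; tessellation is degenerate", call. = FALSE)
  }

  hull <- grDevices::chull(xy)
  on_hull <- seq_len(n) %in% hull

  if (mode == "clip") {
    if (is.null(clip_region)) {
      # counter-clockwise hull, dilated by a relative 1e-9 so the hull
      # sites themselves lie strictly inside the region
      region <- xy[rev(hull), , drop = FALSE]
      cen <- colMeans(region)
      region <- sweep(sweep(region, 2L, cen) * (1 + 1e-9), 2L, cen, `+`)
    } else {
      region <- as.matrix(clip_region)
      stopifnot(ncol(region) == 2L, nrow(region) >= 3L)
      if (shoelace_area(region) < 0) region <- region[rev(seq_len(nrow(region))), ]
    }
    if (is_convex(region)) {
      res <- clip_cells_deldir(xy, region)
    } else {
      res <- clip_cells_spatstat(xy, region)
    }
    polys <- res$polys
    area <- res$area
    clip_area <- abs(shoelace_area(region))
    keep <- seq_len(n)
  } else {
    # enclose the diagram in a frame and push it outwards until no bounded
    # (non-hull) cell touches it: vertices of bounded cells are Delaunay
    # circumcenters, which can lie far outside the data
    keep <- which(!on_hull)
    if (length(keep) == 0L) {
      stop("no interior cells remain after dropping boundary cells", call. = FALSE)
    }
    rng <- apply(xy, 2L, range)
    pad <- 4 * max(diff(rng[, 1L]), diff(rng[, 2L])) + 1
    for (iter in 1:40) {
      rw <- c(
        rng[1L, 1L] - pad, rng[2L, 1L] + pad,
        rng[1L, 2L] - pad, rng[2L, 2L] + pad
      )
      tl <- deldir_tiles(xy, rw, with_bp = TRUE)
      if (!any(tl$on_frame[keep])) break
      pad <- pad * 4
    }
    polys <- tl$polys[keep]
    area <- tl$area[keep]
    clip_area <- NA_real_
  }

  tibble::tibble(
    nucleus_id = sub$nucleus_id[1L],
    loc_id = keep,
    x_nm = xy[keep, 1L],
    y_nm = xy[keep, 2L],
    area_nm2 = as.numeric(area),
    density_nm2inv = 1 / as.numeric(area),
    boundary_cell = on_hull[keep],
    polygon = polys
  ) -> cells
  list(cells = cells, clip_area = clip_area)
}

# raw deldir tiles clipped to the rectangle rw = c(x0, x1, y0, y1),
# returned in site order
deldir_tiles <- function(xy, rw, with_bp = FALSE) {
  dd <- deldir::deldir(xy[, 1L], xy[, 2L], rw = rw)
  tl <- deldir::tile.list(dd)
  ord <- vapply(tl, function(t) t$ptNum, integer(1))
  polys <- vector("list", nrow(xy))
  area <- numeric(nrow(xy))
  on_frame <- logical(nrow(xy))
  for (k in seq_along(tl)) {
    p <- cbind(x = tl[[k]]$x, y = tl[[k]]$y)
    polys[[ord[k]]] <- p
    area[ord[k]] <- abs(shoelace_area(p))
    if (with_bp) on_frame[ord[k]] <- any(tl[[k]]$bp)
  }
  list(polys = polys, area = area, on_frame = on_frame)
}

# fast path: deldir tiles (clipped to the region bounding box) intersected
# with a convex clip polygon by Sutherland-Hodgman
clip_cells_deldir <- function(xy, region) {
  if (!all(point_in_convex(xy, region))) {
    stop("clip_region does not contain all localizations", call. = FALSE)
  }
  rw <- c(range(region[, 1L]), range(region[, 2L]))
  tl <- deldir_tiles(xy, rw)
  # only tiles with a vertex outside the region need clipping
  nv <- vapply(tl$polys, nrow, integer(1))
  verts <- do.call(rbind, tl$polys)
  v_in <- point_in_convex(verts, region)
  tile_of <- rep.int(seq_along(tl$polys), nv)
  needs_clip <- tapply(!v_in, tile_of, any)
  polys <- tl$polys
  area <- tl$area
  for (i in which(needs_clip)) {
    p <- sh_clip_convex(polys[[i]], region)
    if (nrow(p) < 3L) {
      stop("a Voronoi cell degenerated during clipping", call. = FALSE)
    }
    polys[[i]] <- p
    area[i] <- abs(shoelace_area(p))
  }
  list(polys = polys, area = area)
}

# general path for non-convex simple clip polygons
clip_cells_spatstat <- function(xy, region) {
  win <- spatstat.geom::owin(poly = list(x = region[, 1L], y = region[, 2L]))
  if (!all(spatstat.geom::inside.owin(xy[, 1L], xy[, 2L], win))) {
    stop("clip_region does not contain all localizations", call. = FALSE)
  }
  pp <- spatstat.geom::ppp(xy[, 1L], xy[, 2L], window = win)
  tess <- spatstat.geom::dirichlet(pp)
  list(
    polys = lapply(spatstat.geom::tiles(tess), owin_to_poly),
    area = as.numeric(spatstat.geom::tile.areas(tess))
  )
}

# Sutherland-Hodgman: clip polygon `subject` against counter-clockwise
# convex polygon `clip`
sh_clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0L) break
    a <- clip[e, ]
    b <- clip[if (e == nc) 1L else e + 1L, ]
    # inside = left of directed edge a->b
    s <- (b[1L] - a[1L]) * (out[, 2L] - a[2L]) -
      (b[2L] - a[2L]) * (out[, 1L] - a[1L])
    keep_pt <- s >= -1e-12 * max(abs(s), 1)
    n_out <- nrow(out)
    new_pts <- list()
    for (i in seq_len(n_out)) {
      j <- if (i == n_out) 1L else i + 1L
      if (keep_pt[i]) new_pts[[length(new_pts) + 1L]] <- out[i, ]
      if (xor(keep_pt[i], keep_pt[j])) {
        t <- s[i] / (s[i] - s[j])
        new_pts[[length(new_pts) + 1L]] <-
          out[i, ] + t * (out[j, ] - out[i, ])
      }
    }
    out <- if (length(new_pts) > 0) do.call(rbind, new_pts) else subject[0, , drop = FALSE]
  }
  out
}

is_convex <- function(poly) {
  n <- nrow(poly)
  if (n < 4L) {
    return(TRUE)
  }
  nxt <- c(seq_len(n)[-1L], 1L)
  e <- poly[nxt, , drop = FALSE] - poly
  cr <- e[, 1L] * e[nxt, 2L] - e[, 2L] * e[nxt, 1L]
  all(cr >= -1e-12 * max(abs(cr))) || all(cr <= 1e-12 * max(abs(cr)))
}

point_in_convex <- function(xy, region) {
  # region counter-clockwise; points within ~1e-12 of the region diameter
  # from the boundary count as inside
  n <- nrow(region)
  diam <- max(diff(range(region[, 1L])), diff(range(region[, 2L])))
  ok <- rep(TRUE, nrow(xy))
  for (e in seq_len(n)) {
    a <- region[e, ]
    b <- region[if (e == n) 1L else e + 1L, ]
    s <- (b[1L] - a[1L]) * (xy[, 2L] - a[2L]) -
      (b[2L] - a[2L]) * (xy[, 1L] - a[1L])
    elen <- sqrt(sum((b - a)^2))
    ok <- ok & s >= -1e-12 * elen * diam
  }
  ok
}

owin_to_poly <- function(w) {
  if (w$type == "rectangle") {
    return(cbind(
      x = c(w$xrange[1L], w$xrange[2L], w$xrange[2L], w$xrange[1L]),
      y = c(w$yrange[1L], w$yrange[1L], w$yrange[2L], w$yrange[2L])
    ))
  }
  b <- w$bdry[[1L]]
  cbind(x = b$x, y = b$y)
}

shoelace_area <- function(poly) {
  x <- poly[, 1L]
  y <- poly[, 2L]
  j <- c(seq_len(nrow(poly))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Per-nucleus mean Voronoi density
#'
#' The arithmetic mean of the per-cell local densities (inverse polygon
#' areas) of a nucleus, in nm^-2 — the global DNA-compaction summary used for
#' comparing nuclei.
#'
#' @param tess A [voronoi_tessellate()] result.
#' @return A tibble with `nucleus_id`, `n_cells` and
#'   `mean_density_nm2inv`.
#' @export
mean_voronoi_density <- function(tess) {
  stopifnot(inherits(tess, "voronoi_tessellation"))
  if (nrow(tess) == 0L) stop("empty tessellation", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(tess), .data$nucleus_id),
    n_cells = dplyr::n(),
    mean_density_nm2inv = mean(.data$density_nm2inv),
    .groups = "drop"
  )
}

#' Density rendering categories
#'
#' Assigns each Voronoi polygon the category used for density-map rendering:
#' the `ceiling(black_fraction * n)` largest-area polygons per nucleus are
#' `black` (area ties broken by localization index); among the remainder,
#' densities at or above `density_hi` are `clamped_high` (smallest polygons,
#' "yellow" end), densities at or below `density_lo` are `clamped_low`
#' ("blue" end), and intermediate densities are `graded` with position
#' `t = (log10 d - log10 density_lo) / (log10 density_hi - log10 density_lo)`
#' in (0, 1).
#'
#' @param tess A [voronoi_tessellate()] result.
#' @param config An [analysis_config()].
#' @return `tess` with `category` (factor black/clamped_high/graded/
#'   clamped_low) and `grade_t` (in \[0, 1\]; 1 for clamped_high, 0 for
#'   clamped_low, NA for black) columns added.
#' @export
render_density <- function(tess, config = analysis_config()) {
  stopifnot(inherits(tess, "voronoi_tessellation"))
  validate_config(config)
  lo <- log10(config$density_lo)
  hi <- log10(config$density_hi)
  per_nuc <- function(d) {
    n <- length(d$density_nm2inv)
    n_black <- ceiling(config$black_fraction * n)
    ord <- order(-d$area_nm2, d$loc_id)
    black <- seq_len(n) %in% ord[seq_len(n_black)]
    t_raw <- (log10(d$density_nm2inv) - lo) / (hi - lo)
    cat <- dplyr::case_when(
      black ~ "black",
      d$density_nm2inv >= config$density_hi ~ "clamped_high",
      d$density_nm2inv <= config$density_lo ~ "clamped_low",
      TRUE ~ "graded"
    )
    d$category <- factor(cat, levels = c("black", "clamped_high", "graded", "clamped_low"))
    d$grade_t <- ifelse(black, NA_real_, pmin(pmax(t_raw, 0), 1))
    d
  }
  out <- dplyr::bind_rows(lapply(
    split(tibble::as_tibble(tess), tess$nucleus_id),
    per_nuc
  ))
  attr(out, "clip_area_nm2") <- attr(tess, "clip_area_nm2")
  class(out) <- c("voronoi_tessellation", class(out))
  out
}

#' Per-nucleus compaction table
#'
#' Runs the tessellation-and-mean-density summary for a cohort of nuclei and
#' joins the per-nucleus GFP scores and 2C classes, producing the records
#' behind the biaxial compaction-vs-reporter plot.
#'
#' @param locs Localization tibble covering all nuclei.
#' @param gfp_scores Tibble with `nucleus_id` and `gfp_score` (in \[0, 1\],
#'   see [normalize_scores()]).
#' @param config An [analysis_config()] (classification threshold).
#' @param clip_region,mode Passed to [voronoi_tessellate()].
#' @return A tibble with one row per nucleus: `nucleus_id`,
#'   `mean_density_nm2inv`, `gfp_score`, `two_c_class`.
#' @export
compaction_table <- function(locs, gfp_scores, config = analysis_config(),
                             clip_region = NULL, mode = "clip") {
  stopifnot(all(c("nucleus_id", "gfp_score") %in% names(gfp_scores)))
  dens <- mean_voronoi_density(voronoi_tessellate(locs, clip_region, mode))
  out <- dplyr::left_join(dens, gfp_scores[c("nucleus_id", "gfp_score")],
    by = "nucleus_id"
  )
  out$two_c_class <- classify_2c(out$gfp_score, config)
  out[c("nucleus_id", "mean_density_nm2inv", "gfp_score", "two_c_class")]
}
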