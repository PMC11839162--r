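#' Simulation specifications
#'
#' Constructors for the three generator specs. Defaults describe the two
#' chromatin regimes the analyses are designed to separate:
#'
#' * `nucleus_sim_spec()` — a disk nucleus of radius `nucleus_radius_nm`
#'   containing `n_localizations` single-molecule localizations, a fraction
#'   `clustered_fraction` of which is drawn from `n_clusters` isotropic
#'   Gaussian clusters (sd `cluster_sigma_nm`) centred uniformly in the disk,
#'   the remainder uniform; every point receives i.i.d. Gaussian localization
#'   error with sd `localization_precision_nm` (~20 nm, typical of STORM
#'   fits). High `clustered_fraction` mimics compact pluripotent-like
#'   chromatin, low values the decompacted 2C-positive state.
#' * `foci_image_spec()` — an elliptical nucleus over `image_shape` containing
#'   `k_foci` disk-shaped foci of radius `focus_radius_um` and amplitude
#'   `focus_intensity` over a `background_mean` floor, with Poisson shot noise
#'   and/or additive Gaussian read noise; a second channel shares a fraction
#'   `channel_overlap` of focus positions.
#' * `chromatome_sim_spec()` — negative-binomial PSM counts for `n_proteins`
#'   across the four iPOTD conditions; `spike_sets` elevates named protein
#'   subsets by per-condition fold effects over `baseline_mean`; the
#'   no-capture `minusEdU` control uses `background_mean`.
#'
#' @param nucleus_radius_nm,n_localizations,n_clusters,cluster_sigma_nm,clustered_fraction,localization_precision_nm,gfp_level
#'   See above; lengths in nm.
#' @param image_shape `c(ny, nx)` in pixels.
#' @param pixel_size_um,k_foci,focus_radius_um,focus_intensity,background_mean,noise_model,channel_overlap,read_noise_sd
#'   See above.
#' @param min_gap_um Minimum edge-to-edge gap between foci (um); foci are
#'   well-separated by construction so that 8-connected segmentation cannot
#'   bridge them through noise.
#' @param n_proteins,replicates,baseline_mean,dispersion,spike_sets,minus_edu_mean
#'   See above; `dispersion` is the NB dispersion (variance =
#'   mu + dispersion * mu^2); `spike_sets` is a named list of
#'   `list(proteins =, folds = c(Luc =, `2Cneg` =, `2Cpos` =))`.
#' @return A spec object (validated named list).
#' @name sim_specs
NULL

#' @rdname sim_specs
#' @export
nucleus_sim_spec <- function(nucleus_radius_nm = 3000,
                             n_localizations = 2000,
                             n_clusters = 60,
                             cluster_sigma_nm = 60,
                             clustered_fraction = 0.8,
                             localization_precision_nm = 20,
                             gfp_level = 100) {
  stopifnot(
    nucleus_radius_nm > 0, n_localizations >= 1, n_clusters >= 1,
    cluster_sigma_nm > 0,
    clustered_fraction >= 0, clustered_fraction <= 1,
    localization_precision_nm >= 0, gfp_level >= 0
  )
  if (cluster_sigma_nm >= nucleus_radius_nm) {
    warning("cluster_sigma_nm >= nucleus_radius_nm: ",
      "clusters are indistinguishable from a uniform pattern",
      call. = FALSE
    )
  }
  structure(as.list(environment()), class = "nucleus_sim_spec")
}

#' @rdname sim_specs
#' @export
foci_image_spec <- function(image_shape = c(128L, 128L),
                            pixel_size_um = 0.1,
                            k_foci = 9L,
                            focus_radius_um = 0.8,
                            focus_intensity = 400,
                            background_mean = 20,
                            noise_model = c("poisson+gaussian", "poisson", "gaussian"),
                            read_noise_sd = 3,
                            channel_overlap = 1,
                            min_gap_um = 0.3) {
  noise_model <- match.arg(noise_model)
  stopifnot(
    length(image_shape) == 2L, all(image_shape >= 16L),
    pixel_size_um > 0, k_foci >= 0, focus_radius_um > 0,
    focus_intensity >= 0, background_mean >= 0, read_noise_sd >= 0,
    channel_overlap >= 0, channel_overlap <= 1, min_gap_um >= 0
  )
  structure(as.list(environment()), class = "foci_image_spec")
}

#' @rdname sim_specs
#' @export
chromatome_sim_spec <- function(n_proteins = 500L,
                                replicates = c(minusEdU = 3L, Luc = 4L, `2Cneg` = 4L, `2Cpos` = 3L),
                                baseline_mean = 20,
                                dispersion = 0.3,
                                spike_sets = list(),
                                minus_edu_mean = 10) {
  stopifnot(
    n_proteins >= 1, baseline_mean > 0, dispersion >= 0, minus_edu_mean > 0,
    all(chromatome_conditions() %in% names(replicates))
  )
  if (any(replicates < 1)) stop("every condition needs >= 1 replicate", call. = FALSE)
  for (s in spike_sets) {
    stopifnot(
      is.character(s$proteins), length(s$proteins) >= 1,
      all(c("Luc", "2Cneg", "2Cpos") %in% names(s$folds)),
      all(s$folds > 0)
    )
  }
  structure(as.list(environment()), class = "chromatome_sim_spec")
}

#' Simulate a single-nucleus localization table
#'
#' Draws a clustered-plus-uniform point pattern in a disk nucleus and adds
#' Gaussian localization error (see [nucleus_sim_spec()]). A pure function of
#' `(spec, seed)`: identical arguments give identical tables.
#'
#' @param spec A [nucleus_sim_spec()].
#' @param seed Integer seed.
#' @param nucleus_id Id stamped on the rows.
#' @return A list with `locs` (tibble `nucleus_id`, `x_nm`, `y_nm`) and
#'   `truth` (cluster centres, per-point cluster membership, the spec).
#' @examples
#' sim <- simulate_localizations(nucleus_sim_spec(n_localizations = 100), seed = 1)
#' nrow(sim$locs)
#' @export
simulate_localizations <- function(spec, seed, nucleus_id = "n1") {
  stopifnot(inherits(spec, "nucleus_sim_spec"))
  local_stream_seed(seed, paste0("localizations/", nucleus_id))
  n <- spec$n_localizations
  n_clu <- round(spec$clustered_fraction * n)
  centers <- runif_disk(spec$n_clusters, spec$nucleus_radius_nm)
  member <- integer(n)
  xy <- matrix(0, n, 2L)
  if (n_clu > 0) {
    member[seq_len(n_clu)] <- sample.int(spec$n_clusters, n_clu, replace = TRUE)
    xy[seq_len(n_clu), ] <- centers[member[seq_len(n_clu)], , drop = FALSE] +
      matrix(stats::rnorm(2L * n_clu, sd = spec$cluster_sigma_nm), n_clu, 2L)
  }
  if (n_clu < n) {
    xy[(n_clu + 1L):n, ] <- runif_disk(n - n_clu, spec$nucleus_radius_nm)
  }
  xy <- xy + matrix(stats::rnorm(2L * n, sd = spec$localization_precision_nm), n, 2L)
  locs <- tibble::tibble(nucleus_id = nucleus_id, x_nm = xy[, 1L], y_nm = xy[, 2L])
  truth <- list(
    cluster_centers_nm = centers, cluster_member = member,
    n_clustered = n_clu, spec = spec
  )
  list(locs = locs, truth = truth)
}

# uniform points in a disk of given radius centred at the origin
runif_disk <- function(n, radius) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th))
}

#' Simulate a two-channel nucleus image with bright foci
#'
#' Renders `k_foci` disk foci inside an elliptical nucleus mask over a noisy
#' background (see [foci_image_spec()]). Focus centres are rejection-sampled
#' to be pairwise separated by at least `2 * focus_radius_um + min_gap_um`
#' and to lie fully inside the nucleus. Channel 2 reuses a
#' `channel_overlap` fraction of channel-1 centres and places the rest
#' independently under the same constraints.
#'
#' @param spec A [foci_image_spec()].
#' @param seed Integer seed.
#' @param nucleus_id Id for the mask/truth.
#' @return A list with `stack` (an [image_stack()] with channels `ch1`,
#'   `ch2`), `mask` (logical nucleus matrix) and `truth` (exact centres in um
#'   per channel, radius, count, the spec).
#' @export
simulate_foci_image <- function(spec, seed, nucleus_id = "n1") {
  stopifnot(inherits(spec, "foci_image_spec"))
  local_stream_seed(seed, paste0("foci_image/", nucleus_id))
  ny <- spec$image_shape[1L]
  nx <- spec$image_shape[2L]
  px <- spec$pixel_size_um
  cy <- (ny + 1) / 2
  cx <- (nx + 1) / 2
  ry <- 0.44 * ny
  rx <- 0.46 * nx
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  mask <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1

  r_px <- spec$focus_radius_um / px
  gap_px <- max(1, spec$min_gap_um / px)
  place <- function(k, fixed = NULL) {
    centers <- fixed
    tries <- 0L
    while ((nrow(centers) %||% 0L) < k + nrow(fixed %||% matrix(0, 0, 2))) {
      if (is.null(centers)) centers <- matrix(0, 0, 2L)
      if (tries > 5000L) {
        stop("could not place ", k, " foci without overlap; achievable maximum here: ",
          nrow(centers) - nrow(fixed %||% matrix(0, 0, 2)),
          call. = FALSE
        )
      }
      tries <- tries + 1L
      cand <- c(
        stats::runif(1, 1 + r_px, ny - r_px),
        stats::runif(1, 1 + r_px, nx - r_px)
      )
      # focus fully inside the nucleus ellipse (shrunken by the radius)
      inside <- ((cand[1L] - cy) / (ry - r_px))^2 +
        ((cand[2L] - cx) / (rx - r_px))^2 <= 1
      if (!inside) next
      if (nrow(centers) > 0) {
        d <- sqrt((centers[, 1L] - cand[1L])^2 + (centers[, 2L] - cand[2L])^2)
        if (any(d < 2 * r_px + gap_px)) next
      }
      centers <- rbind(centers, cand)
    }
    centers %||% matrix(0, 0, 2L)
  }

  c1 <- place(spec$k_foci)
  n_shared <- round(spec$channel_overlap * spec$k_foci)
  shared <- c1[seq_len(n_shared), , drop = FALSE]
  c2 <- place(spec$k_foci - n_shared, fixed = shared)

  render <- function(centers) {
    sig <- matrix(0, ny, nx)
    if (nrow(centers) > 0) {
      for (i in seq_len(nrow(centers))) {
        d2 <- (yy - centers[i, 1L])^2 + (xx - centers[i, 2L])^2
        sig[d2 <= r_px^2] <- sig[d2 <= r_px^2] + spec$focus_intensity
      }
    }
    clean <- spec$background_mean + sig
    out <- switch(spec$noise_model,
      "poisson" = stats::rpois(length(clean), clean),
      "gaussian" = clean + stats::rnorm(length(clean), sd = spec$read_noise_sd),
      "poisson+gaussian" = stats::rpois(length(clean), clean) +
        stats::rnorm(length(clean), sd = spec$read_noise_sd)
    )
    matrix(pmax(round(out), 0), ny, nx)
  }

  stack <- image_stack(
    list(ch1 = render(c1), ch2 = render(c2)),
    pixel_size_um = px
  )
  to_um <- function(m) {
    if (nrow(m) == 0) {
      return(matrix(numeric(), 0, 2, dimnames = list(NULL, c("y_um", "x_um"))))
    }
    matrix(c((m[, 1L] - 0.5) * px, (m[, 2L] - 0.5) * px),
      ncol = 2, dimnames = list(NULL, c("y_um", "x_um"))
    )
  }
  truth <- list(
    nucleus_id = nucleus_id,
    centers_ch1_um = to_um(c1), centers_ch2_um = to_um(c2),
    k_foci = spec$k_foci, focus_radius_um = spec$focus_radius_um,
    n_shared = n_shared, spec = spec
  )
  list(stack = stack, mask = mask, truth = truth)
}

#' Simulate a conventional GFP field with several nuclei
#'
#' Places non-overlapping elliptical nuclei on a dark field; each nucleus is
#' filled with its spec's `gfp_level` plus Poisson+Gaussian noise. Used to
#' exercise GFP-score normalization: the expected mean ADU of a nucleus
#' equals its `gfp_level` plus the field background, so the ground-truth
#' ordering of `gfp_level` is the ordering of expected mean intensity.
#'
#' @param nuclei_specs List of [nucleus_sim_spec()]s (only `gfp_level` is
#'   used here).
#' @param seed Integer seed.
#' @param image_shape Field shape `c(ny, nx)` in pixels.
#' @param nucleus_radius_px Nucleus radius in pixels.
#' @param background_mean Field background, ADU.
#' @param read_noise_sd Additive Gaussian noise sd (0 for noiseless).
#' @param poisson Logical; apply Poisson shot noise.
#' @param pixel_size_um Pixel size.
#' @return A list with `stack` (channel `gfp`), `masks` (integer label matrix,
#'   nucleus i labelled i) and `truth` (`gfp_level` per nucleus).
#' @export
simulate_gfp_field <- function(nuclei_specs, seed,
                               image_shape = c(64L, 64L * length(nuclei_specs)),
                               nucleus_radius_px = 20,
                               background_mean = 0,
                               read_noise_sd = 2,
                               poisson = TRUE,
                               pixel_size_um = 0.16) {
  stopifnot(length(nuclei_specs) >= 1)
  for (s in nuclei_specs) stopifnot(inherits(s, "nucleus_sim_spec"))
  local_stream_seed(seed, "gfp_field")
  ny <- image_shape[1L]
  nx <- image_shape[2L]
  n <- length(nuclei_specs)
  if (nx < n * (2 * nucleus_radius_px + 2)) {
    stop("field too narrow for ", n, " non-overlapping nuclei", call. = FALSE)
  }
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  labels <- matrix(0L, ny, nx)
  clean <- matrix(background_mean, ny, nx)
  step <- nx / n
  for (i in seq_len(n)) {
    cxi <- (i - 0.5) * step
    cyi <- (ny + 1) / 2
    in_i <- (yy - cyi)^2 + (xx - cxi)^2 <= nucleus_radius_px^2
    if (!any(in_i)) stop("empty nucleus mask for nucleus ", i, call. = FALSE)
    labels[in_i] <- i
    clean[in_i] <- clean[in_i] + nuclei_specs[[i]]$gfp_level
  }
  out <- clean
  if (poisson) out <- matrix(stats::rpois(length(clean), clean), ny, nx)
  if (read_noise_sd > 0) {
    out <- out + matrix(stats::rnorm(length(out), sd = read_noise_sd), ny, nx)
  }
  out <- pmax(out, 0)
  list(
    stack = image_stack(list(gfp = out), pixel_size_um),
    masks = labels,
    truth = list(
      gfp_level = vapply(nuclei_specs, `[[`, numeric(1), "gfp_level"),
      background_mean = background_mean
    )
  )
}

#' Simulate a chromatome PSM table
#'
#' Negative-binomial counts per (protein, condition, replicate): the capture
#' conditions (`Luc`, `2Cneg`, `2Cpos`) use `baseline_mean` multiplied by any
#' spike-set fold for that protein and condition; the no-capture `minusEdU`
#' control uses `minus_edu_mean` for every protein. Variance is
#' `mu + dispersion * mu^2`.
#'
#' @param spec A [chromatome_sim_spec()].
#' @param seed Integer seed.
#' @return A list with `table` (validated chromatome tibble) and `truth`
#'   (per-protein spike label and fold matrix).
#' @export
simulate_chromatome <- function(spec, seed) {
  stopifnot(inherits(spec, "chromatome_sim_spec"))
  local_stream_seed(seed, "chromatome")
  prot <- sprintf("P%04d", seq_len(spec$n_proteins))
  conds <- chromatome_conditions()
  folds <- matrix(1, spec$n_proteins, 3L,
    dimnames = list(prot, c("Luc", "2Cneg", "2Cpos"))
  )
  spike_label <- rep(NA_character_, spec$n_proteins)
  for (nm in names(spec$spike_sets)) {
    s <- spec$spike_sets[[nm]]
    idx <- match(s$proteins, prot)
    if (anyNA(idx)) stop("spike set '", nm, "' names unknown proteins", call. = FALSE)
    folds[idx, ] <- rep(s$folds[c("Luc", "2Cneg", "2Cpos")], each = length(idx))
    spike_label[idx] <- nm
  }
  rows <- list()
  for (cond in conds) {
    mu <- if (cond == "minusEdU") {
      rep(spec$minus_edu_mean, spec$n_proteins)
    } else {
      spec$baseline_mean * folds[, cond]
    }
    for (r in seq_len(spec$replicates[[cond]])) {
      counts <- if (spec$dispersion > 0) {
        stats::rnbinom(spec$n_proteins, mu = mu, size = 1 / spec$dispersion)
      } else {
        stats::rpois(spec$n_proteins, mu)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        protein_id = prot, condition = cond, replicate = r, psm = counts
      )
    }
  }
  tbl <- chromatome_table(dplyr::bind_rows(rows))
  list(
    table = tbl,
    truth = list(spike_label = stats::setNames(spike_label, prot), folds = folds, spec = spec)
  )
}
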