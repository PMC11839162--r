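#' Analysis configuration
#'
#' Bundles every fixed constant of the pipeline in one place so that a whole
#' analysis is reproducible from a single object. All defaults are the values
#' used throughout the package's reference workflow: the Voronoi rendering
#' bounds (`density_hi` = 0.01 nm^-2, `density_lo` = 1e-4 nm^-2), the fraction
#' of largest polygons blacked out in renderings (`black_fraction` = 0.5%),
#' the GFP-score cutoff separating 2C-negative from 2C-positive nuclei
#' (`gfp_threshold` = 0.2, strict inequality), the Gaussian blur width applied
#' before colocalization (`blur_sigma_px` = 0.5 px), the fold-change cutoff
#' for chromatome selection (`fc_cutoff` = 2), the pseudocount added to PSM
#' means before ratios (`pseudocount` = 1), the localization precision of the
#' STORM fits (`localization_precision_nm` = 20) and the effective camera
#' pixel size (`pixel_size_nm` = 160).
#'
#' @param density_hi Upper rendering bound, nm^-2; densities at or above it are
#'   clamped high ("yellow" end).
#' @param density_lo Lower rendering bound, nm^-2; densities at or below it are
#'   clamped low ("blue" end).
#' @param black_fraction Fraction of largest-area polygons set to black.
#' @param gfp_threshold GFP intensity score above which a nucleus is 2C-positive.
#' @param blur_sigma_px Gaussian blur sigma in pixels.
#' @param fc_cutoff Minimum average enrichment (linear fold) for selection.
#' @param pseudocount Added to PSM condition means before forming ratios.
#' @param localization_precision_nm Gaussian localization error (sd, nm).
#' @param pixel_size_nm Effective pixel size used to convert pixel-dialect
#'   localization files to nm.
#' @param rng_seed Integer seed recorded with the configuration.
#'
#' @return An object of class `analysis_config` (a validated named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$fc_cutoff
#' @export
analysis_config <- function(density_hi = 0.01,
                            density_lo = 1e-4,
                            black_fraction = 0.005,
                            gfp_threshold = 0.2,
                            blur_sigma_px = 0.5,
                            fc_cutoff = 2.0,
                            pseudocount = 1.0,
                            localization_precision_nm = 20,
                            pixel_size_nm = 160,
                            rng_seed = 1L) {
  cfg <- list(
    density_hi = density_hi, density_lo = density_lo,
    black_fraction = black_fraction, gfp_threshold = gfp_threshold,
    blur_sigma_px = blur_sigma_px, fc_cutoff = fc_cutoff,
    pseudocount = pseudocount,
    localization_precision_nm = localization_precision_nm,
    pixel_size_nm = pixel_size_nm, rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  stopifnot(
    "density_lo must be < density_hi" = cfg$density_lo < cfg$density_hi,
    "black_fraction must be in (0, 1)" =
      cfg$black_fraction > 0 && cfg$black_fraction < 1,
    "fc_cutoff must be > 0" = cfg$fc_cutoff > 0,
    "pseudocount must be > 0" = cfg$pseudocount > 0,
    "gfp_threshold must be in [0, 1]" =
      cfg$gfp_threshold >= 0 && cfg$gfp_threshold <= 1,
    "blur_sigma_px must be >= 0" = cfg$blur_sigma_px >= 0,
    "pixel_size_nm must be > 0" = cfg$pixel_size_nm > 0,
    "localization_precision_nm must be >= 0" =
      cfg$localization_precision_nm >= 0
  )
  invisible(cfg)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (k in names(x)) cat(sprintf("  %-26s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read or write a flat key-value configuration file
#'
#' The on-disk format is one `key: value` pair per line (a flat YAML subset);
#' unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path File path.
#' @param config An `analysis_config` (for writing).
#' @return `read_config()` returns an `analysis_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1L], collapse = ":"), ""))
  known <- names(formals(analysis_config))
  bad <- setdiff(keys, known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  args <- stats::setNames(as.list(as.numeric(vals)), keys)
  do.call(analysis_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  writeLines(sprintf("%s: %.15g", names(config), unlist(config)), path)
  invisible(path)
}

# Seed a reproducible, generator-local RNG stream. Each generator passes its
# own `stream` name so substreams are independent: adding one generator never
# perturbs another's draws. Mersenne-Twister throughout.
local_stream_seed <- function(seed, stream, .local_envir = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  sub <- (as.double(seed) %% 2147483647) * 48271 + h
  withr::local_seed(as.integer(sub %% 2147483647), .local_envir = .local_envir)
}
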