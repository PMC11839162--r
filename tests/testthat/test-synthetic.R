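test_that("localization generator is deterministic and respects the disk", {
  spec <- nucleus_sim_spec(n_localizations = 1, localization_precision_nm = 0)
  one <- simulate_localizations(spec, seed = 3)
  expect_equal(nrow(one$locs), 1L)
  expect_lte(sqrt(one$locs$x_nm^2 + one$locs$y_nm^2), spec$nucleus_radius_nm)

  a <- simulate_localizations(nucleus_sim_spec(), seed = 9)
  b <- simulate_localizations(nucleus_sim_spec(), seed = 9)
  expect_identical(a, b)
  c <- simulate_localizations(nucleus_sim_spec(), seed = 10)
  expect_false(identical(a$locs, c$locs))

  expect_warning(
    nucleus_sim_spec(cluster_sigma_nm = 4000, nucleus_radius_nm = 3000),
    "uniform"
  )
})

test_that("clustered_fraction = 0 gives complete spatial randomness", {
  spec <- nucleus_sim_spec(n_localizations = 2000, clustered_fraction = 0)
  pvals <- vapply(1:20, function(s) {
    sim <- simulate_localizations(spec, seed = s)
    oracle_quadrat_csr_p(sim$locs$x_nm, sim$locs$y_nm, spec$nucleus_radius_nm)
  }, numeric(1))
  # at alpha = 0.01 per seed, allow at most one chance rejection in 20
  expect_gte(sum(pvals > 0.01), 19L)
})

test_that("clustered patterns are rejected by the same CSR test", {
  spec <- nucleus_sim_spec(n_localizations = 2000, clustered_fraction = 0.8)
  sim <- simulate_localizations(spec, seed = 1)
  p <- oracle_quadrat_csr_p(sim$locs$x_nm, sim$locs$y_nm, spec$nucleus_radius_nm)
  expect_lt(p, 1e-6)
})

test_that("foci image generator honours k, separation and overlap", {
  spec <- foci_image_spec(k_foci = 5, focus_radius_um = 1.0)
  sim <- simulate_foci_image(spec, seed = 4)
  tr <- sim$truth
  expect_equal(nrow(tr$centers_ch1_um), 5L)
  d <- as.matrix(dist(tr$centers_ch1_um))
  expect_true(all(d[upper.tri(d)] >= 2 * spec$focus_radius_um))

  # k = 0 leaves a pure-background channel: no pixel near the focus level,
  # and zero foci at a threshold above the background noise
  empty <- simulate_foci_image(foci_image_spec(k_foci = 0), seed = 5)
  expect_equal(nrow(empty$truth$centers_ch1_um), 0L)
  bg <- empty$truth$spec$background_mean
  lab <- segment_foci(empty$stack$channels$ch1, empty$mask,
    method = "absolute", threshold = bg + 6 * sqrt(bg)
  )
  expect_equal(max(lab), 0L)

  # full overlap with no noise: channel masks identical above threshold
  clean <- simulate_foci_image(
    foci_image_spec(
      k_foci = 4, channel_overlap = 1, noise_model = "gaussian",
      read_noise_sd = 0
    ),
    seed = 6
  )
  expect_identical(
    clean$stack$channels$ch1 > clean$truth$spec$background_mean,
    clean$stack$channels$ch2 > clean$truth$spec$background_mean
  )

  # impossible packing is a typed error
  expect_error(
    simulate_foci_image(foci_image_spec(k_foci = 200), seed = 1),
    "achievable maximum"
  )
})

test_that("gfp field reproduces levels and preserves brightness ranking", {
  specs <- list(
    nucleus_sim_spec(gfp_level = 10),
    nucleus_sim_spec(gfp_level = 100)
  )
  noiseless <- simulate_gfp_field(specs, seed = 1,
    read_noise_sd = 0, poisson = FALSE
  )
  sc <- measure_nuclei(noiseless$stack$channels$gfp, noiseless$masks)
  expect_equal(sc$mean_adu, c(10, 100))

  # ranking matches gfp_level at SNR >= 10 for 10 nuclei
  lv <- seq(100, 1000, by = 100)
  specs10 <- lapply(sample(lv), function(g) nucleus_sim_spec(gfp_level = g))
  field <- simulate_gfp_field(specs10, seed = 2)
  sc10 <- measure_nuclei(field$stack$channels$gfp, field$masks)
  expect_equal(
    rank(sc10$mean_adu),
    rank(vapply(specs10, `[[`, numeric(1), "gfp_level"))
  )
})

test_that("chromatome generator matches its negative-binomial spec", {
  # flat spec: expected log2FC to control ~ log2(21/11), mean abs deviation small
  spec <- chromatome_sim_spec(
    n_proteins = 500L,
    replicates = c(minusEdU = 5L, Luc = 5L, `2Cneg` = 5L, `2Cpos` = 5L),
    baseline_mean = 20, minus_edu_mean = 20, dispersion = 0.1
  )
  sim <- simulate_chromatome(spec, seed = 21)
  fc <- log2fc_to_control(sim$table, "Luc")
  expect_lt(abs(mean(fc$log2fc)), 0.1)

  # empirical moments: mean within standard error at n >= 1e4 draws
  x <- sim$table$psm[sim$table$condition == "Luc"]
  se <- sqrt((20 + 0.1 * 400) / length(x))
  expect_lt(abs(mean(x) - 20), 4 * se)

  expect_identical(
    simulate_chromatome(spec, seed = 5)$table,
    simulate_chromatome(spec, seed = 5)$table
  )
  expect_error(
    chromatome_sim_spec(replicates = c(minusEdU = 0L, Luc = 1L, `2Cneg` = 1L, `2Cpos` = 1L)),
    "replicate"
  )
})

test_that("generator substreams are independent", {
  # drawing a foci image between two localization calls must not change them
  a <- simulate_localizations(nucleus_sim_spec(), seed = 13)
  invisible(simulate_foci_image(foci_image_spec(), seed = 13))
  b <- simulate_localizations(nucleus_sim_spec(), seed = 13)
  expect_identical(a, b)
})
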