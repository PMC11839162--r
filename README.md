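# chromquant

Quantitative analyses of heterochromatin remodeling in the reversible
transition between mouse embryonic stem cells (ESCs) and the
totipotent-like **2C state**. Entry into the 2C-like state (marked by a
MERVL::EGFP reporter, "2C⁺") reorganizes constitutive heterochromatin:
H3K9me3-marked chromocenters become fewer and larger, and global DNA
compaction drops. `chromquant` implements the measurements behind those
statements for researchers analyzing super-resolution DNA images,
immunofluorescence stacks, and chromatin-bound proteome (chromatome)
tables — plus seeded synthetic-data generators with ground truth so every
estimator can be validated by parameter recovery.

## What it computes

* **Voronoi DNA compaction** — from a STORM localization list, one Voronoi
  polygon per localization; local density δᵢ = 1/areaᵢ (nm⁻²); per-nucleus
  compaction = mean δᵢ. Cells are clipped to the nucleus region (areas sum
  exactly to the region area) or border cells dropped. Density-map
  rendering grades polygons in log₁₀ δ between 10⁻⁴ and 10⁻² nm⁻², with
  the largest 0.5% blacked out.
* **GFP scoring and 2C classification** — mean ADU per nucleus, cohort
  min–max normalization onto [0, 1], 2C⁺ iff score > 0.2 (strict).
* **Chromocenter foci** — max-projection, optional Gaussian blur (σ = 0.5
  px), Otsu-in-mask or absolute thresholding, 8-connected components,
  per-focus area (µm²)/intensity/centroid and per-nucleus counts.
* **Manders colocalization** — M1 = Σ ch1 over (ch2 > t₂) / Σ ch1 within
  the nucleus mask, and symmetrically M2; threshold-0 or Otsu auto mode.
* **Chromatome enrichment** — from PSM counts (protein × condition ×
  replicate; conditions −EdU, Luc, 2C⁻, 2C⁺): log₂ FC to the −EdU
  control, pairwise condition folds, average enrichment per condition,
  FC ≥ 2 selection, Venn decomposition of the three capture conditions,
  log₂FC ranking, and replicate QC (Pearson matrix, low-yield flags).
* **Reporting statistics** — ANOVA (Tukey/Dunnett), Student's t,
  per-stratum Welch t, Mann–Whitney, Fisher's exact; fold summaries
  rounded half-up to one decimal.

Results are tibbles designed for piping; fitted objects have
`tidy()`/`glance()` methods and `plot_*()`/`autoplot()` figures.

## Worked example

Simulate a six-nucleus cohort (four compact "2C⁻"-like, two decompacted
"2C⁺"-like), tessellate, and join GFP scores:

```r
library(chromquant)

cf <- c(0.8, 0.8, 0.8, 0.8, 0.3, 0.3)            # clustered fraction per nucleus
locs <- dplyr::bind_rows(lapply(seq_along(cf), function(i) {
  simulate_localizations(
    nucleus_sim_spec(n_localizations = 600, clustered_fraction = cf[i]),
    seed = i, nucleus_id = paste0("n", i)
  )$locs
}))
gfp <- tibble::tibble(
  nucleus_id = paste0("n", 1:6),
  gfp_score  = c(0.05, 0.10, 0.00, 0.15, 0.60, 1.00)
)
compaction_table(locs, gfp)
#> # A tibble: 6 × 4
#>   nucleus_id mean_density_nm2inv gfp_score two_c_class
#>   <chr>                    <dbl>     <dbl> <fct>
#> 1 n1                   0.000145       0.05 2Cneg
#> 2 n2                   0.000136       0.1  2Cneg
#> 3 n3                   0.000151       0    2Cneg
#> 4 n4                   0.000159       0.15 2Cneg
#> 5 n5                   0.0000432      0.6  2Cpos
#> 6 n6                   0.0000438      1    2Cpos
```

The decompacted, reporter-bright nuclei (n5, n6) show a ~3.4-fold lower
mean Voronoi density — the compaction contrast the biaxial plot
(`plot_compaction()`) displays. Chromocenter counting on a synthetic
nucleus with 9 true foci of radius 0.8 µm:

```r
sim <- simulate_foci_image(foci_image_spec(k_foci = 9), seed = 2)
lab <- segment_foci(sim$stack$channels$ch1, sim$mask)
foci_count(foci_stats(lab, sim$stack$channels$ch1, 0.1))
#> # A tibble: 1 × 4
#>   nucleus_id n_foci mean_area_um2 total_area_um2
#>   <chr>       <int>         <dbl>          <dbl>
#> 1 n1              9          2.03           18.3
```

All 9 foci are recovered; the mean measured area (2.03 µm²) matches the
true disk area π·0.8² ≈ 2.01 µm². Fold summaries reproduce the reporting
convention for group means — e.g. ESCs average 8.88 H3K9me3 foci/nucleus
against 3.89 in 2C⁺ cells:

```r
fold_summary(8.88, 3.89)
#> # A tibble: 1 × 2
#>   fold_raw fold_rounded
#>      <dbl>        <dbl>
#> 1     2.28          2.3
```

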