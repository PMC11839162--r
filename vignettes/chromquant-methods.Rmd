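---
title: "Methods: quantifying heterochromatin remodeling in the 2C-like transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying heterochromatin remodeling in the 2C-like transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromquant)
```

Mouse embryonic stem cell (ESC) cultures contain a rare, transient
subpopulation that re-expresses 2-cell-embryo genes (MERVL reporter
positive, "2C⁺"). Entry into this 2C-like state comes with a striking
reorganization of constitutive heterochromatin: chromocenters — the
H3K9me3-dense clusters of pericentromeric repeats — become fewer and
larger, and global DNA compaction decreases. `chromquant` implements the
quantitative analyses used to measure these changes, each paired with a
seeded synthetic-data generator that carries ground truth, so every
estimator in the package can be validated by parameter recovery rather
than by eye.

## Voronoi density analysis of localization data

STORM imaging of labeled DNA yields a list of (x, y) fluorophore
localizations per nucleus (nm units; localization precision about 20 nm).
`voronoi_tessellate()` partitions the plane into one Voronoi polygon per
localization; the *local density* of a polygon is the inverse of its area
(nm⁻²), and the per-nucleus arithmetic mean of these densities
(`mean_voronoi_density()`) summarizes global DNA compaction. Compact
chromatin packs localizations tightly, giving small polygons and high mean
density.

Border cells of a raw Voronoi diagram are unbounded, so a boundary policy
is required:

* **clip** (default): every cell, including unbounded ones, is intersected
  with a clip region (the convex hull of the nucleus's localizations when
  no region is given, dilated by a relative 1e-9 so hull sites are interior
  to it). Retained areas then sum exactly to the region area, which the
  test suite exploits as a conservation check.
* **drop_boundary**: cells whose *raw* region is unbounded are discarded.
  A Voronoi cell is unbounded exactly when its site lies on the convex
  hull of the point set, so the hull membership decides the drop. Bounded
  cells are recovered inside an enclosing frame that is pushed outward
  until no retained cell touches it (cell vertices are Delaunay
  circumcenters and can lie far outside the data, so a fixed frame is not
  safe).

The tessellation geometry itself is delegated to the `deldir` engine, with
cells crossing the region boundary clipped by Sutherland–Hodgman against
convex regions; non-convex simple polygons fall back to
`spatstat.geom::dirichlet()`, which handles arbitrary polygonal windows.
The test suite checks both routes against an independently written O(n²)
half-plane-intersection oracle (each cell is the intersection, over all
other sites, of the nearer half-plane with the region) at 1e-8 relative
tolerance.

Exact duplicate coordinates would create zero-area cells and are removed
before tessellation with a message; each retained localization then owns
exactly one cell, so averaging over polygons and over localizations
coincide.

For rendering (`render_density()`), the `ceiling(0.005 · n)` largest
polygons per nucleus are blacked out (area ties broken by localization
index for determinism), densities ≥ 0.01 nm⁻² are clamped to the
high/"yellow" end, densities ≤ 1e-4 nm⁻² to the low/"blue" end, and
intermediate cells are graded linearly in log₁₀ density between those two
bounds. The bounds are the two stated endpoints of the color code; the
log-linear interpolation between them is the package's choice, since only
the endpoints are fixed.

## GFP scoring and 2C classification

Nuclei are scored from conventional GFP images: `mean_adu()` is the summed
ADU count inside the nucleus mask divided by the number of mask pixels,
and `normalize_scores()` maps a cohort's mean intensities onto [0, 1] by
min–max normalization (dimmest nucleus 0, brightest 1). Scores are
therefore *cohort-relative*: they are comparable only within one imaging
batch, and `score_gfp_field()` stamps a batch id on its output. A
degenerate all-equal cohort (including a single nucleus) scores 0
everywhere. No outlier exclusion is applied before normalization.
`classify_2c()` calls a nucleus 2C-positive when its score strictly
exceeds the threshold (default 0.2); a score exactly at the threshold is
negative. `compaction_table()` joins mean Voronoi density, GFP score, and
class per nucleus — the record behind the biaxial compaction-vs-reporter
plot (`plot_compaction()`).

## Chromocenter foci quantification

Immunofluorescence z-stacks are max-projected (`max_project()`) before any
2D quantification, matching how such images are routinely analyzed; no 3D
mode is provided. `segment_foci()` thresholds within the nucleus mask —
Otsu's method on the masked pixels by default, because the original
object-counting threshold of such workflows is typically manual and
unreported; an absolute threshold is exposed for sensitivity analysis and
the threshold used is recorded on the result. Supra-threshold pixels are
labeled as 8-connected components in deterministic raster-scan order, and
components smaller than `min_area_px` (default 4) are removed to suppress
single-pixel noise. `foci_stats()` reports per-focus area
(pixel count × pixel area, µm²), mean intensity, and centroid;
`foci_count()` aggregates per nucleus. Counts and labels are invariant
under affine intensity rescaling with the Otsu threshold, since the
threshold covaries.

Gaussian blurring (`blur()`, σ in pixels, default 0.5 for the SMARCAD1
channel before colocalization) goes through `EBImage::gblur`; σ = 0 is the
identity. Foci metrics are computed on raw channels by default — blur is
applied only where a workflow states it.

For embryo-style images, `normalized_nuclear_intensity()` divides the mean
nuclear signal by the mean of a mask-disjoint square background box ("the
average cytoplasmic signal"). The box is auto-placed as the nearest
mask-disjoint square of equivalent area to the nucleus centroid, or given
manually; a warning is raised when the box-to-mask area ratio leaves
[0.5, 2].

## Manders colocalization

`manders()` reports both coefficients within the nucleus mask: m1 is the
fraction of channel-1 intensity in pixels where channel 2 exceeds its
threshold, m2 the converse. Since workflows often report a single
unspecified "Manders' coefficient", both are always returned. Thresholds
default to 0 (all strictly positive signal counts) with a per-channel
Otsu-within-mask auto mode; the thresholds used are recorded in the
output. Manders coefficients are invariant to positive rescaling of the
quantified channel, which is why they are preferred when channel
intensities are not calibrated against each other. A channel with zero
total intensity in the mask yields `NA` with the reason in a `note`
column.

## Chromatome enrichment

iPOTD-style experiments capture EdU-labeled genomic DNA and identify
chromatin-bound proteins by mass spectrometry, quantified as PSM counts
per protein × condition × replicate across four conditions: the no-capture
background control (`minusEdU`), a luciferase control population (`Luc`),
and MERVL-reporter-sorted `2Cneg` and `2Cpos` populations.

Replicates are aggregated by their mean (median optional) before any
ratio. With pseudocount ε (default 1, to keep zero detections defined):

* `log2fc_to_control()`: log₂((mean_cond + ε) / (mean_minusEdU + ε));
* `pairwise_enrichment()`: (mean_A + ε) / (mean_B + ε);
* `average_enrichment()`: the per-protein summary of a condition's
  pairwise folds against the other capture conditions;
* selection: a protein is *enriched* in a condition when its average
  enrichment is ≥ the fold-change cutoff (default 2), and
  `select_and_venn()` decomposes the three selection flags into the 7 Venn
  regions plus the unselected remainder. The `Luc&2Cneg` region — enriched
  in both chromocenter-containing populations but not in 2C⁺ — is the
  candidate set for chromocenter-maintenance factors.

The averaging mode deserves a note. For a protein enriched in *both* Luc
and 2Cneg, one of its two pairwise folds (Luc vs 2Cneg) is ≈ 1 by
construction; only the fold against 2Cpos carries the signal. The
geometric mean of {1, 8} is 2.83, barely above a cutoff of 2, so under
realistic between-replicate dispersion a geometric-mean selection misses a
large fraction of genuinely shared proteins. The arithmetic mean of the
linear folds ({1, 8} → 4.5) keeps shared proteins clearly above the
cutoff and is therefore the default; the geometric mode (scale-consistent
for ratios, equivalent to averaging log folds) remains available as
`mode = "geometric"` and the mode used is recorded on the result. This
package implements only this downstream average-enrichment/FC-cutoff/
overlap procedure; probabilistic interactor scoring (SAINT) is an external
step that published candidate lists may additionally reflect.

`replicate_qc()` computes Pearson correlations of per-protein PSM counts
between all replicate pairs and flags replicates whose total PSM count
falls below a configurable fraction (default 0.5) of their condition's
median — the signature of a failed capture run that warrants exclusion.

`rank_proteins()` orders a condition's proteins by log₂ fold change to the
control, ties broken lexicographically by protein id so rankings are
deterministic.

## Reporting statistics

`group_compare()` wraps the standard tests used in per-nucleus/per-focus
comparisons: one-way ANOVA with Tukey or Dunnett post-hoc adjustment,
unpaired two-tailed Student's t-test (equal-variance, matching the named
test), per-stratum Welch t-tests (unadjusted by default, with any
`p.adjust` method optional), Mann–Whitney, and Fisher's exact test for
2×2 tables. All are delegated to base R and `multcomp`; the suite checks
them against enumeration (hypergeometric) and permutation oracles.
`fold_summary()` reports group-mean ratios raw and rounded half-up to one
decimal — the convention behind in-text statements like "2.3-fold fewer
foci" (8.88/3.89 = 2.28 → 2.3) and "2.4-fold larger area" (4.76/1.99 =
2.39 → 2.4).

## Synthetic data and what it does (not) show

Each generator is a pure function of (spec, seed). One PRNG algorithm
(Mersenne-Twister) is used throughout, with a named substream per
generator derived from the user seed, so adding one generator never
perturbs another's draws.

* `simulate_localizations()` draws a fraction `clustered_fraction` of
  points from isotropic Gaussian clusters (default 60 clusters of σ =
  60 nm) centred uniformly in a disk nucleus (default radius 3 µm), the
  remainder uniform, then adds i.i.d. Gaussian localization error
  (default sd 20 nm, the typical STORM fit precision). Compaction is thus
  parameterized by a single number: high clustered fraction mimics
  compact pluripotent-like chromatin, low values the decompacted 2C⁺
  state. Cluster size and count are synthetic choices — localization data
  at STORM resolution do not come with published cluster-size priors — so
  recovered *contrasts* (ordering, cohort separation), not absolute
  density values, are the meaningful outputs.
* `simulate_foci_image()` renders disk-shaped foci (default radius 0.8 µm,
  amplitude 400 over a background of 20) inside an elliptical nucleus
  mask, with Poisson shot noise plus additive Gaussian read noise
  (sd 3) — the standard fluorescence camera model. Centres are
  rejection-sampled to keep an edge-to-edge gap of at least `min_gap_um`
  (default 0.3 µm), making foci well-separated by construction so that
  8-connected segmentation cannot bridge two foci through a noise pixel.
  A second channel shares a `channel_overlap` fraction of centres for
  colocalization tests. No PSF rendering, drift, or photoblinking
  kinetics are simulated.
* `simulate_gfp_field()` fills non-overlapping elliptical nuclei with
  their `gfp_level` plus noise, so the expected mean ADU ordering equals
  the ground-truth level ordering.
* `simulate_chromatome()` draws negative-binomial PSM counts (variance
  μ + φμ², default dispersion φ = 0.3) with condition means =
  baseline × spike fold for the capture conditions and a lower background
  mean for `minusEdU`; defaults are 500 proteins, baseline mean 20,
  background 10, and replicates (3, 4, 4, 3) for (minusEdU, Luc, 2Cneg,
  2Cpos).

Passing recovery tests on these generators demonstrates that the
*estimators* are correct and well-behaved under a plausible noise model at
the study's sample sizes (23 vs 12 nuclei for the compaction cohorts,
foci counts of 3–12 per nucleus, 500-protein tables with 40 spiked
proteins over 100 simulated experiments). It does not certify performance
on real microscopy or MS data, whose artifacts (uneven illumination,
optical sectioning, bleed-through, peptide-level biases, shared-peptide
protein inference) are deliberately out of the generators' scope.

## Numerical choices and problem sizes

Geometry is computed in double precision; the area-conservation identity
(Σ cell areas = clip-region area) holds to better than 1e-6 relative and
the half-plane oracle agreement to 1e-8 relative at n ≤ 200. Degenerate
inputs (< 3 distinct points, all-collinear points, empty masks, zero
background means) raise typed errors rather than producing silent
results. The validation suites run at deliberately desk-sized problems —
600–2000 localizations per nucleus, 10 seeds for ordering properties,
128×128 px images over a 3–12 foci grid, 100 simulated chromatome
experiments — chosen as the smallest sizes at which the tested
statistical contrasts are unambiguous.

## Known limitations

2D analysis only (tessellation and foci metrics are planar); no drift
correction or raw STORM frame processing (the pipeline starts from
localization lists); nucleus masks are inputs, mirroring manual selection,
not computed; no watershed splitting of touching foci; chromatome analysis
works on supplied PSM counts and does not perform spectral search, protein
inference, or PSM-level FDR control.
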