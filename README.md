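# itfprofiler

Quantitative profiling of the **invasive tumor front (ITF)** — the zone
where a tumor invades adjacent normal tissue — for digital-pathology and
epigenomics workflows. The package is aimed at computational pathology
groups studying stromal remodelling (reticulin/collagen scaffolding),
immune infiltration and DNA-methylation drift at the front, and at anyone
who needs a fully synthetic, ground-truthed benchmark for such pipelines.

It implements four analysis arms behind one tidyverse-style interface
(data frames in, tibbles out; `tidy()`/`glance()`/`autoplot()` on fitted
objects):

- **Reticulin fiber morphometry** on Gomori silver-stained tiles:
  Beer–Lambert stain unmixing, probabilistic fiber segmentation
  (multiscale ridge enhancement + two-component Gaussian mixture +
  hysteresis on the fiber posterior), and a fifteen-parameter suite per
  region — sizes (area, width as twice the mean medial-axis distance,
  height as the maximum Feret diameter, Crofton perimeter), a dispersion
  index *deformity* = R_g(fiber) / R_g(equal-area disk) (disk ⇒ 1), shape
  (roundness 4A/πh², moment-ellipse aspect ratio, perimeter ratio,
  shape factor 4πA/P², Douglas–Peucker vertex count, box-counting fractal
  dimension of the skeleton), plus fiber density (fibers/mm² of tissue)
  and percent stained area (%SA).
- **Multiplex immunofluorescence profiling** (DAPI, CD3, CD8, CD20, CD68,
  CD66b): deterministic nucleus detection, perinuclear-ring marker gating,
  the standard panel logic (CD3⁺CD8⁺ → CD8 T, CD3⁺CD8⁻ → CD4 T, CD20⁺ →
  B cell, CD68⁺ → macrophage, CD66b⁺ → neutrophil, all-negative →
  "other"), densities in cells/mm², and TTF1⁺ nucleus density.
- **Infinium-style differential methylation**: β = M/(M+U), Greedycut
  detection-quality filtering, SNP/cross-reactive blacklist removal,
  probe-type quantile normalisation, per-CpG paired/two-group linear
  models with Benjamini–Hochberg FDR (significant: p < 0.05 and
  FDR < 0.05), Δβ sign convention "positive = hypermethylated in the
  first-named group", CpG island/shore(≤2 kb)/shelf(2–4 kb)/open-sea
  annotation, top-k signature clustering and PCA.
- **Cohort statistics**: 5 × 4 mm parent regions tiled into 1 × 1 mm
  tumor / target-tissue / ITF categories by tumor fraction, Student
  t-test comparisons and a significance matrix whose cells print the
  higher group plus stars (`ITF*`, `T**`, …).

A first-class **synthetic-data generator** (seeded, byte-reproducible)
creates fiber tiles with exact pixel ground truth, multichannel cell
images with planted phenotype densities, and paired EPIC-like intensity
matrices with planted Δβ effects — so every stage of the pipeline is
testable offline.

## Worked example

Simulate a loose-plexus fiber tile, segment it, and summarise the region:

```r
library(itfprofiler)

p   <- fiber_preset("loose_plexus", seed = 42)
sim <- simulate_fiber_roi(p)
od  <- deconvolve_stain(sim$image, pixel_size_um = p$pixel_size_um)
tis <- compute_tissue_mask(sim$image, pixel_size_um = p$pixel_size_um)
seg <- segment_fibers(od, tissue_mask = tis$mask)
summarize_roi(seg, tis) |>
  dplyr::select(n_fibers, tissue_area_mm2, density, pct_stained_area,
                mean_roundness, mean_deformity)
#> # A tibble: 1 × 6
#>   n_fibers tissue_area_mm2 density pct_stained_area mean_roundness
#>      <int>           <dbl>   <dbl>            <dbl>          <dbl>
#> 1       46          0.0624    737.             7.97         0.0428
#>   mean_deformity
#>            <dbl>
#> 1           4.41
```

46 fibers were recovered on the 0.25 × 0.25 mm tile (49 planted), at
737 fibers/mm² of tissue covering 8.0% of the tissue area; the low mean
roundness (0.043) and high deformity (4.4) are the signature of a loose,
spatially extended network — the dense-bundle preset scores roundness
roughly three times higher.

Differential methylation on a paired simulation (6 primary/metastasis
pairs, 10,000 probes, 50 planted Δβ = +0.4 effects):

```r
ms  <- simulate_methylation(meth_sim_params(seed = 1))
bm  <- compute_beta(ms$M, ms$U)
fit <- test_dm(bm, ms$samples, design = "paired",
               group_a = "LM", group_b = "P")
fit
#> Differential methylation fit (paired design): LM vs P
#>   probes tested: 10000 (excluded: 0)
#>   significant at p<0.05 & FDR<0.05: 47
dplyr::arrange(tidy(fit), p) |> head(3)
#> # A tibble: 3 × 8
#>   probe_id   delta_beta statistic    df         p     fdr significant degenerate
#>   <chr>           <dbl>     <dbl> <dbl>     <dbl>   <dbl> <lgl>       <lgl>
#> 1 cg00004686      0.418      60.1     5   2.40e-8 2.40e-4 TRUE        FALSE
#> 2 cg00007314      0.417      34.7     5   3.76e-7 1.72e-3 TRUE        FALSE
#> 3 cg00002006      0.452      31.8     5   5.78e-7 1.72e-3 TRUE        FALSE
```

47 of the 50 planted probes are recovered at FDR < 0.05 with Δβ estimates
close to the planted +0.4. `autoplot(fit)` draws the volcano,
`build_signature(fit, bm, k = 1000)` the clustered signature, and
`pca_beta(bm)` the sample-level PCA.

The end-to-end demonstration (layout → fibers → immunofluorescence →
methylation → comparison matrix) runs with
`run_pipeline(pipeline_config(seed = 1, out_dir = "out"))`, writing
per-stage CSVs and a JSON run manifest whose hash is identical across
reruns with the same seed. A thin command-line wrapper is installed at
`inst/scripts/itfprofiler` (`itfprofiler run|simulate …`).

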