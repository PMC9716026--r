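---
title: "Methods: quantitative profiling of the invasive tumor front"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative profiling of the invasive tumor front}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and rationale

The invasive tumor front (ITF) — the zone where tumor invades adjacent
normal tissue — is where extracellular-matrix remodelling
(stromatogenesis), immune exclusion and epigenetic drift are most visible.
`itfprofiler` implements the three measurement arms used to characterise
this zone and the statistical reporting that ties them together:

1. **Reticulin fiber morphometry** on Gomori silver-stained tiles: fiber
   segmentation and a fifteen-parameter suite — four sizes (area, width,
   height, perimeter), a dispersion index ("deformity"), six shape
   parameters (roundness, aspect ratio, perimeter ratio, shape factor,
   vertices, fractal dimension), plus two region-level quantities (fiber
   density per mm^2 and percent stained area, %SA).
2. **Multiplex-immunofluorescence immune profiling** (DAPI, CD3, CD8,
   CD20, CD68, CD66b): nucleus detection, marker gating, phenotype
   assignment and densities in cells/mm^2, plus TTF1-positive nucleus
   density for lung tissue.
3. **Infinium-style differential methylation**: beta values
   `M/(M + U)`, Greedycut quality filtering, blacklist removal, probe-type
   normalisation, per-CpG tests with Benjamini–Hochberg FDR, Δβ
   signatures, CpG island/shore/shelf context annotation, clustering and
   PCA.

A fourth component, the **synthetic-data generator**, produces
ground-truthed inputs with the statistical structure each stage assumes, so
the full pipeline is verifiable without any external download.

Region design follows the study layout: a 5 × 4 mm parent region over the
front is tiled into twenty 1 × 1 mm tiles, each labelled *tumor*,
*target tissue* (myometrium or lung), or *ITF* from its tumor fraction.

## The synthetic tiles: what they emulate, and what they do not

### Fiber tiles

Fibers are random-walk polylines: a base orientation, then per-step turning
angles drawn `Normal(0, curliness)`; the stroke is a disk of the fiber's
width swept along the path. This reproduces the two phenotypes the
morphometry must distinguish: a *loose plexus* (isotropic orientations,
curly, long thin fibers) and *dense bundles* (orientations concentrated
around a dominant direction with a bundled fraction snapped to it; short,
straight, thicker fibers). The preset construction fixes the expected
contrast direction: compact bundles score **higher** roundness
(`4A/(pi * height^2)`) than the spread-out loose plexus, whose fibers reach
further in space — the loose-network phenotype is the low-roundness one.

Base orientations for `orientation_kappa > 0` use a wrapped
`Normal(theta0, 1/sqrt(kappa))` — a standard small-dispersion approximation
of a von Mises distribution, adequate here because only the
aligned-vs-isotropic contrast matters.

The image model is two-stain Beer–Lambert: a near-neutral silver absorbance
vector for fibers and an eosin-like pink counterstain over tissue, with
additive optical-density noise and optional circular tissue holes (holes
scale with the tile so the requested hole fraction is met closely). Default
resolution is the scanner's 0.46 um/pixel; a 0.25 × 0.25 mm preset tile
keeps a full simulate–segment–measure cycle fast, and all geometry is
computed in physical units so tile size is immaterial to the descriptors.

Not emulated: scanner point-spread blur, stain heterogeneity along a
fiber, fiber branching, and out-of-focus tissue. Segmentation recall
measured on these tiles is therefore an upper bound on real-slide
performance; the descriptor definitions and their oracle tests are
unaffected by this gap.

### Immunofluorescence tiles

Cell counts are Poisson(density × area) per phenotype; each cell gets a
DAPI nucleus disk and marker signal on a 2 um perinuclear ring for the
channels its phenotype expresses (CD8 T: CD3+CD8; CD4 T: CD3; B cell:
CD20; macrophage: CD68; neutrophil: CD66b; "other": DAPI only). Cells are
placed without overlap, so ring measurements are unmixed and the marker
logic can be verified exactly. Default pixel size is 1.0 um — coarser than
a Vectra-class scanner, keeping a six-channel 1 mm^2 tile at ~48 MB while
leaving nuclei ~7 px across, ample for blob detection. Not emulated:
spectral bleed-through, touching/overlapping nuclei, autofluorescence —
hence phenotyping accuracy on these tiles exceeds what trained classifiers
achieve on real panels.

### Methylation matrices

Per observation a true beta is drawn from a three-component mixture
(unmethylated/intermediate/methylated, the canonical bimodal-plus-shoulder
shape), shifted by the planted signed Δβ in the first group, perturbed by
`Normal(0, noise_sd)` and clamped inside (0, 1). Total intensity is a
scaled Gamma draw split as `M = T*beta`, `U = T*(1-beta)`: intensities are
strictly positive and the implied `M/(M+U)` equals the noisy beta exactly,
which is what makes the generator its own oracle. An optional compression
of type II betas toward 0.5 emulates the probe-design bias the
normalisation step corrects. Desk-scale default is 10,000 probes and 6
pairs; array-scale runs only change `n_probes`.

## Fiber morphometry

### Stain separation and tissue mask

RGB is converted to optical density (`-log10` of transmittance, intensity
floor 1e-3) and unmixed by per-pixel least squares onto a two-vector stain
basis; the silver component feeds segmentation. Default vectors are shipped
and overridable — stain vectors are scanner- and batch-specific and should
be re-estimated for real material. The tissue mask keeps pixels with
appreciable channel-mean OD (default threshold 0.04), cleaned by a 5-px
morphological closing and opening; density and %SA are always computed
over tissue area, not tile area.

### Probabilistic segmentation

The silver OD map is enhanced as the pointwise maximum of the raw OD and a
multiscale tubeness (most-negative Hessian eigenvalue of
Gaussian-smoothed OD, scale-normalised, over sigmas matched to fiber
half-widths, default 0.5 and 1 um). Taking the maximum with the *raw* map
rather than a smoothed copy keeps stroke edges sharp: a blur halo around
thin fibers would otherwise be classified as fiber, thickening and merging
them. A two-component Gaussian mixture (background vs fiber) is fitted to
the enhanced values by EM with deterministic percentile initialisation
(medians at the 50th and 99.5th percentiles; no random restarts, so
identical inputs give identical labels). The per-pixel fiber posterior is
thresholded with hysteresis — components of the 0.5 level set are kept
only if they contain a 0.9-posterior pixel — and components under 5 um^2
are dropped. A collapsed mixture (constant map, or the two means merging)
returns zero fibers with a degeneracy flag instead of an error; the QC
stage turns that flag into an "unsatisfactory segmentation" exclusion.
Touching fibers are *not* split: a connected component is a fiber. This is
a documented bias at high fiber density and the main reason detected
counts can undershoot planted counts.

### Descriptor definitions

The descriptor names are standard but not self-defining; the package fixes
ImageJ-compatible conventions:

| parameter | definition | unit |
|---|---|---|
| area | pixel count × pixel area | um^2 |
| width | 2 × mean medial-axis distance over the skeleton (mean thickness) | um |
| height | maximum Feret diameter | um |
| perimeter | Crofton estimate from boundary intercepts in 4 directions | um |
| deformity | radius of gyration of the pixel set / that of an equal-area disk | – |
| roundness | `4·area / (pi·height^2)` | – |
| aspect ratio | major/minor axis of the moment-equivalent ellipse | – |
| perimeter ratio | perimeter / convex-hull perimeter (clamped ≥ 1) | – |
| shape factor | `4·pi·area / perimeter^2` (clamped ≤ 1) | – |
| vertices | Douglas–Peucker vertex count of the outer contour, ε = 2 px | count |
| fractal dimension | box-count slope on the skeleton, dyadic boxes 2–64 px | – |

Deformity is normalised so a disk scores exactly 1 — it reads directly as
"how much further the fiber's mass spreads from its centre than a compact
reference of the same area". The skeleton comes from Zhang–Suen thinning;
the distance map from the Euclidean distance transform. The Crofton
perimeter is exact in expectation on smooth convex shapes (disk error
well under 1%) but biased about −5 to −7% on axis-aligned rectangles; this
is the documented estimator tolerance used wherever a rectangle's
perimeter is asserted. `height` is taken as the Feret length (not the
bounding-box height), the natural reading for elongated fibers. All
descriptors are validated against closed forms and brute-force pixel
oracles on rasterized shapes, and all are scale-covariant: doubling the
pixel size doubles lengths, quadruples areas, and leaves shape parameters
unchanged.

### QC

A tile fails QC when the median channel-mean tissue OD is below 0.03
(insufficient staining — blank or washed-out tile), above 1.0 (excessive
staining — the segmentation has nothing to separate), or when the mixture
degenerated. Bounds were chosen from the simulator's nominal output
(~0.07 median OD for a counterstained tile) with wide margins; they are
plain configuration values for real material.

## Immune profiling

Nucleus detection is a classical deterministic substitute for a trained
StarDist model: Gaussian smoothing (1.5 um), Otsu threshold,
distance-transform watershed to split touching nuclei, 8 um^2 minimum
area. An Otsu split that lands inside pure background noise (foreground
fraction > 0.3) is treated as a blank channel. Membrane/cytoplasmic
markers are measured on a 2 um dilated ring around each nucleus; nuclear
signals (DAPI, TTF1) on the nucleus.

Positivity is per-channel Otsu by default (floored at 0.1 to guard
channels containing only background), overridable by absolute thresholds —
the published analysis used per-marker random-trees classifiers that are
not reproducible from text, so thresholds are the documented substitute.
Phenotype logic follows the panel definitions: CD3+CD8+ → CD8 T, CD3+CD8−
→ CD4 T, then CD20/CD68/CD66b in that precedence order, all-negative →
"other". The CD3 lineage always wins cross-lineage conflicts; the
precedence order is configurable but must stay a total order. Densities
are counts of in-polygon centroids over polygon area; the six phenotype
densities partition the total exactly.

## Differential methylation

Betas are the plain ratio `M/(M+U)` (offset 0 by default, matching the
printed formula; `M = U = 0` is missing, not an error). Greedycut removes,
iteratively, the probe or sample with the highest detection-failure
fraction (failure: detection p ≥ 0.01) until every remaining row and
column fails in at most 5% of entries; ties resolve probe-first, then
lowest index, so the filter is fully deterministic.

BMIQ itself is a published three-state beta-mixture method and is not
re-implemented; the default normalisation is a per-sample quantile mapping
of type II betas onto the type I distribution ("type2-quantile"), which
addresses the same probe-design bias and has an exactly testable defining
property (after mapping, type II sample quantiles coincide with type I
quantiles on the sample grid). `"none"` is available for data normalised
upstream.

Tests run on betas, not M-values, because effects are reported as Δβ on
the beta scale; the heteroskedasticity cost of that choice is accepted for
interpretability and noted here. The "hierarchical" model is realised as
the simplest fixed-effect per-probe linear model consistent with the
design: pair intercepts for paired data (algebraically the paired t-test
on within-pair differences) and the pooled two-sample t-test otherwise.
Δβ is `mean(group A) − mean(group B)` with group A named first (metastasis
vs primary by default), so positive Δβ means hypermethylated in the
first-named group. BH-FDR is computed across all tested probes;
"significant" requires both p < 0.05 and FDR < 0.05. Zero-residual-variance
probes get p = 1 when their effect is 0 (identical groups carry no
evidence) and are flagged `degenerate` when the effect is nonzero (perfect
separation — left to the analyst rather than silently assigned an
arbitrary p). Untestable probes (all-missing, < 2 complete pairs) are
excluded and logged.

Context annotation uses 1-based, both-ends-closed intervals: Island inside
an island, Shore within 2 kb of an edge, Shelf within 2–4 kb, open sea
beyond — the platform's standard convention; "bp from the edge" counts
`pos − end` (or `start − pos`), so 1,999 bp is Shore and 2,001 bp is
Shelf. Probes on chromosomes absent from the island set are returned
unannotated rather than guessed. Signatures take the top-k probes by
p-value among significant ones (the study's headline figure used
k = 10,000; requesting more than available uses all with a warning) and
cluster rows and columns by average-linkage on Euclidean distance with
`hclust`'s deterministic leaf order. PCA centres samples over probes,
imputes missing betas by probe means (count logged) and fixes signs so
each component's largest-magnitude loading is positive.

## Cohort statistics

Tiles are categorised from tumor fraction: tumor ≥ 0.9, target tissue
≤ 0.1, ITF within 0.5 ± 0.2, the rest unassigned and excluded — the source
design says only "approximately 50%", so the band widths are explicit,
configurable choices, and the constructor rejects overlapping bands.
Group comparison defaults to the pooled-variance Student t-test (the
literal reading of the reported method), with Welch and paired variants
exposed; two-sided p-values map to the reporting convention * < 0.05,
** < 0.01, *** < 0.001, and each significant cell shows the
higher-mean group's abbreviation (e.g. `ITF*`). No multiple-testing
correction is applied across parameters by default, matching the raw-star
reporting; a BH switch exists. Whether ROIs or cases are the unit of
analysis is ambiguous in per-ROI tables; the package tests per-ROI values
by default and `summarize_parameters()` supports aggregating to cases
first. Treating ROIs from the same case as independent inflates
significance — a known limitation, matching the source analysis rather
than correcting it (a mixed-effects extension is deliberately out of
scope).

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen to exercise every code path with comfortable margins:
0.25 mm fiber tiles with 50–90 fibers (10 seeds for recovery and
phenotype-contrast checks), one 1 mm^2 six-channel immunofluorescence tile
(~850 cells), and 10,000-probe × 6-pair methylation simulations (5–10
seeds). Every generator is byte-reproducible from its integer seed; the
pipeline derives per-stage seeds from one master seed, and two runs with
identical configuration produce identical run manifests (verified by
hashing the manifest JSON).

## Known limitations

- Connected components are fibers: heavily crossing networks undercount.
- Threshold gating is not a trained classifier; on real panels with
  bleed-through it will misclassify more than on synthetic tiles.
- Per-probe t-tests on betas are not a variance-moderated (limma-style)
  fit; at very small n, moderation would gain power.
- The type2-quantile normalisation assumes type I and II probes sample the
  same underlying beta distribution per sample; regional composition
  differences violate this mildly on real arrays, as they do for any
  marginal quantile method.
- Reported DMCpG counts from array-scale cohorts depend on pipeline and
  annotation versions that are not pinned down here; the package
  guarantees the statistical properties it tests (power, FDR control,
  estimator bias), not any specific published count.
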