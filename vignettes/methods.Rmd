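---
title: "Whole-slide versus hot-spot IHC quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-slide versus hot-spot IHC quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tumor-microenvironment biomarkers — endothelial CD31 for vascularization,
FOXP3 and CD8 for infiltrating T cells — are conventionally quantified by
*hot-spot analysis*: a pathologist selects a few small regions of maximal
marker density (here circles of 0.26 mm², three per section) and scores them
by micro-vessel density (MVD), Chalkley count, or stained-area fraction. This
convention comes from carcinomas, where vessels cluster into abundant,
well-defined hot spots. In morphologically heterogeneous tumors such as
osteosarcoma, hot spots may not represent the section at all: a marker can be
scattered diffusely, or concentrated in a few foci whose intensity has little
to do with the tumor's overall vascularization. `ihcquant` implements both
whole-slide and hot-spot quantification on calibrated RGB rasters, the cohort
statistics that compare them, and a synthetic slide generator with full
ground truth so that every stage of the pipeline can be validated without
patient material.

## Forward model: synthetic slides

### Spatial layout

Objects (vessel cross-sections or discrete cells) are placed by one of two
point processes on the tissue polygon (an ellipse inscribed in the canvas,
covering ~92% of each half-axis; the rest is bare glass):

* **homogeneous** — a Poisson process with the stated intensity (objects/mm²);
* **clustered** — a Thomas-type parent–offspring process: parents form a
  Poisson process (sampled on a buffered bounding box so boundary clusters
  enter without edge bias), each parent receives a Poisson number of
  offspring displaced by an isotropic Gaussian with sd `cluster_sigma`.

Two refinements make the clustered process behave like tissue rather than
like an abstract process. First, each cluster's offspring mean is scaled by a
unit-mean lognormal *strength* (`cluster_strength_cv`, default 0.8 for
vessels): individual hot spots vary in intensity independently of the slide's
overall abundance, which is precisely why a hot spot need not represent the
whole section. Second, vessel centres are thinned by a hard-core rule
(centres closer than 1.4× the sum of outer radii are dropped, in arrival
order): vessel cross-sections are disjoint anatomical structures separated by
at least a stromal cell width, and without this exclusion dense foci fuse
into single connected components under the merge-gap closing and vessel
counting becomes meaningless. The 1.4 factor keeps the minimum wall-to-wall
gap (≥12 µm) above the bridging range of the default 8 µm closing for all but
the smallest vessel pairs.

### Appearance

Vessels render as elliptical rings (elongation 1–1.8, wall 40% of the outer
radius, unstained lumen); with probability 0.3 a ring carries an arc gap
(10–25% of the circumference), emulating interruptions of the endothelial
lining by tissue tears or focally absent staining. Cells render as disks of
radius 9 µm — generous for a lymphocyte nucleus, deliberate at the package's
working resolutions (a disk must span a few pixels at 4–8 µm/px to be a
detectable object).

Color is composed by Beer–Lambert absorption. Each pixel's optical density is
`c_h·V_h + c_c·V_c`, where `V_h`, `V_c` are unit absorption vectors
(defaults: the published hematoxylin and red-chromogen/AEC calibration
vectors), `c_h` is the counterstain OD (0.3 ± 0.05 inside tissue), and `c_c`
is the chromogen OD of painted pixels, drawn per object from
`chromogen_od_range` (default 0.6–1.2) to emulate staining-intensity
variation. Transmitted 8-bit intensity per channel is
`background · 10^(−OD)` plus additive Gaussian scanner noise (sd 1.5
intensity steps).

The painted raster *is* the ground truth: objects are rasterized by even-odd
scanline filling of their polygons (pixel-centre rule), and
`true_area_fraction` is the painted-pixel count over the tissue-pixel count.
It is therefore exact by construction and invariant under re-rendering with
the same seed.

### Cohorts

A cohort plan fixes, per subject and marker, the pattern kind (exactly
`round(n × heterogeneous_fraction)` subjects clustered), a per-subject
abundance multiplier, and a render seed derived from one master seed by
multiplicative mixing modulo 2³¹−1, so any slide regenerates in isolation.
The defaults are the study conditions the package emulates:

| parameter | default | rationale |
|---|---|---|
| vessel marker clustered fraction | 0.85 | hot-spot-distributed vascularization in the large majority of specimens |
| FOXP3-like clustered fraction | 0.30 | homogeneous distribution in 70% of samples |
| CD8-like clustered fraction | 0.20 | homogeneous distribution in 80% of samples |
| vessel base intensity | 86 /mm² | calibrated once on generator truth (after hard-core thinning) so the default mixture's median whole-slide area fraction is ≈6.5%, the middle of the reported 1.17–12.77% range |
| FOXP3-like base intensity | 7.3 /mm² | 0.73 cells/0.1 mm², the reported cohort median |
| per-subject abundance multiplier | U(0.2, 1.9) | spans the reported between-patient dynamic range; without it all slides share one expected value and cross-slide correlations are undefined noise |
| cell-marker clusters | σ = 0.5 mm, 15–30 offspring, strength cv 0.3 | lymphocyte aggregates are diffuse and mild relative to vascular hot spots — the structural reason hot-spot analysis remains valid for these markers |

## Quantification pipeline

**Color deconvolution.** Per-channel OD is `−log10((I + 1/255)/255)` (the ε
avoids log 0); concentrations are the OD vector projected through the inverse
of the 3×3 stain matrix (counterstain, chromogen, and their normalized cross
product as residual). Negative concentrations — quantization noise outside
the stain simplex — are clipped to zero by default; `clip = FALSE` gives the
exact linear inversion, which recomposes the OD image to numerical precision.
Matrices with 2-norm condition number above 100 are rejected.

**Per-slide threshold.** Otsu's between-class-variance maximization over a
256-bin histogram of chromogen OD within tissue, subject to an OD floor
(default 0.15). The floor is the operative guard: on slides whose background
forms one tight mode near zero, the unfloored Otsu cut sits just above the
noise, and on degenerate (constant) histograms the floor itself is returned.
This reproduces "threshold optimized per section" as a deterministic,
oracle-testable rule. Whether to threshold in RGB or deconvolved OD space is
an open choice in conventional workflows; deconvolved OD is used here because
it is the space in which stains are additive.

**Immunoreactive mask.** `chromogen ≥ threshold` within tissue, then removal
of 8-connected components below `min_object_px` (default 8 px ≈ 128 µm² at
4 µm/px — sub-capillary debris). Components are labelled 8-connected;
EBImage's 4-connected first pass is merged across diagonal adjacencies by
union-find. Masks are monotone in the threshold by construction.

**Area fraction.** `100 · |mask ∩ ROI ∩ evaluable| / |ROI ∩ evaluable|`.

**Micro-vessel density.** Morphological closing with a disk of radius
`merge_gap_um` (default 8 µm, capillary-wall scale) bridges interrupted
walls, then 8-connected components whose centroid lies in the ROI are
counted. Centroid membership prevents double counting across adjacent hot
spots.

**Chalkley count.** A 25-dot graticule (dots sampled once in the unit disk
under a 0.18 minimum separation from a fixed layout seed, shipped as a
package constant) is scaled to the hot-spot field and placed at its centre;
the count is the maximum number of dots landing on mask-positive pixels over
a deterministic grid of 64 rotations × 9 small translations (jitter radius
10% of the field radius) — the digital analogue of the pathologist adjusting
the eyepiece graticule for maximal hits. A dot touches a vessel when its
nearest raster pixel is positive; no sub-pixel interpolation. Physical
graticule layouts vary between instruments and the original adjustment
protocol (rotate, translate, or both) is not standardized, so both motions
are searched and the grid sizes are configurable.

**Hot-spot selection.** The density field is the mask convolved with the
circular kernel of radius `sqrt(area/π)` (FFT convolution on a zero-padded
raster), evaluated on a stride grid (stride = radius/4) of candidate centres
whose circle lies ≥90% inside evaluable tissue (perimeter-artifact guard).
Greedy selection of k maxima with centre distance ≥ 2r; ties break by
row-major scan order; fully deterministic. Density-selected hot spots are by
construction at least as stained as the slide average — the selection-bias
mechanism that makes hot spots overestimate heterogeneous markers.

**Evident-hot-spot index.** Mean hot-spot area fraction over the whole-slide
fraction; `evident` when ≥ 2 (configurable). The human judgement "this
specimen has evident hot spots" has no published operationalization and the
reported 15% prevalence cannot be recomputed; under the default mixture the
index flags most clustered slides (ratios 4–18) and also some homogeneous
ones (extreme-order statistics of Poisson noise give ratios near 2 at these
intensities). The ratio distribution, not the binary flag, is the
informative output.

**Cell detection.** Threshold the chromogen map (default OD 0.3), label
8-connected blobs, keep areas within 100–2000 µm², merge centroids closer
than 25 µm by single-linkage (a merged group counts once), report centroids
in evaluable tissue. Densities are reported as cells per 0.1 mm² everywhere,
including CSV headers, to avoid unit drift. Semiquantitative categories
(low/intermediate/high) default to cohort tertiles with ties to the lower
category; fixed cut points are available for sensitivity analysis.

**Cohort statistics.** Slides with evaluable area strictly below 5 mm² are
marked excluded (never deleted). Pearson correlations with two-sided p from
the t-transform (n−2 df), significance at p < 0.05, no multiple-testing
correction (matching conventional practice; Holm adjustment can be applied by
the user). Interobserver variability is `|obs1 − obs2| / cohort mean × 100`
per slide, acceptable strictly below 10%; "compared to mean values" could
also mean the per-slide mean, so both normalizations are implemented
(`mean_mode`), cohort-mean default. Observers are simulated as pipeline runs
with a lognormal-jittered threshold and hot-spot centres displaced up to
150 µm, since the original observers were humans.

## What the generator does and does not emulate

It emulates: the homogeneous/clustered dichotomy and its mixture fractions;
between-subject abundance variation; per-object staining-intensity variation;
vessel anisotropy, lumina, and wall interruptions; additive scanner noise;
bare-glass background. It does **not** emulate: histological texture
(nuclear chromatin, stroma, necrosis), decalcification artifacts,
out-of-focus regions, stain vector drift between slides (the quantifier and
generator share vectors only through configuration), or annotation error in
the tissue mask. Passing tests therefore demonstrate the *algorithms* are
correct and the *comparative statistics* behave as the spatial structure
dictates; they do not certify performance on scanner output, where stain
estimation and tissue detection (both out of scope) dominate.

## Numerical choices and problem sizes

* ε = 1/255 in the OD transform; recovery through 8-bit quantization is
  exact to ~0.01 OD (median) with a propagated worst-case bound.
* 8-connectivity everywhere; tie-breaks are always lowest-index/scan-order.
* Otsu threshold ties on an empty inter-mode gap resolve to the lower edge;
  any threshold in the gap induces the same partition.
* Test and validation cohorts use 8×8 mm canvases: ground-truth recovery and
  determinism at 4 µm/px (2000² px, the package's working resolution), the
  20-slide correlation cohorts at 8 µm/px (1000² px) — correlation contrasts
  are cohort-level properties and are insensitive to the finer raster, while
  a full section at scanner resolution (0.5 µm/px) is a configuration change,
  not a code path.
* The law-of-large-numbers check of the evidence ratio uses mask-level
  simulation (200 replicates) rather than full renders; the selection
  operates on masks, so nothing is lost.

## Known limitations

* The 0.26 mm² hot spot and the 5 mm² exclusion threshold are conventions,
  not optima; both are configuration.
* Greedy k-disjoint-circle selection is not guaranteed globally optimal
  (exhaustive search agrees on all tested rasters, but adversarial masks can
  separate them); the greedy rule *is* the contract because it is
  deterministic and order-stable.
* Hard-core thinning caps achievable cluster density, so very extreme
  "vascular lakes" are outside the generator's range.
* Correlations between quantification methods (area fraction vs MVD or
  Chalkley) are strong in fixed ROIs, which span empty to dense tissue; over
  *selected* hot spots they are attenuated by restriction of range — selected
  hot spots of clustered slides all sit near the cluster-packing density.
* The interobserver simulation jitters threshold and hot-spot placement only;
  it does not model disagreement about the tissue annotation itself.
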