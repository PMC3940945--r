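# ihcquant

Whole-slide versus hot-spot quantification of immunohistochemical stains.

## The problem

Immunovascular biomarkers of the tumor microenvironment — endothelial CD31,
regulatory FOXP3⁺ and cytotoxic CD8⁺ T cells — are conventionally scored in a
few pathologist-selected *hot spots*: small circles (0.26 mm² here, three per
section) of maximal marker density, quantified by micro-vessel density (MVD),
Chalkley count, or stained-area fraction. In heterogeneous tumors such as
osteosarcoma this convention is unsafe: when a marker is concentrated in a
few foci whose intensity is decoupled from the section's overall
vascularization, hot spots systematically overestimate it and correlate
poorly with whole-slide analysis; when the marker is homogeneously scattered,
the two agree. `ihcquant` implements both analyses end to end for calibrated
RGB rasters and the cohort statistics that compare them, plus a synthetic
slide generator with exact ground truth so the whole pipeline is testable
without patient material.

## What it computes

* **Color deconvolution** — Beer–Lambert unmixing: per-channel optical
  density `OD = −log10((I + 1/255)/255)` projected through the inverse stain
  matrix (hematoxylin counterstain, red chromogen, residual).
* **Per-slide threshold** — Otsu's between-class-variance maximization on the
  chromogen OD histogram within tissue, with an OD floor (default 0.15) for
  degenerate slides; every section gets its own threshold by a reproducible
  rule.
* **Immunoreactive mask and area fraction** — `100·|mask∩ROI∩evaluable| /
  |ROI∩evaluable|`, with 8-connected components below 8 px removed as debris.
* **Micro-vessel density** — morphological closing (8 µm disk) bridges
  interrupted vessel walls, then components with centroid in the ROI are
  counted.
* **Digital Chalkley count** — a fixed 25-dot graticule scaled to the
  hot-spot field; the count is the maximum number of dots on stained pixels
  over 64 rotations × 9 translations, the deterministic analogue of the
  manual adjustment.
* **Hot-spot selection** — the top-k non-overlapping 0.26 mm² circles of the
  mask-density field (circular-kernel convolution, stride grid, ≥90% in
  tissue, greedy, row-major tie-break), plus an evident-hot-spot enrichment
  index.
* **Cell metrics** — deterministic blob detection (area-bounded, 25 µm merge
  rule), densities in cells per 0.1 mm², tertile or fixed-cut
  low/intermediate/high categories.
* **Cohort statistics** — exclusion of sections under 5 mm² evaluable tissue
  (strict), Pearson correlations (two-sided t-transform p, α = 0.05) between
  quantification methods and between hot-spot and whole-slide analyses,
  per-slide interobserver variability `|Δ|/cohort mean × 100` (acceptable
  strictly below 10%), and a simulated two-observer mode.
* **Synthetic slides** — homogeneous Poisson or Thomas-type clustered layouts
  (per-cluster lognormal strength, hard-core vessel thinning), elliptical
  vessel rings with arc gaps, cell disks, per-object chromogen OD, additive
  scanner noise, and ground truth that is exact by construction.

## Worked example

```r
library(ihcquant)

# a homogeneous and a clustered synthetic section, 8 x 8 mm at 8 um/px
st  <- stain_model_params(mpp = 8)
hom <- spatial_pattern_params("homogeneous", intensity = 86, object_kind = "vessel")
clu <- spatial_pattern_params("clustered", parent_intensity = 86 / 68,
                              offspring_per_parent = 68, cluster_sigma = 0.25,
                              object_kind = "vessel")
s1 <- render_slide(hom, stain = st, seed = 11, slide_id = "homogeneous")
s2 <- render_slide(clu, stain = st, seed = 11, slide_id = "clustered")

quantify_slide(s1$slide, ihc_config(), "vessel", truth = s1$truth)
quantify_slide(s2$slide, ihc_config(), "vessel", truth = s2$truth)
```

```
<slide_quantification> homogeneous (vessel marker)
  evaluable 42.5 mm^2, threshold 0.150 OD
  area fraction: whole slide 7.344%, hot spots 12.324% (ratio 1.68)
  MVD per hot spot: 15, 17, 14; Chalkley: 10, 10, 9
<slide_quantification> clustered (vessel marker)
  evaluable 42.5 mm^2, threshold 0.150 OD
  area fraction: whole slide 5.365%, hot spots 13.864% (ratio 2.58, evident hot spots)
  MVD per hot spot: 22, 16, 24; Chalkley: 11, 9, 9
```

Same stain model and similar whole-slide area fractions — but the clustered
section's hot spots carry 2.6× its whole-slide fraction where the homogeneous
section's carry 1.7×: the selection bias that makes hot-spot analysis
overestimate heterogeneously distributed markers. At cohort scale, the
vascular marker (85% of subjects clustered by default) against a
mostly-homogeneous cell marker:

```r
plan_v <- cohort_plan(20, marker_spec = default_marker_spec()["cd31"],
                      master_seed = 7, mpp = 8)
plan_f <- cohort_plan(20, marker_spec = default_marker_spec()["foxp3"],
                      master_seed = 7, mpp = 8)
rec <- rbind(quantify_cohort(plan_v), quantify_cohort(plan_f))
compare_methods(rec, min_n = 10)
```

```
<ihc_comparison> 40 slides (0 excluded)
Method correlations over pooled hot spots:
  hotspot_area_fraction ~ mvd: r = 0.564, p = 2.68e-06, n = 60 *
  hotspot_area_fraction ~ chalkley: r = 0.222, p = 0.0886, n = 60 (n.s.)
Hot-spot vs whole-slide correlations:
  cd31_hotspot ~ cd31_whole_slide: r = 0.453, p = 0.0451, n = 20 *
  foxp3_hotspot ~ foxp3_whole_slide: r = 0.703, p = 0.000552, n = 20 *
Stratified by spatial pattern:
  cd31_clustered_hotspot ~ cd31_clustered_whole_slide: r = 0.804, p = 0.000101, n = 17 *
  cd31_homogeneous_hotspot ~ cd31_homogeneous_whole_slide: r = 0.801, p = 0.408, n = 3 (n.s.)
  foxp3_clustered_hotspot ~ foxp3_clustered_whole_slide: r = 0.825, p = 0.0431, n = 6 *
  foxp3_homogeneous_hotspot ~ foxp3_homogeneous_whole_slide: r = 0.832, p = 0.000224, n = 14 *
```

Hot-spot analysis tracks whole-slide analysis much more weakly for the
heterogeneously distributed vascular marker (r = 0.45, borderline) than for
the mostly homogeneous cell marker (r = 0.70) under the identical pipeline —
and a pure homogeneous vessel cohort reaches r ≈ 0.98 while a pure clustered
one stays below it (see `scripts/acceptance.R`). Correlations between the
three vessel methods are attenuated over *selected* hot spots by restriction
of range; in fixed ROIs spanning empty to dense tissue they are strong
(r ≥ 0.7, tested; see the methods vignette).

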