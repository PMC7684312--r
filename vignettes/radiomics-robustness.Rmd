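---
title: "Screening MR radiomics features for multi-scanner robustness"
author: "radirep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening MR radiomics features for multi-scanner robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radirep)
```

## The procedure and its assumptions

T2-weighted MR intensity is an arbitrary-unit signal: vendor, coil, and
sequence parameters all rescale and distort it, largely *monotonically* —
brighter tissue stays brighter, but the mapping between scanners is a
nonlinear, image-specific gain. `radirep` operationalizes one question: which
quantitative image features survive such changes, and how much does
landmark-based intensity normalization help?

The pipeline, end to end:

1. **Simulate** a multi-scanner study (or supply your own NIfTI volumes and
   VOI masks). Each subject is a fixed textured phantom; each session applies
   a scanner/parameter transform plus Rician noise.
2. **Preprocess**: resample image and mask to 1 mm isotropic voxels (cubic /
   nearest-neighbour); optional bias-field and registration hooks are
   identity functions here because the synthetic data need neither.
3. **Normalize** (one of the two arms): match each image's percentile
   landmarks (5, 10, 20, ..., 90, 95 %) to a reference session's landmarks
   with a monotone piecewise-cubic map.
4. **Discretize** in-mask intensities to L = 256 gray levels by
   histogram-equalization quantization, `level = ceil(L * ecdf(x))` with the
   midpoint tie convention. This depends on ranks only, so every texture
   feature downstream is *exactly* invariant under strictly monotone
   intensity maps — the formal reason texture can be robust where raw
   first-order statistics are not.
5. **Extract** the 396-feature catalog per session.
6. **Screen**: per-subject CV and QCD across repeated sessions, averaged
   within subject groups, thresholded at CV < 0.1 / 0.15 and QCD < 10 / 15;
   counts reported in the familiar group x cutoff table shape.
7. **Select**: four sequential reproducibility filters (phantom inter- and
   intra-scanner, then volunteer inter- and intra-scanner, all at CV < 0.1
   and QCD < 10), then hierarchical clustering of the survivors and the
   lowest-CV member of each cluster as its representative.
8. **Evaluate**: Mann–Whitney AUC (DeLong or bootstrap CI) of each
   representative for discriminating the two tissue layers of the two-layer
   phantoms, in both arms.

Key assumptions: the VOI is delineated once per subject and carried through
all sessions (no segmentation variability is modelled); inter-scanner
differences are monotone in intensity; sessions of one subject are
geometrically aligned.

## The feature catalog

Class totals are pinned and asserted at load: 42 histogram + 9 form factor +
100 GLCM + 180 run-length + 11 size-zone + 36 cluster + 18 correlation = 396
(345 texture features). The main text of the catalog's source tradition
fixes only these totals, not the base x angle x offset composition, so the
registry pins one and documents it:

- GLCM: 4 core bases (energy, entropy, inertia, inverse difference moment)
  at 5 directions (angles 0/45/90/135 plus `AllDirection`) x offsets
  {1, 4, 7} = 60, plus 8 extended bases (max probability, sum
  average/entropy/variance, difference average/entropy/variance, joint
  variance) at 5 directions, offset 1 = 40.
- Run-length: 12 bases x 5 directions x 3 offset *tags* = 180. Runs have no
  displacement, so the offset tag is a naming dimension: the three tags of a
  direction carry one value. This keeps the printed class total without
  inventing a nonstandard run statistic.
- Cluster: shade/prominence/tendency x 4 angles x 3 offsets = 36.
- Correlation: Pearson correlation of the co-occurrence pairs at all 15
  direction x offset combinations, plus a raw-second-cross-moment variant
  (`HaralickCorrelation`, the autocorrelation form) at `AllDirection` x 3
  offsets. The textbook normalized Haralick correlation is algebraically
  identical to the Pearson form on a symmetric matrix and would duplicate a
  feature, hence the unnormalized variant.
- Histogram: 21 first-order statistics plus a 21-entry percentile family
  (2.5 %, every 5 % from 5 to 95, 97.5 %). All statistics are positive-mean
  or location statistics; a zero-centred statistic (e.g. excess kurtosis)
  is deliberately excluded because CV = sigma/|mu| is meaningless when mu
  is near 0. Intensity energy (sum of squared intensities) fills that slot.
- `AllDirection` is the element-wise sum of the four per-angle count
  matrices before normalization — a *mixture*. Its entropy is therefore at
  least the per-angle minimum (concavity) but may exceed the per-angle
  maximum by up to log2(4) mixing bits; its energy never exceeds the
  per-angle maximum (convexity). The tests assert exactly these bounds.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `targetSpacing` | 1 | mm | isotropic grid for comparable texture offsets |
| `levels` (L) | 256 | gray levels | standard discretization depth; fixed across sessions |
| `offsets` | 1, 4, 7 | voxels | short/medium/long-range texture scales |
| `histBins` | 256 | bins | histogram entropy/energy bin rule (unstated in the tradition; pinned here) |
| landmark percentiles | 5, 10, 20, ..., 90, 95 | % | the printed 11-entry grid is used verbatim, although its source calls it "10 quantiles"; nothing identifies which entry would be dropped |
| `cvCutoffs` | 0.1, 0.15 | — | reproducibility thresholds |
| `qcdCutoffs` | 10, 15 | — | supplementary thresholds |
| `k` | 8 | clusters | number of representatives; no automatic selection is claimed — the source tradition reports 8 and 10 without a rule |

## The synthetic generator

`generatePhantom()` builds each tissue as *mean + Gaussian random field +
voxel noise*: white noise smoothed to the tissue's correlation length
(separable Gaussian kernel), rescaled to the texture amplitude. The
two-layer layout nests a core cylinder (inner layer) in an annulus (outer
layer) with different means and textures, mimicking two adjacent tissues
delineated separately. `applyScannerEffect()` then applies, in order, the
strictly increasing intensity map `gain * x^gamma + offset`, optional
Gaussian blur (TE/contrast surrogate), in-plane downsampling (acquisition
matrix), adjacent-slice averaging (slice thickness / partial volume — the
simplest defensible partial-volume surrogate) and Rician noise (magnitude of
two independent Gaussian channels, the correct magnitude-MR statistic).

Default study conditions mirror the reference design: 3 single-tissue
phantoms (group G.0) and 9 two-layer volunteers (G.1–G.3, three per group);
3 scanners sharing a nominal protocol (TR 3000 ms, TE 80 ms, ST 5 mm, AM
256x256) but differing in gain/offset/gamma; four one-parameter-at-a-time
sweeps — TR-like (3 levels), TE-like (4), ST-like (4, labels 3/4/5/6 mm) and
AM-like (4). The magnitudes of the inter-scanner gain/offset/gamma values
(1.00/0/1.00, 1.60/25/1.08, 0.65/8/0.93) are free parameters: no published
quantification of inter-vendor T2WI intensity differences exists to
calibrate them, so they were chosen once as "clearly visible but monotone"
and exposed in the configuration. Mild Rician noise (sigma 2 on a mean-100
signal) keeps session replicates from being identical.

What the generator does **not** emulate: bias fields, motion, anatomy-shaped
organs, coil sensitivity, Bloch-equation contrast, segmentation variability.
Passing tests therefore demonstrate the pipeline's statistical machinery and
the monotone-harmonization mechanism — not that any particular feature will
be robust on clinical images.

Seeding: every phantom and session seed derives from the master seed and the
(subject, arm, condition) labels through a 31-bit string hash
(`deriveSeed()`), so any cell of the design is independently reproducible.

## Numerical conventions

- Quantiles everywhere (landmarks, QCD quartiles, percentile features) use
  linear interpolation between order statistics (R type 7). QCD at n = 3–4
  sessions is sensitive to this; it is fixed and documented.
- CV uses the sample (n−1) standard deviation and is reported as an absolute
  value, since features such as skewness and cluster shade can be negative.
  Degenerate cases: sigma = 0 gives CV = 0 even at mu = 0 (a constant
  feature is reproducible); sigma > 0 with mu = 0 is an NA sentinel and the
  feature fails every cutoff. QCD: Q1 = Q3 gives 0; Q1 + Q3 = 0 otherwise is
  a sentinel.
- Discretization: `ceil(L * ecdf_mid(x))` clamped to [1, L]; all ties share
  one level (no dithering, determinism); a constant region maps to level 1.
- Entropies use log base 2 with 0·log 0 = 0; gray levels are 1-based.
- The landmark map is a Fritsch–Carlson monotone cubic Hermite interpolant
  implemented in the package (the `stats::splinefun` "monoH.FC" variant was
  observed to produce slightly non-monotone output on some knot sets, which
  would invert tissue contrast locally); beyond the outermost landmarks the
  terminal segments continue linearly. Tied source landmarks are collapsed
  to unique knots (reference values averaged); a fully degenerate source
  maps to the reference median with a warning.
- Resampling: output length per axis is `floor(extent/target) + 1` with the
  voxel-centre extent `(n-1) * spacing`; intensities by natural cubic
  splines per grid line (constants are reproduced exactly), masks by
  nearest neighbour re-binarized at 0.5.
- Surface area counts exposed voxel faces (exactly testable, unlike
  marching cubes); the maximum 3D diameter searches boundary-voxel pairs.
- Size zones use 26-connectivity in 3D; co-occurrence and run matrices are
  2D in-plane, accumulated over axial slices, because the four angles are
  planar constructs.
- Undefined features (no valid pair at an offset, zero-variance
  correlation) are NaN sentinels, never dropped; screening counts them as
  non-reproducible.
- Ties in representative picking break by catalog order; clustering is
  fully deterministic (no random initialization exists in agglomerative
  clustering).

## Open design choices

- Discretization is recomputed per image (each session's own ranks), the
  reading most consistent with per-ROI processing; a fixed global mapping
  would couple sessions.
- Order of operations is resample → normalize → discretize.
- CV is computed per subject across that subject's sessions and then
  averaged within the group ("means within each group"); a pooled variant
  is available behind `pooled = TRUE`.
- For the intra-scanner stage of the five-step filter, per-sweep records are
  stacked: a feature must pass in every sweep and every group.
- The high-versus-low parameter comparison (two-sample t-test over
  per-feature mean CVs) splits 4-level sweeps 2 + 2; 3-level sweeps use the
  overlapping halves {1,2} vs {2,3} because a single session cannot yield a
  CV. Identical vectors return p = 1 by convention.
- Clustering profiles are the volunteer inter-scanner sessions; the
  observation set is configurable in principle but fixed in the pipeline.
- The ROC arm comparison excludes form-factor features: they depend on the
  mask only and cannot change with intensity normalization.

## Problem sizes

The shipped demonstration configuration (`demoPipelineConfig()`) uses 1
single-tissue + 2 two-layer subjects, 3 scanners and the two 4-level sweeps
on a 32 x 32 x 24 voxel grid — chosen so a full two-arm run, including
texture extraction at L = 256 over 33 sessions, completes in a few minutes
on a single CPU while exercising every stage. The harmonization experiment
in `scripts/acceptance.R` uses ten independent 3-phantom x 3-scanner
studies. The full reference-layout design (3 + 9 subjects, all four sweeps)
is the package default for real use.

## Limitations

- Synthetic textures are Gaussian random fields; real tissue texture has
  structure (edges, layering) that rank discretization may treat
  differently.
- Monotone inter-scanner maps are the mechanism normalization can fix;
  non-monotone effects (B1 shading within the VOI, fat suppression
  differences) are out of scope, as are ComBat-style batch harmonization,
  ICC/Bland–Altman agreement statistics, wavelet/LoG-filtered features and
  3D (13-direction) texture.
- The number of clusters k is user-chosen; representatives depend on it.
- QCD with three sessions rests on interpolated quartiles of three points;
  treat its absolute values with care.
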