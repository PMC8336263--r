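---
title: "Methods: segmentation, concentration quotients and heritability of plant micro-XRF maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, concentration quotients and heritability of plant micro-XRF maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Micro X-ray fluorescence (micro-XRF) mapping yields per-element intensity
rasters of whole plants — here rosettes of the Zn/Ni hyperaccumulator
*Noccaea caerulescens* — in which intensity is a proxy for local element
concentration. Whether the *spatial pattern* of metal accumulation (petiole
vs. leaf margin vs. vasculature vs. interveinal tissue) is under genetic
control is a quantitative question: it requires (i) segmenting each scan
into substructures, (ii) a scale-free per-plant statistic of spatial
enrichment, and (iii) a variance-component analysis across genetically
distinct accessions grown with replication.

`xrfleaf` implements this chain end to end, together with the validation
machinery (segmentation scoring against annotated pixels, random-substructure
negative controls, label-noise injection, parameter sensitivity sweeps) and a
synthetic rosette generator that provides exact ground truth for all of it.

## Segmentation model

The pipeline is purely morphological and deterministic:

1. **Plant foreground.** Each metal raster (Zn, K, Ca, Ni) is binarized with
   Otsu's method (256-bin histogram, threshold minimizing intra-class
   variance, mask where `pixel > t`); the plant mask is the union of the four
   masks. The Compton scatter raster is not used here.
2. **Blade vs. petiole.** A morphological opening with a square all-ones
   structuring element (default 15 x 15, one iteration) removes structures
   narrower than the kernel — petioles — leaving the blade mask. The residual
   `plant \ blade` is cleaned by discarding 8-connected components smaller
   than 0.001% of the image area (rounded up to a whole pixel); what remains
   is the petiole mask.
3. **Leaf margin.** The internal gradient of the blade: `blade` minus its
   erosion with a square kernel. A kernel of side `2w + 1` leaves a band of
   width `w` on straight edges; the default 7 gives the 3-px margin band.
4. **Vasculature.** The Compton scatter image shows veins as bright ridges.
   An aperture-7 Laplacian (see below) gives strongly negative responses on
   ridges. Thick vasculature is `response < vein1_threshold` (default
   -2500); thin vasculature is the Zhang–Suen skeleton of `response < 0`
   (strict, so a perfectly flat response detects nothing). Their union is
   intersected with `blade \ margin`.
5. **Tissue.** The blade remainder. By construction margin, vein and tissue
   are pairwise disjoint with union equal to the blade, the petiole is
   disjoint from the blade, and every non-background pixel lies in the plant
   mask. These partition invariants are asserted property-style in the tests.

Plants too small for the opening kernel produce an empty blade; they are
still processed (everything becomes petiole) with a warning rather than an
error, since this is a known failure mode of the method on seedlings.

### The Laplacian dialect

Discrete "Laplacian" operators differ across libraries, and threshold values
are only meaningful relative to one fixed kernel. `xrfleaf` uses the extended
(Sobel-style) second-derivative family: a second-difference row `[1, -2, 1]`
convolved with a binomial row, smoothed with a binomial row in the
perpendicular direction, summed over both axes, *unnormalized*, with
edge-replicated borders. For aperture 7 the 1-D derivative row is
`[1, 2, -1, -4, -1, 2, 1]` and the smoothing row `[1, 6, 15, 20, 15, 6, 1]`.
Response magnitudes therefore grow with the aperture, and the default
thresholds (-2500 / 0) are specific to this dialect and to 8-bit dynamic
range; both are exposed as parameters. On the synthetic fixtures (vein
ridges ~110 intensity units above tissue) the aperture-7 crest response is
of order -10^4, so the -2500 default detects rendered veins with a margin;
the fixture tests gate this calibration at per-class F1 >= 0.8.

Because the convolution is FFT-based, responses on perfectly flat regions
carry round-off of order 1e-10; these are snapped to exact zero so that the
strict `< 0` threshold is deterministic.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `opening_kernel` | 15 px | blade/petiole separation scale; structures narrower than this become petiole |
| `min_component_fraction` | 1e-5 | petiole residual components below this fraction of the image area are dropped |
| `margin_erosion_kernel` | 7 px | margin band width = (kernel - 1) / 2 = 3 px |
| `laplacian_kernel` | 7 px | aperture of the second-derivative kernel |
| `vein1_threshold` | -2500 | thick-vasculature threshold (dialect-specific) |
| `vein2_threshold` | 0 | thin-vasculature threshold, strict, then skeletonized |

All structuring elements are square and all-ones; the sizes are the
documented contract, the shape is the simplest consistent choice. Sensitivity
of segmentation quality to the four main parameters is available through
`sensitivity_sweep()`, whose default grids run from two steps below to two
steps above the defaults (opening 7..23 by 4, Laplacian 3..11 by 2, vein1
-3500..-1500 by 500, vein2 -200..200 by 100), re-scoring a fixed set of
annotated pixel coordinates at every value.

One documented ambiguity: descriptions of the margin step variously pair a
"3 x 3" or "5 x 5" erosion kernel with a stated 3-px band width. A square
kernel of side `2w + 1` yields width `w`, so only 7 x 7 honours the stated
width; we treat the output width as the testable contract and default to 7,
with the size exposed as a parameter.

## Quantification

The **concentration quotient** of substructure *s* on element raster *P* is

CQ_s = mean(P over s) / mean(P over plant),

dimensionless, 1 when the substructure is unenriched, invariant under global
rescaling of the raster. The plant denominator is the set of non-background
label pixels, which makes the conservation identity exact: the
pixel-count-weighted mean of the four substructure CQs equals 1. An empty
substructure yields a missing value, never 0 — a silent 0 would bias the
heritability fits downstream. Per-plant traits additionally include plant
size (non-background pixel count), per-element plant means, relative
substructure sizes, and pixel-level colocalization (Pearson *r* between two
element rasters over plant-foreground pixels, on raw intensities).

Segmentation quality is scored on manually annotated pixels: for each class,
up to 1000 predicted pixels are sampled uniformly without replacement and
presented in shuffled order (annotator blind to the predicted class); the
confusion matrix holds ground truth in rows and predictions in columns, and
per-class precision = M_ii / column sum, recall = M_ii / row sum,
F1 = harmonic mean. Reported values follow the 2-decimal convention only in
reports; internal values are full precision.

## Heritability

Broad-sense heritability (repeatability) of a trait across accessions with
replicate plants is estimated from the one-way random-intercept model
`P = G + e` fitted by REML (`lme4::lmer`), with

H^2 = Var(G) / (Var(G) + Var(e)).

REML was chosen over ML because it is unbiased for the residual variance in
small balanced designs; negative variance estimates are truncated at zero by
the fitter, so H^2 lies in [0, 1]. On balanced designs the estimate agrees
with the closed-form one-way ANOVA method-of-moments estimator
(`anova_variance_components()`, kept as an independent oracle in the tests;
agreement to 1e-6 relative tolerance). Unbalanced panels are handled natively
by REML. Each fit also reports the residual-vs-fitted correlation as an
advisory diagnostic — it is not a gate, since assumption violations are
expected (and observed) only for the random-substructure control traits.

## The synthetic study

`panel_spec()` defines the emulated design: 86 accessions x 3 replicates
(the study design of the motivating experiment), one 256 x 256 scan per
plant, 5-leaf rosettes of elliptical blades (semi-axes 22 x 17 px at scale
1) with 9 x 21 px petiole strips, a 3-px margin rim, and a vein system
(3-px midrib, 2-px secondaries). These sizes were chosen once so that the
generator satisfies the structural premises of the segmentation: petioles
narrower than the opening kernel, blades wider, blade tip curvature radius
larger than the kernel's half-diagonal (so the box opening does not shave
tips into spurious petiole), and tissue the dominant class (which the
label-noise argument relies on). A "hard" fixture family with 1-px
secondaries (`vein_secondary_halfwidth = 0.5`) reproduces the vein/tissue
confusion seen at the resolution limit.

Metal intensities are multiplicative: element base intensity x substructure
multiplier, where the multiplier is `mu_s * exp(G + e)` with accession-level
`G ~ N(0, sigma_G^2)` and replicate-level `e ~ N(0, sigma_e^2)` on the log
scale (keeping intensities positive; for the default sigmas the lognormal is
nearly linear, so effects map directly onto CQs). The implied true
heritability sigma_G^2 / (sigma_G^2 + sigma_e^2) is recorded in the panel
spec object;
the defaults (0.134, 0.067) give 0.80. Accession effects are drawn
independently per element x substructure, matching the observation that CQs
of different metals are only weakly correlated. Plant size carries its own
log-scale accession effect (clamped at +-0.3 so extreme draws cannot outgrow
the canvas). Pixel noise is Gaussian (sd 5 by default); the Compton raster
gets elevated vein/petiole levels and no genotype effect. Rasters are kept
real-valued in memory and rounded only on 8-bit TIFF export.

The generator's bookkeeping records the realized noiseless CQ of every
substructure x element in closed form (multiplier over the area-weighted
plant mean multiplier); with zero noise the CQ measured from the rendered
raster equals it exactly, which the tests assert to 1e-12.

### What the generator does and does not emulate

It emulates: rosette morphology at the scale relationships the segmentation
assumes, bright-vein Compton contrast, substructure-specific enrichment with
controlled genotype/replicate variance, detector noise, and batch layouts
(multiple plants per canvas, for `split_plants`). It does **not** emulate
XRF physics (absorption, sample-thickness effects, spectral overlap),
touching or occluding leaves, developmental gradients, or non-elliptical
leaf shapes. Passing tests therefore demonstrate correctness of the
*algorithmic chain* under the stated geometric premises, not segmentation
accuracy on real scans — on real data the published per-class scores (F1
0.67–0.80) are the realistic expectation, not the fixture scores.

### Desk-scale adaptations

Two deliberate scale adaptations, both visible in the code and tests:

* **Random-substructure squares.** The published control draws five 30 x 30
  squares per plant. On megapixel scans that is a few percent of the plant;
  on a ~6,000-px synthetic plant it would cover half of it, and
  centre-on-foreground placement then *systematically* underweights boundary
  classes (the 3-px margin alone is about a third of a desk-scale plant), so
  the control would inherit genotype signal instead of being noise. Panel
  analyses therefore scale the square side to preserve relative coverage,
  side = 30 * sqrt(A_desk / A_paper) ~ 8 px (~5%). `random_substructure()`
  itself keeps the published defaults.
* **Estimator-bias replicates.** The 20-panel bias check of the H^2
  estimator streams panels labelled with ground truth rather than re-running
  segmentation: the property under test concerns the variance-component
  estimator, and segmentation-induced error is covered by the full-pipeline
  panel in the same test. Problem sizes used by the tests: one 86 x 3 panel
  through the full pipeline, 20 panels for the bias check, 50 rosettes for
  the partition properties.

### Label noise

`inject_label_noise()` reassigns a seeded, uniformly chosen fraction *f* of
plant pixels a class drawn uniformly from the four substructure classes; the
draw may repeat the original class ("assigning a random class", read
literally), so the effective corruption rate is 0.75 f. Under full noise
(f = 1) every noisy class mask becomes a uniform random sample of plant
pixels, so the four CQ traits of an element collapse onto the same quantity
(≈1): the dominant-class convergence is asserted on the trait values in the
tests. At moderate noise the mixing coefficients are nearly constant across
plants, so genotype and error variance shrink together and H^2 is almost
unchanged — the robustness reported for this metric on real scans, and what
the noise-curve test asserts at f = 0.2.

## Numerical choices

* Otsu ties are broken towards the smallest threshold; non-8-bit input is
  min-max binned into 256 levels first. Constant rasters yield an all-false
  mask with a warning (no separating threshold exists).
* Connected components use 8-connectivity throughout (diagonally touching
  leaves belong to one plant); implemented with a compiled flood fill, since
  the available image stack labels 4-connected only.
* Skeletonization is Zhang–Suen thinning (compiled): topology-preserving,
  1-px, 8-connected, skeleton ⊆ mask, endpoints of 1-px lines preserved.
* All stochastic operations take explicit integer seeds; sub-seeds are
  derived with a seeded `sample.int` stream and kept within 32-bit range.
  The RNG state of the caller is always restored.
* Pixel coordinates are (row, col), 1-based in R, row-major; masks are
  logical matrices co-indexed with rasters everywhere.

## Known limitations

* Threshold defaults for vein detection do not transfer across Laplacian
  dialects or bit depths; recalibrate when importing parameters from other
  software.
* The box-kernel opening shaves a 1-px rind from highly curved digital
  boundaries; with realistic petiole sizes this costs petiole precision (the
  published scores show the same artifact on real scans).
* CQ assumes co-registered rasters and equal effective sample thickness; no
  absolute concentrations are produced.
* H^2 is repeatability: it includes any stable micro-environmental component
  and is an upper bound on narrow-sense heritability.
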