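# xrfleaf

Substructure segmentation and heritability analysis of plant micro-XRF
elemental maps.

Micro X-ray fluorescence (micro-XRF) mapping produces per-element intensity
rasters of whole plants — e.g. rosettes of the Zn/Ni hyperaccumulator
*Noccaea caerulescens* — in which pixel intensity is a proxy for local
element concentration. `xrfleaf` is for researchers who want to turn such
scans into *genetic* statements about the spatial pattern of metal
accumulation. It provides:

* **Segmentation** of each scan into petiole, leaf margin, vasculature
  (vein) and interveinal tissue, by a deterministic morphological pipeline:
  Otsu-union plant mask → opening-based blade/petiole split (square 15×15
  structuring element, small-component cleaning at 0.001% of the image
  area) → internal-gradient 3-px margin → Laplacian ridge detection on the
  Compton scatter raster (aperture-7 second-derivative kernel; thresholded
  for thick vasculature, thresholded-and-skeletonized for thin vasculature).
* **Quantification** with the concentration quotient,
  `CQ_s = mean(P over substructure s) / mean(P over plant)` — dimensionless,
  scale-free, `CQ = 1` meaning no enrichment — plus plant size, plant mean
  concentrations, relative substructure sizes and pixel colocalization
  (Pearson *r* per element pair).
* **Broad-sense heritability** (repeatability)
  `H² = Var(G) / (Var(G) + Var(ε))` of any trait across accessions with
  replicates, from a one-way random-effects model fitted by REML
  (`lme4`), with a closed-form balanced-ANOVA cross-check.
* **Validation machinery**: blind sampling of predicted pixels for manual
  annotation; per-class precision/recall/F1 from the confusion matrix;
  random-substructure negative controls; label-noise injection; sensitivity
  sweeps over the four main segmentation parameters.
* A **synthetic rosette generator** (`panel_spec()`, `generate_panel()`)
  with exact per-pixel ground truth and controlled genotype variance, so the
  full pipeline is testable without original scans.

Rasters are single-channel greyscale TIFFs (8-bit, 16-bit accepted); label
maps are TIFFs with documented integer codes; tables are CSV.

## Worked example

```r
library(xrfleaf)

# a small synthetic panel: 8 accessions x 3 replicates, true H2 = 0.8
panel <- generate_panel(panel_spec(n_accessions = 8, seed = 42))
plant <- panel_plant(panel, 1)
labels <- segment_bundle(plant$bundle)
print(labels)
#> <seg_labels> 256 x 256: background=60032, petiole=973, margin=1752, vein=952, tissue=1827

# score the segmentation against the generator's ground truth
ev <- evaluate_labels(labels, ground_truth_from_labels(plant$truth$labels))
print(ev, digits = 2)
#>     class precision recall   f1
#> 1 petiole      0.70   0.95 0.81
#> 2  margin      0.91   0.83 0.87
#> 3    vein      0.92   0.96 0.94
#> 4  tissue      0.98   0.91 0.94

# per-plant traits -> per-trait broad-sense heritability
traits <- panel_trait_table(panel, labels = "segment")
rep <- heritability_report(traits,
  traits = c(sprintf("cq_Zn_%s", SUBSTRUCTURES), "plant_size"))
print(rep[, c("trait", "var_G", "var_e", "H2")], digits = 2)
#>           trait   var_G   var_e   H2
#> 1 cq_Zn_petiole 4.3e-03 3.1e-03 0.58
#> 2  cq_Zn_margin 8.5e-03 3.1e-03 0.73
#> 3    cq_Zn_vein 2.6e-02 5.6e-03 0.82
#> 4  cq_Zn_tissue 7.7e-03 1.7e-03 0.82
#> 5    plant_size 1.3e+06 3.3e+05 0.80
```

Reading the output: the label map counts pixels per class; the evaluation
table gives per-class precision, recall and their harmonic mean (F1) against
the generator's exact ground truth; the report gives the genotype and
residual variance components per trait and their ratio H². With only 8
accessions the per-trait H² estimates scatter widely around the generating
value of 0.8 (the full 86-accession design pins them down much more tightly).

For real scans, build bundles from TIFFs with `load_bundle()` /
`read_manifest()`, or run the thin CLI (`inst/cli/xrfleaf.R`) with
subcommands `simulate`, `segment`, `quantify`, `evaluate`, `heritability`,
`sweep`, `noise-curve` and `run-all`.

## Layout

```
R/                  segmentation, quantification, heritability, robustness,
                    synthetic generator, IO, pipeline
src/                compiled 8-connected labelling + Zhang-Suen thinning
tests/testthat/     unit + property tests, end-to-end acceptance suite
scripts/acceptance.R
inst/cli/xrfleaf.R  command-line front end
vignettes/          methods vignette (model, parameters, design decisions)
```
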