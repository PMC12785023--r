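# msimargin

Tumor margin delineation and intratumor heterogeneity mapping from
low-mass-range imaging mass spectrometry (IMS/MSI).

## The problem

MALDI-TOF imaging mass spectrometry records a full mass spectrum at every
pixel of a tissue raster. For colorectal-cancer resections, the spatial
pattern of small molecules (200–1000 Da) carries information that routine
hematoxylin–eosin histology does not: the biochemical margin between tumor
and peritumor tissue, and the heterogeneity of the tumor mass itself. This
package implements the whole analysis chain a histopathology-adjacent MSI
study needs:

- **imzML I/O** — reading continuous- and processed-mode imzML/ibd pairs
  into a pixel × m/z datacube, and writing cubes back out.
- **Preprocessing** — total-ion-current (TIC) normalization and windowing
  of the axis into the four canonical ranges 200–400, 400–600, 600–800 and
  800–1000 Da (0.1 Da bins for centroided data).
- **Segmentation** — exact single-linkage hierarchical clustering of pixel
  spectra under Euclidean distance, computed through the minimum-spanning-
  tree formulation (O(n²) time, O(n) memory, provably identical to naive
  agglomeration), cut into *binary* (k = 2, margin depiction) or *denary*
  (k = 10, heterogeneity) class images with deterministic coloring.
- **Margin statistic** — with two tumor and two peritumor regions of
  interest (ROIs), the margin is deemed correctly localized when the
  percentage of peritumor-ROI pixels carrying the tumor's modal cluster
  label is strictly below 10%:
  `match% = 100 · #{peritumor pixels with tumor label} / #{peritumor pixels}`.
  Collection-level recognition is tested against chance with the exact
  one-sided binomial tail `P(X ≥ s | n, ½) = Σ_{i≥s} C(n,i)/2ⁿ`.
- **Information content** — the byte size of the segmented label image
  after lossless PNG compression (a surrogate complexity measure), with
  OLS trend tests of size on the window index and a slope-difference
  t-test between ionization modes.
- **Annotation** — tentative MS1 annotation of dominant m/z values against
  a local formula table (±0.1 Da, [M+H]⁺/[M−H]⁻/[M+Na]⁺/[M+K]⁺ adducts).
- **Phantoms** — a ground-truthed synthetic MSI generator (tumor cores,
  margin band, peritumor, fat; per-case peak panels; two ionization modes)
  so every stage is testable end-to-end without patient data.

## Worked example

```r
library(msimargin)

ph   <- make_phantom(default_phantom_spec(seed = 1, mode = "negative"))
cube <- tic_normalize(ph$cube)
wc   <- window_mass_range(cube, canonical_windows()[["800-1000"]])

seg <- hca_segment(wc, 2)
seg
#> <segmentation_result> k = 2 (single linkage, euclidean), sizes: 1087, 513

margin_assessment(seg$label_map, ph$truth$rois)
#> match_pct = 0.00, recognized = TRUE
```

The binary cut separates the 513 tumor-side pixels (cores plus margin
band) from the 1087 background pixels; no peritumor-ROI pixel carries the
tumor's label, so the margin is recognized (0% < 10%). Against the phantom
ground truth this segmentation scores an adjusted Rand index of 0.900, and
its denary sibling compresses to 310 B versus 241 B for the binary image —
more classes, more information content.

Collection-level inference and annotation:

```r
recognition_binomial_test(9, 10)$p_value
#> 0.010742   # printed as p = 0.011

annotate(465.94, "negative")[1, ]
#>   name      formula      class adduct theoretical_mz      delta tentative
#> 1 dCTP C9H16N3O13P3 nucleotide [M-H]-       465.9823 0.04232101      TRUE
```

## The analysis workflow

Numbered drivers under `analysis/` reproduce the synthetic study over a
10-case collection with tumor/peritumor contrast confined to 800–1000 Da
(writing tables under `results/`):

```sh
Rscript analysis/01_simulate_phantoms.R    # build the 10-case collection
Rscript analysis/02_segment_margins.R      # factorial study + recognition table
Rscript analysis/03_information_content.R  # binary vs denary sizes, trends
Rscript analysis/04_annotate_margins.R     # dominant margin m/z annotation
```

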