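---
title: "Margin delineation from low-mass-range MSI: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Margin delineation from low-mass-range MSI: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msimargin)
```

## The data model

An MSI acquisition is a pixel raster (default pitch 30 µm) where each
pixel carries a mass spectrum over 200–1000 Da. `msi_cube` stores this as
an `n_pixels × n_bins` intensity matrix on a shared, strictly increasing
m/z axis, with 0-based pixel coordinates (x rightward, y downward — the
imzML top-left convention; the choice is arbitrary but must be fixed for
the row-major tie-break rules below). Intensities are serialized as 32-bit
floats, ample for TOF dynamic range. Every transforming operation appends
to a provenance log and never truncates it, so the processing order of any
cube can be audited after the fact.

Continuous-mode imzML files come in as-is; processed-mode (centroided)
files are resampled by fixed-width binning at 0.1 Da. The bin width
deliberately matches the annotation tolerance: vendor centroiding
algorithms are proprietary and unspecifiable, while plain binning is
reproducible and preserves everything the downstream statistics consume.
Bins are anchored at the low edge of the range and are half-open,
`[low + i·w, low + (i+1)·w)`; a value sitting exactly on a boundary is
assigned to the bin it opens, with a forward nudge of 1e-9 bins guarding
against floating-point division error.

## Preprocessing

**TIC normalization** rescales each pixel so its intensity sum equals the
grand mean of the raw per-pixel totals. The target's absolute value is
irrelevant to segmentation — Euclidean distances scale uniformly under any
positive constant — but the grand mean keeps intensities interpretable.
Zero-TIC pixels either stay zero and are flagged in provenance (default)
or are dropped, per configuration. Normalization is idempotent to 1e-9.

**Windowing** restricts the axis to one of the four canonical ranges
(200–400, 400–600, 600–800, 800–1000 Da), half-open except the terminal
window, which closes at 1000 Da so the last bin is not orphaned. The
pipeline normalizes on the full acquisition range *first* and windows
afterwards: the two operations only commute when the window is the whole
axis, so the order must be fixed. Whether a per-window re-normalization is
preferable is genuinely open; both are available, global is the default.

## Segmentation

Pixel spectra are clustered by agglomerative hierarchical clustering with
Euclidean distance and single (nearest-neighbor) linkage, cut at k = 2
(binary, margin depiction) and k = 10 (denary, heterogeneity). Single
linkage over Euclidean distances is computed exactly through the minimum
spanning tree: Prim's algorithm builds the MST in O(n²) time and O(n)
memory, and cutting the k−1 heaviest edges yields precisely the partition
a naive O(n³) agglomeration produces. The test suite verifies this
equivalence against two independent oracles (a from-scratch naive
agglomerator and `stats::hclust`) on dozens of random cubes.

Determinism is engineered in at three points, because the margin statistic
references "the color of the tumor" and colors must be stable across
reruns: (i) equal-weight merges resolve in lexicographic pixel-index
order; (ii) final labels are ordered by descending cluster size, ties by
the first member pixel in row-major order; (iii) the rendering palette is
a fixed built-in sequence of 10 distinct colors plus a background color
for positions without tissue. Two runs of the same cube render
byte-identical PNGs.

No feature selection precedes clustering: distances use all bins of the
active window. k is fixed at 2 and 10 by protocol; automatic selection of
the number of segments is explicitly out of scope.

## The margin statistic and its inference

Four ROIs — two tumor, two peritumor — are placed on the binary image. The
tumor's reference label is the modal label over the union of the tumor
ROIs (mode over the union is the simplest estimator consistent with two
tumor ROIs; ties go to the smaller label). The match percentage is the
share of peritumor-ROI tissue pixels carrying that label, pooled over both
peritumor ROIs (a per-ROI variant is a one-line change; pooling is the
default). Recognition requires `match% < 10` **strictly** — "less than
10%" is taken at its word, so exactly 10% is a miss.

Collection-level recognition is tested with the exact one-sided binomial
tail under p₀ = ½, the chance probability of a binary call agreeing with
the pathologist's gold standard at random. One-sided is the only reading
that reproduces the canonical worked value: s = 9, n = 10 gives
11/1024 ≈ 0.0107 (printed 0.011), where the two-sided tail would give
0.021. For the denary cut the same statistic is computed but flagged
advisory-only — with ten classes the tumor's modal color fragments and
matching is unreliable — and the count of distinct denary labels inside
the tumor ROIs is reported instead as a heterogeneity index.

## Information content

The complexity of a segmented image is measured as the byte size of its
losslessly compressed PNG. The encoder is therefore pinned: 8-bit
truecolor RGB, one image pixel per raster position, no interlace, no
ancillary chunks, libpng's adaptive filter heuristic (the `png` package);
identical (labels, palette) inputs produce byte-identical files. Sizes are
reported in raw bytes, with kb = bytes/1024 for display only (the binary
convention; the decimal one would change nothing downstream). Comparisons
should be made between segmentations of the *same* raster — encoder filter
heuristics can shift absolute sizes by tens of bytes between pathological
test patterns, but within-raster orderings (a denary image compresses to
at least as many bytes as its binary sibling) are stable.

Trends of size across the four windows are fit by OLS on the window index
1–4 — the ranges are presented categorically, so the index, not the window
midpoint, is the regressor (midpoint available via configuration). Two
readings of "slope difference t-test" are defensible, so both are
reported: each mode's slope against zero (one-sided for a decrease) and
the between-mode difference via the interaction term of a joint
regression. Degenerate fits get explicit handling: zero residual variance
yields p = 0 for a negative slope and p = 1 otherwise, never NaN.

## Annotation

Dominant m/z values (the tallest bin of a cluster's mean spectrum; ties
to the lowest m/z) are looked up in a local three-column table (name,
formula, class) shipped with ~35 metabolites: nucleotides including dCTP,
common glycerophospholipids, fatty acids, sugars. Monoisotopic masses are
summed from standard atomic constants; adducts [M+H]⁺, [M+Na]⁺, [M+K]⁺
(positive mode) and [M−H]⁻ (negative mode) use proton-adjusted ion-mass
shifts. A hit requires |query − theoretical| ≤ 0.1 Da; hits are sorted by
mass error. Every output is labeled tentative: MS1 mass alone cannot
identify a molecular species, and no table entry asserts the lipid-region
assignment near 885.75 Da, which is plausibly a triglyceride but has no
defensible single formula.

## The phantom generator

Patient MSI data are not redistributable, so the package ships a
ground-truthed generator emulating the structure the study design assumes:
a peritumor background, an elliptical tumor containing a biochemically
shifted subregion, a margin band around the tumor, and a small fat
deposit. Each region owns a peak panel; per pixel, intensities are the sum
of Gaussian-shaped peaks (σ = 0.05 Da on the 0.1 Da grid) scaled by
lognormal per-pixel amplitude draws (CV 0.25), plus a baseline, times a
lognormal TIC-drift factor (CV 0.3), plus absolute-valued Gaussian
detector noise. Everything is a deterministic function of the seed.

Default choices, made once:

- **Grid 40 × 40** (1600 pixels): large enough for ~500-pixel tumors and
  stable ROI placement, small enough that a 20-seed recovery study and the
  10-case factorial run in tens of seconds.
- **Noise σ = 0.5 (positive) / 1.0 (negative)** against discriminant peak
  amplitudes of 80–100: the high-SNR regime in which single-linkage
  clustering should recover planted structure. Negative mode carries the
  larger noise, emulating its higher observed information content. Noise
  is additive truncated-Gaussian rather than Poisson — simpler, and
  adequate for exercising clustering behavior.
- **Discriminant masses** anchored at the reported features 465.94 Da
  (margin), 864.15 and 885.75 Da (tumor, terminal window): the phantoms
  speak the field's language, but amplitudes are free parameters, not
  claims about real tissue.
- **Margin panel at 0.85 × the tumor panel plus its own 465.94 Da
  feature** ("distinct" preset; a "gradient" preset makes it a 50/50
  tumor/peritumor mixture instead). Keeping the margin's tumor-side
  features near the tumor's prevents single-linkage chaining from
  bridging tumor to peritumor through the band.
- **ROIs** are auto-placed squares eroded well inside their regions, so no
  ROI touches the margin band — mirroring how a pathologist marks
  unambiguous tissue.

The multi-case generator draws each case's shared panel as a stratified
random subset of an 80-compound pool (three per window, so every window
carries signal) and adds window-specific tumor discriminants scaled by a
per-window contrast vector; `c(0, 0, 0, 1)` confines the tumor/peritumor
contrast to 800–1000 Da, the configuration of the synthetic study. Cases
consequently share only a handful of m/z values, emulating strong
interindividual variability.

What the phantoms do **not** emulate: isotope envelopes, matrix cluster
ions, physically realistic TOF peak shapes, ion suppression, spatially
correlated noise, or irregular (non-elliptical) tumor morphology. Passing
the recovery tests therefore shows that the pipeline's statistics behave
correctly on data with planted structure at realistic SNR — not that real
tissue would yield the same recognition rates. The per-patient recognition
outcomes and absolute image sizes of any real cohort are outside what a
synthetic twin can certify.

## Problem sizes and numerical choices

The shipped studies use 40 × 40 phantoms, 20 recovery seeds, a 10-case
collection and 100 Monte-Carlo replicates for the trend-test power check —
sizes chosen so the full suite completes in minutes on one core while
leaving the binomial margins (≥ 18/20, ≥ 9/10, ≥ 90/100) meaningfully
testable. Key numerical conventions: strict inequality at the recognition
threshold; half-open bins with a 1e-9 forward nudge at boundaries;
low-m/z tie-break for dominant peaks; smaller-label tie-break for modal
labels; lexicographic tie-break for equal merge distances; TIC
normalization tolerance 1e-9 relative.

## Known limitations

Single linkage chains: one aberrant pixel can become the second binary
cluster (it occasionally does, in about one seed in twenty at default
noise), which is faithful to the method rather than a defect of the
implementation; methods with spatial regularization are deliberately out
of scope. The binomial test treats cases as exchangeable Bernoulli trials;
the information-content metric depends on the pinned encoder and is only
comparable within one encoder version; annotation is MS1-only and
tentative by construction.
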