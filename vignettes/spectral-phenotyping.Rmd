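---
title: "Spectral phenotyping of cells: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral phenotyping of cells: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectrapheno)
```

## The problem

Mid-infrared absorbance spectra of cells integrate the vibrational
signatures of their proteins, lipids, nucleic acids and carbohydrates
into one chemical fingerprint. In hyperspectral FTIR microscopy a
focal-plane-array detector records a full absorbance spectrum (typically
4000–800 cm⁻¹) at every pixel of a tile, so a single field of view holds
thousands of spectra covering many cells. The question this package
addresses: given such images for two groups of cultured cells (disease
and control), can the per-cell chemistry classify the groups — and from
which subcellular compartment should the spectra be taken?

The pipeline has three stages, each exposed as ordinary R functions and
orchestrated by `run_pipeline()`:

1. **Segmentation** — reduce each cube to an amide-I intensity image,
   find cells, nuclei and cytoplasm, and average the pixel spectra of
   each compartment into one mean spectrum per cell segment.
2. **Quality testing and preprocessing** — screen mean spectra with
   calibrated absorbance/SNR/water-vapor cutoffs, then convert survivors
   to vector-normalized Savitzky–Golay second derivatives.
3. **Classification and statistics** — embed the spectra (UMAP or PCA),
   quantify cluster separation with a silhouette score and a label
   permutation test, and classify spectra with k-nearest neighbours
   under 3-fold cross validation, summarized as a confusion matrix with
   accuracy, sensitivity and specificity (disease = positive class).

## Segmentation

The amide-I band (1630–1670 cm⁻¹, protein backbone C=O stretch) is the
strongest cellular absorption and gives the best cell/background
contrast, so `integrate_band()` forms the per-pixel trapezoidal integral
over that window (units absorbance·cm⁻¹) and everything downstream
thresholds that image.

Cell foreground comes from a *local* Otsu threshold
(`local_otsu_mask()`): each pixel is compared with the Otsu threshold of
its disk-shaped neighbourhood, which tolerates the non-uniform
illumination background typical of mosaicked acquisitions. Two
implementation choices matter:

* Histogram bins (256) are fixed globally over the image range; the
  per-pixel neighbourhood statistics are accumulated by convolution, bin
  by bin, which makes the per-pixel thresholds *identical* to running
  global-bin Otsu on each clipped neighbourhood (tested against exactly
  that oracle) while staying fast enough for 128×128 tiles.
* Borders are handled by clipping the neighbourhood, never by padding
  with fabricated intensities. Neighbourhoods whose values fall in a
  single bin have no threshold and are classed background.

A pixel far from any cell sees a neighbourhood of pure background noise,
and Otsu will happily split noise — local thresholding always speckles
empty regions. The pipeline is robust to this because (a) components
smaller than `min_object_px` (default 16 px ≈ one 4.7 µm-radius object
at 5.5 µm pitch) are removed, and (b) the seeded watershed only labels
mask components that contain a nucleus seed, so distant speckle never
becomes a cell.

Nuclei are the brightest amide-I structures. The default
`nucleus_strategy = "global_otsu"` computes a *second* Otsu threshold
over the cell-foreground intensities only and takes in-cell pixels above
it; a local-Otsu alternative with a smaller disk is available. One seed
per nucleus component (at the centroid, snapped to the nearest in-mask
pixel) feeds a seeded watershed (`EBImage::propagate`, a
Voronoi-on-manifold flood) that partitions the cell mask into one basin
per seed; ridge assignment is deterministic. Finally nucleus and
cytoplasm (cell minus nucleus) are each eroded by a Euclidean disk of
radius 2 px — implemented by distance transform: pixels closer than the
radius to the segment boundary are removed — to sharpen
nucleus/cytoplasm and cell–cell delineation. Whole-cell mean spectra are
computed on the *uneroded* cell mask; cells whose eroded nucleus or
cytoplasm vanishes are flagged, not silently dropped. For evaluation
against ground truth the pre-erosion partitions are retained
(`evaluate_segmentation()` scores those): erosion is a spectra-extraction
refinement, and comparing an eroded 3-px disk against an uneroded 5-px
truth disk would measure the erosion, not the detection.

## Quality testing

Each mean spectrum gets five statistics (`compute_qt_metrics()`), all
built from the plain successive-difference first derivative — quality
testing precedes smoothing in the pipeline, so no Savitzky–Golay here:

| statistic | window (cm⁻¹) | meaning |
|---|---|---|
| `qt_absorbance` | full range | mean absorbance (sample amount) |
| `S1` | 1600–1700 | amide-I signal (max−min of 1st derivative) |
| `S2` | 960–1260 | sugar-ring/phosphate signal |
| `N` | 2000–2100 | noise, from the spectroscopically silent region |
| `WVC` | 1837–1847 | water-vapor rotational-line contamination |

plus the ratios `snr1 = S1/N`, `snr2 = S2/N`, `swr1 = S1/WVC`,
`swr2 = S2/WVC`. Cutoffs are calibrated on a reference set
(`calibrate_qt()`): absorbance mean ± 5 sd, each ratio mean ± 1 sd
(sample sd). The rejection rule is configurable because the underlying
convention is genuinely ambiguous; the defaults are `two_sided` (reject
outside the ± 1 sd interval) and `both` (a pair of ratios must *both*
offend). A literal "reject only when equal to mean ± 1 sd" would reject
almost nothing; `low_only`/`any` variants are exposed and recorded.

One pipeline-level choice deserves emphasis: **cutoffs are calibrated
per segment kind**. The noise of a mean spectrum scales with the pixel
count of its segment, so whole-cell spectra (hundreds of pixels) have
systematically higher SNR than nucleus spectra (tens of pixels). Cutoffs
calibrated on one population and applied to another reject the *cleaner*
population wholesale under a two-sided rule — on phantom studies,
nucleus+cytoplasm-calibrated cutoffs rejected ~90 % of whole-cell
spectra for being too good. Judging each record against its own segment
population keeps the screen meaningful for all three compartments.

Note the WVC window spans 10 cm⁻¹: at the native 2 cm⁻¹ axis step it
holds 5–6 points, the minimum for a meaningful derivative range. Axes
coarser than ~4 cm⁻¹ cannot support this quality test, which is why the
package keeps the 2 cm⁻¹ step even in scaled-down simulations.

## Preprocessing

`preprocess()` = crop to 900–4000 cm⁻¹ (closed interval, as all windows
in this package) → Savitzky–Golay second derivative (window 21 points,
polynomial order 2) → vector normalization to unit Euclidean norm.
Numerical choices:

* Smoothing and differentiation are fused in one least-squares
  convolution — mathematically identical to smooth-then-differentiate
  with the same window and order.
* Derivatives are taken with respect to wavenumber (cm⁻¹), not point
  index, so results are independent of axis spacing and storage
  direction; the axis must be uniform within 1 % (resampling is the
  caller's job).
* The output is trimmed to the interior points where the window fits
  entirely (length − 20 points for the default window). No polynomial
  edge extrapolation: edge artifacts must not enter the classifier.
* True sign convention: absorption peaks become minima.
* Normalization runs over the full retained range once;
  `display_regions()` then crops the lipid-rich (2800–3050 cm⁻¹) and
  fingerprint (900–1800 cm⁻¹) views without renormalizing.

The operator is exact on polynomials up to the fit order (a ν² input
returns exactly 2), annihilates constant and linear baselines, and
commutes with positive scaling once normalization is applied — these
are the package's acceptance properties. For oscillatory signals the
filter attenuates: at 2 cm⁻¹ step and window 21, a sin(ων) input is
reproduced within 2 % for ω ≤ 0.02 rad·cm but attenuated by ~8 % at
ω = 0.05 rad·cm (measured against the analytic derivative). That is the
price of the 21-point smoothing and the reason sharp features (water
vapor lines) remain prominent after differentiation.

## Classification and statistics

Embeddings are 2-D: PCA (`pca_embed()`, deterministic sign convention,
explained-variance fractions and loadings returned) or UMAP
(`umap_embed()`, n_neighbors 15, min_dist 0.1, seeded and
single-threaded, hence bit-reproducible). The silhouette score is
computed on the 2-D embedding by default — the embedding is what the
cluster claim is about — with per-point widths
s(i) = (b−a)/max(a,b), singleton clusters contributing 0. The
permutation test fixes the coordinates, permutes class labels B = 999
times and reports p = (1 + #{S_perm ≥ S_obs})/(B+1), so p is never 0 and
perfect separation gives p = 0.001.

kNN classification runs on the full preprocessed second-derivative
vectors (Euclidean), not the embedding — the spectra are the
measurement; the embedding is a view. Default k_nn = 5 (odd, so no vote
ties in two-class problems), 3-fold seeded cross validation, held-out
predictions pooled into one confusion matrix (TP/TN/FP/FN with disease
positive), from which accuracy, sensitivity = TP/(TP+FN) and
specificity = TN/(TN+FP) follow; undefined ratios are reported `NA`,
never 0.

## The phantom generator

`generate_tile()` emulates one FPA acquisition: 128×128 pixels at
5.5 µm, 4000–800 cm⁻¹ at 2 cm⁻¹ step. Cells are non-overlapping random
disks (radius 7–12 px) with concentric nuclei (radius fraction 0.5);
compartment spectra are sums of Gaussian bands at the standard cellular
assignments (amide A/I/II, CH₂/CH₃ stretches, ester C=O 1740, δCH 1455,
PO₂⁻ 1240/1085, sugar 1050), with nuclei carrying stronger amide and
nucleic-acid bands (hence brighter amide-I images) and cytoplasm
carrying the lipid bands. The disease class multiplies the lipid-band
amplitudes (bands in 2800–3050, 1730–1750, 1445–1465 cm⁻¹) of the
target compartment (cytoplasm by default) by (1 + `lipid_effect`);
`lipid_effect = 0.05` and pixel noise sd 0.002 are the study conditions
used throughout the tests. On top: a per-tile linear baseline
(offset 0.02–0.05, slope ±2×10⁻⁶ per cm⁻¹), a mild spatial illumination
gradient (exercises the local thresholding), a fixed water-vapor line
pattern (σ 1.3 cm⁻¹, one line at 1842 cm⁻¹ inside the WVC window) with
per-tile random amplitude, per-cell thickness scaling 0.92–1.08 (removed
later by vector normalization), and i.i.d. Gaussian pixel noise.
Everything is reproducible from one seed; studies
(`generate_study()`) record per-tile seeds in a manifest and regenerate
tiles on demand, or write ENVI cubes plus truth masks to disk.

What the phantom does *not* emulate — and therefore what passing tests
do not show about real data: realistic astrocyte morphology (disks
only), Mie and resonant-Mie scattering, detector-correlated noise,
fixation chemistry, substrate/coating signatures, storage drift, or
mosaicking across tiles. The phantom validates the *algorithms*
(segmentation recovery, screen behaviour, statistical calibration,
end-to-end signal recovery), not instrument physics.

One emergent property worth knowing: the per-tile water-vapor amplitude
is a batch effect shared by all cells of a tile, and narrow lines are
amplified by differentiation. In small studies (2 tiles per class) the
batch occasionally confounds with class, and single null replicates can
reach nominally significant p — the same vulnerability a real two-slide
study has. Across many independent null replicates the permutation test
is calibrated (measured type-I ≈ 3–7 % at α = 0.05); more tiles per
class dilute the confounding.

## Problem sizes used in the shipped tests

Unit tests use 64×64 tiles with 6–8 cells. The acceptance suite runs
segmentation recovery on 20 default-geometry tiles, the end-to-end
study at 2 classes × 4 tiles × 15 cells (60 cells per class, the
condition for the headline metrics), and the null control at 20
replicates of a reduced 64×64 geometry — chosen so the whole suite
stays desk-scale while every claim is still computed, never assumed.
The 2 cm⁻¹ axis step is kept everywhere (see the WVC note above).

## Limitations

* Mean spectra per segment are the unit of classification; per-pixel
  classification is supported by the QT stage in principle but not
  wired through the pipeline.
* No atmospheric or scattering correction — the quality test screens
  contaminated spectra instead of correcting them.
* Multi-class studies are handled pairwise (one-vs-one reports), not by
  a single multi-class classifier.
* The seeded watershed follows `EBImage::propagate`'s regularized
  metric; for uniform-intensity regions it reduces to the Voronoi
  partition of the seeds, which is the behaviour the tests pin down.

## A minimal worked run

```{r example, eval = FALSE}
cfg <- phantom_config()                      # the study conditions
study <- generate_study(cfg, n_tiles_per_class = 4, seed = 1)
tab <- compare_segments(study, pipeline_config(seed = 1))
tab   # one row per compartment: S, permutation p, accuracy, sens, spec
```
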