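# spectrapheno

Disease-class prediction from hyperspectral FTIR images of cultured
cells — "spectral phenotyping". Every pixel of a mid-infrared
hyperspectral tile carries a full absorbance spectrum (4000–800 cm⁻¹)
whose bands integrate the cell's protein, lipid, nucleic-acid and
carbohydrate chemistry. This package turns a set of such tiles for two
cell groups (e.g. disease vs control) into a per-cell chemical
classifier, and quantifies *which subcellular compartment* — whole
cell, cytoplasm, or nucleus — carries the discriminating signal. It is
aimed at spectroscopists and image analysts working with FPA-FTIR
microscopy of cells.

## Pipeline

1. **Segmentation.** Each cube is reduced to an amide-I intensity image
   (trapezoidal integral over 1630–1670 cm⁻¹). Cells are found by local
   (disk-neighbourhood) Otsu thresholding, nuclei by a second Otsu pass
   over the cell foreground; nucleus centroids seed a watershed that
   splits touching cells; cytoplasm = cell − nucleus, and both
   sub-segments are eroded by 2 px. A mean spectrum is extracted per
   cell segment.
2. **Quality test.** Per spectrum: mean absorbance A; first-derivative
   ranges S1 (amide I, 1600–1700 cm⁻¹), S2 (sugar-ring, 960–1260 cm⁻¹),
   N (noise, silent 2000–2100 cm⁻¹ region), WVC (water vapor,
   1837–1847 cm⁻¹); ratios SNRᵢ = Sᵢ/N and SWRᵢ = Sᵢ/WVC. Cutoffs are
   calibrated on the study itself (A: mean ± 5σ; ratios: mean ± 1σ) and
   spectra failing the screen are dropped.
3. **Preprocessing.** Crop to 900–4000 cm⁻¹, Savitzky–Golay second
   derivative (21 points, order 2, with respect to cm⁻¹), vector
   normalization to unit Euclidean norm.
4. **Classification and statistics.** 2-D UMAP (or PCA) embedding;
   silhouette score S ∈ [−1, 1] with per-point
   s(i) = (b(i)−a(i))/max(a(i), b(i)); label-permutation p-value
   p = (1 + #{S_perm ≥ S_obs})/(B+1), B = 999; kNN (k = 5, Euclidean,
   on the full second-derivative vectors) under 3-fold cross
   validation, pooled into a confusion matrix with disease positive:
   A = (TP+TN)/(TP+TN+FP+FN), SEN = TP/(TP+FN), SPEC = TN/(TN+FP).

A synthetic **phantom generator** emulates FPA tiles (128×128 px,
5.5 µm, 2 cm⁻¹ step) of disk-shaped cells with lipid-rich cytoplasm and
amide-bright nuclei, a class-dependent lipid-band amplitude shift,
noise, baseline drift and water-vapor lines — with ground-truth masks,
so the whole pipeline is testable without instrument data.

## Worked example

```r
library(spectrapheno)

cfg <- phantom_config()        # 2 classes, lipid effect 0.05 in cytoplasm,
                               # pixel noise 0.002, 15 cells per 128x128 tile
study <- generate_study(cfg, n_tiles_per_class = 4, seed = 1)  # 60 cells/class
tab <- compare_segments(study, pipeline_config(seed = 1))
tab
#>     segment  n          S permutation_p  accuracy sensitivity specificity
#> 1      cell 70 0.93086824         0.001 1.0000000   1.0000000  1.00000000
#> 2 cytoplasm 69 0.96760165         0.001 1.0000000   1.0000000  1.00000000
#> 3   nucleus 73 0.03302970         0.037 0.4931507   0.8974359  0.02941176
```

Reading the table: `n` is the number of per-cell mean spectra that
survived the quality screen. Whole-cell and cytoplasm spectra separate
the two classes cleanly (silhouette ≈ 0.93–0.97, permutation p at its
floor of 0.001, perfect cross-validated confusion metrics), while the
nuclear segment — whose band amplitudes are identical between classes
in this phantom — classifies at chance. The simulated disease effect
lives in cytoplasmic lipid bands, and the analysis recovers exactly
that compartment dependence: choosing the wrong segment destroys an
otherwise strong chemical signature.

Single-tile pieces are available individually: `segment_cube()`,
`extract_mean_spectra()`, `compute_qt_metrics()` / `calibrate_qt()` /
`apply_qt()`, `preprocess()`, `umap_embed()` / `pca_embed()`,
`silhouette_score()`, `permutation_test()`, `knn_crossval()`. Cubes
read/write as ENVI header+raster (`read_envi_cube()`,
`write_envi_cube()`), spectra as delimited tables
(`read_spectra_table()`, `write_spectra_table()`). A thin CLI wrapper
with `phantom`/`segment`/`qt`/`preprocess`/`classify`/`run` subcommands
ships in `inst/cli/spectrapheno`.

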