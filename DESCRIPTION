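Package: spectrapheno
Title: Spectral Phenotyping of Cells from Hyperspectral FTIR Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for disease-class prediction from
    hyperspectral Fourier transform infrared (FTIR) images of cultured
    cells. Reduces each hyperspectral tile to an amide-I intensity image,
    segments whole cells, nuclei and cytoplasm by local Otsu thresholding
    and seeded watershed, extracts per-segment mean absorbance spectra,
    screens them with calibrated signal-to-noise and water-vapor quality
    tests, converts survivors to vector-normalized Savitzky-Golay second
    derivatives, and classifies them by k-nearest-neighbour cross
    validation with PCA/UMAP embeddings, silhouette scores and label
    permutation tests. Includes a synthetic phantom generator that
    emulates focal-plane-array FTIR tiles with known ground-truth masks
    and class-dependent lipid-band differences, so every stage is
    testable without instrument data. Reads and writes ENVI header/raster
    cubes and delimited spectra tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    signal,
    class,
    uwot,
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
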