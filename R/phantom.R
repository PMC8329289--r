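# Synthetic hyperspectral phantom: FPA-style FTIR tiles of disk-shaped
# cells with concentric nuclei, Gaussian-band absorbance models for each
# subcellular compartment, class-dependent lipid-band amplitudes,
# additive Gaussian noise, baseline drift and narrow water-vapor lines.
# Ground-truth masks make every pipeline stage testable without
# instrument data.

#' A Gaussian absorbance band
#'
#' @param center band centre in cm^-1.
#' @param width Gaussian sigma in cm^-1 (> 0).
#' @param amplitude peak absorbance (>= 0).
#' @return a one-row data.frame.
#' @export
band_spec <- function(center, width, amplitude) {
  stopifnot(width > 0, amplitude >= 0)
  data.frame(center = center, width = width, amplitude = amplitude)
}

#' Default band tables for phantom compartments
#'
#' Band centres follow the standard assignments of a cellular mid-IR
#' spectrum: amide A (~3290), CH3/CH2 stretches (2960/2925/2872/2852),
#' ester carbonyl (1740), amide I/II (1655/1545), CH bending (1455),
#' COO- (1395), PO2- asymmetric/symmetric (1240/1085) and sugar-ring
#' (1050) modes. Nuclei carry stronger amide and nucleic-acid bands
#' (hence brighter amide-I images); cytoplasm is lipid-rich. Amplitudes
#' are phantom choices, documented here as the generator's defaults.
#'
#' @param segment `"nucleus"` or `"cytoplasm"`.
#' @return a data.frame with columns `center`, `width`, `amplitude`.
#' @export
default_band_table <- function(segment = c("nucleus", "cytoplasm")) {
  segment <- match.arg(segment)
  if (segment == "nucleus")
    data.frame(
      center    = c(3290, 2960, 2925, 2872, 2852, 1740, 1655, 1545,
                    1455, 1395, 1240, 1085, 1050),
      width     = c(60,   14,   14,   12,   11,   8,    18,   15,
                    8,    9,    14,   14,   12),
      amplitude = c(0.28, 0.09, 0.11, 0.05, 0.07, 0.02, 0.80, 0.45,
                    0.09, 0.08, 0.22, 0.26, 0.18))
  else
    data.frame(
      center    = c(3290, 2960, 2925, 2872, 2852, 1740, 1655, 1545,
                    1455, 1395, 1240, 1085, 1050),
      width     = c(60,   14,   14,   12,   11,   8,    18,   15,
                    8,    9,    14,   14,   12),
      amplitude = c(0.18, 0.14, 0.22, 0.07, 0.12, 0.10, 0.45, 0.25,
                    0.12, 0.06, 0.08, 0.10, 0.08))
}

# lipid windows in which the disease effect acts
.lipid_windows <- rbind(c(2800, 3050), c(1730, 1750), c(1445, 1465))

is_lipid_band <- function(center) {
  any(center >= .lipid_windows[, 1] & center <= .lipid_windows[, 2])
}

#' Evaluate a Gaussian band model
#'
#' `absorbance(v) = offset + slope * v + sum a_k exp(-(v - c_k)^2 / (2 w_k^2))`.
#'
#' @param wavenumber wavenumber axis in cm^-1.
#' @param bands data.frame with `center`, `width`, `amplitude` columns
#'   (may have zero rows).
#' @param baseline_offset,baseline_slope linear baseline parameters.
#' @return an [ir_spectrum()].
#' @export
band_model <- function(wavenumber, bands, baseline_offset = 0,
                       baseline_slope = 0) {
  wavenumber <- wavenumber_axis(wavenumber)
  y <- baseline_offset + baseline_slope * wavenumber
  if (nrow(bands))
    for (j in seq_len(nrow(bands)))
      y <- y + bands$amplitude[j] *
        exp(-(wavenumber - bands$center[j])^2 / (2 * bands$width[j]^2))
  ir_spectrum(wavenumber, y)
}

# fixed water-vapor line pattern (relative amplitudes); one line sits
# inside the 1837-1847 cm^-1 WVC window
.wv_lines <- data.frame(
  center = c(3853, 3744, 3649, 1918, 1870, 1842, 1812, 1772),
  width  = rep(1.3, 8),
  rel    = c(0.5, 0.7, 0.4, 0.5, 0.8, 1.0, 0.7, 0.5))

#' Phantom study configuration
#'
#' Defaults emulate the acquisition geometry of a focal-plane-array FTIR
#' microscope: 128 x 128 pixel tiles at 5.5 um pitch, a 4000-800 cm^-1
#' axis at 2 cm^-1 step, disk-shaped cells with concentric nuclei, a
#' two-class design in which the disease class differs only in
#' cytoplasmic lipid-band amplitudes, plus pixel noise, baseline drift,
#' a mild spatial illumination gradient and narrow water-vapor lines.
#'
#' @param rows,cols tile size in pixels.
#' @param wavenumber axis in cm^-1 (descending by default).
#' @param n_cells cells per tile.
#' @param cell_radius_px min/max cell radius in pixels.
#' @param nucleus_radius_fraction nucleus radius as a fraction of the
#'   cell radius (in (0, 1)).
#' @param class_labels the two class names (control first).
#' @param disease_class which label receives the lipid effect.
#' @param lipid_effect fractional amplitude shift of lipid bands
#'   (2800-3050, 1740, 1455 cm^-1) in the disease class (default 0.05).
#' @param effect_target compartment carrying the effect
#'   (`"cytoplasm"` default, or `"nucleus"`).
#' @param noise_sd i.i.d. Gaussian noise sd per pixel per point
#'   (absorbance units, default 0.002).
#' @param baseline_offset_range,baseline_slope_range per-tile baseline
#'   parameter ranges (offset in absorbance, slope per cm^-1).
#' @param spatial_gradient per-pixel illumination gradient magnitude
#'   (absorbance per pixel), drawn uniformly in +/- this value per axis.
#' @param water_vapor_amplitude peak absorbance scale of the shared
#'   water-vapor line pattern; each tile draws a random fraction of it.
#' @param cell_scale_range per-cell multiplicative amplitude range
#'   (thickness variation; removed later by vector normalization).
#' @param nucleus_bands,cytoplasm_bands band tables; defaults from
#'   [default_band_table()].
#' @param pixel_size_um pixel pitch in micrometres.
#' @param seed default seed for generation.
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(rows = 128L, cols = 128L,
                           wavenumber = seq(4000, 800, by = -2),
                           n_cells = 15L,
                           cell_radius_px = c(7, 12),
                           nucleus_radius_fraction = 0.5,
                           class_labels = c("WT", "HD"),
                           disease_class = "HD",
                           lipid_effect = 0.05,
                           effect_target = c("cytoplasm", "nucleus"),
                           noise_sd = 0.002,
                           baseline_offset_range = c(0.02, 0.05),
                           baseline_slope_range = c(-2e-6, 2e-6),
                           spatial_gradient = 1.5e-4,
                           water_vapor_amplitude = 0.002,
                           cell_scale_range = c(0.92, 1.08),
                           nucleus_bands = default_band_table("nucleus"),
                           cytoplasm_bands = default_band_table("cytoplasm"),
                           pixel_size_um = 5.5,
                           seed = 0L) {
  stopifnot(rows >= 8, cols >= 8, n_cells >= 1,
            length(cell_radius_px) == 2, cell_radius_px[1] > 0,
            nucleus_radius_fraction > 0, nucleus_radius_fraction < 1,
            length(class_labels) >= 2, disease_class %in% class_labels,
            noise_sd >= 0, water_vapor_amplitude >= 0)
  if (max(cell_radius_px) * 2 + 4 > min(rows, cols))
    stop("cell radius does not fit in the tile")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 wavenumber = wavenumber_axis(wavenumber),
                 n_cells = as.integer(n_cells),
                 cell_radius_px = cell_radius_px,
                 nucleus_radius_fraction = nucleus_radius_fraction,
                 class_labels = class_labels,
                 disease_class = disease_class,
                 lipid_effect = lipid_effect,
                 effect_target = match.arg(effect_target),
                 noise_sd = noise_sd,
                 baseline_offset_range = baseline_offset_range,
                 baseline_slope_range = baseline_slope_range,
                 spatial_gradient = spatial_gradient,
                 water_vapor_amplitude = water_vapor_amplitude,
                 cell_scale_range = cell_scale_range,
                 nucleus_bands = nucleus_bands,
                 cytoplasm_bands = cytoplasm_bands,
                 pixel_size_um = pixel_size_um,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# band table with lipid bands scaled by (1 + effect)
apply_lipid_effect <- function(bands, effect) {
  if (effect == 0) return(bands)
  lipid <- vapply(bands$center, is_lipid_band, logical(1))
  bands$amplitude[lipid] <- bands$amplitude[lipid] * (1 + effect)
  bands
}

# the noiseless compartment spectra of one class (no baseline)
phantom_class_spectra <- function(config, class_label) {
  diseased <- identical(class_label, config$disease_class)
  nuc <- config$nucleus_bands
  cyt <- config$cytoplasm_bands
  if (diseased && config$effect_target == "nucleus")
    nuc <- apply_lipid_effect(nuc, config$lipid_effect)
  if (diseased && config$effect_target == "cytoplasm")
    cyt <- apply_lipid_effect(cyt, config$lipid_effect)
  list(nucleus = band_model(config$wavenumber, nuc)$absorbance,
       cytoplasm = band_model(config$wavenumber, cyt)$absorbance)
}

#' Generate one phantom tile with ground truth
#'
#' Places non-overlapping random disk cells with concentric nucleus
#' disks, assigns compartment spectra from the Gaussian band model (with
#' the lipid effect applied to the disease class), adds a per-tile
#' linear baseline, a spatial illumination gradient, a shared
#' water-vapor line pattern with per-tile random amplitude, per-cell
#' thickness scaling and i.i.d. Gaussian noise. Fully reproducible from
#' the seed.
#'
#' @param config a [phantom_config()].
#' @param class_label class of the tile's cells.
#' @param seed random seed (defaults to the config seed).
#' @return a list of class `phantom_tile`: `cube` ([hyper_cube()]),
#'   `truth` (a `segmentation_result` of the uneroded true masks plus
#'   `noiseless` compartment spectra and per-cell geometry), and
#'   `class_label`.
#' @export
generate_tile <- function(config, class_label, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"),
            class_label %in% config$class_labels)
  set.seed(as.integer(seed))
  rows <- config$rows; cols <- config$cols
  nu <- config$wavenumber; nb <- length(nu)

  # --- cell geometry: rejection-sampled non-overlapping disks ---
  centers <- matrix(0, 0, 2); radii <- numeric(0)
  tries <- 0L; max_tries <- 300L * config$n_cells
  while (nrow(centers) < config$n_cells) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("placement error: cannot place ", config$n_cells,
           " non-overlapping cells; reduce n_cells or cell_radius_px")
    r <- runif(1, config$cell_radius_px[1], config$cell_radius_px[2])
    cr <- runif(1, r + 2, rows - r - 1)
    cc <- runif(1, r + 2, cols - r - 1)
    if (nrow(centers)) {
      d <- sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2)
      if (any(d < radii + r + 2)) next
    }
    centers <- rbind(centers, c(cr, cc)); radii <- c(radii, r)
  }
  rr <- matrix(seq_len(rows), rows, cols)
  cc_m <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  cell_lab <- matrix(0L, rows, cols)
  nuc_lab <- matrix(0L, rows, cols)
  for (k in seq_len(config$n_cells)) {
    d2 <- (rr - centers[k, 1])^2 + (cc_m - centers[k, 2])^2
    cell_lab[d2 <= radii[k]^2] <- k
    nuc_lab[d2 <= (radii[k] * config$nucleus_radius_fraction)^2] <- k
  }
  cyt_lab <- cell_lab * (nuc_lab == 0L)

  # --- spectra ---
  base <- phantom_class_spectra(config, class_label)
  offset <- runif(1, config$baseline_offset_range[1],
                  config$baseline_offset_range[2])
  slope <- runif(1, config$baseline_slope_range[1],
                 config$baseline_slope_range[2])
  gx <- runif(1, -config$spatial_gradient, config$spatial_gradient)
  gy <- runif(1, -config$spatial_gradient, config$spatial_gradient)
  wv_amp <- runif(1, 0.3, 1) * config$water_vapor_amplitude
  wv <- numeric(nb)
  for (j in seq_len(nrow(.wv_lines)))
    wv <- wv + .wv_lines$rel[j] *
      exp(-(nu - .wv_lines$center[j])^2 / (2 * .wv_lines$width[j]^2))
  wv <- wv * wv_amp
  scales <- runif(config$n_cells, config$cell_scale_range[1],
                  config$cell_scale_range[2])

  npx <- rows * cols
  mat <- matrix(rnorm(npx * nb, sd = config$noise_sd), npx, nb)
  offset_map <- offset + gy * (rr - rows / 2) + gx * (cc_m - cols / 2)
  mat <- mat + as.vector(offset_map)          # recycled down columns
  mat <- mat + rep(slope * nu + wv, each = npx)
  for (k in seq_len(config$n_cells)) {
    for (seg in c("nucleus", "cytoplasm")) {
      lab <- if (seg == "nucleus") nuc_lab else cyt_lab
      idx <- which(lab == k)
      if (length(idx))
        mat[idx, ] <- mat[idx, ] + rep(base[[seg]] * scales[k],
                                       each = length(idx))
    }
  }
  cube <- hyper_cube(array(mat, c(rows, cols, nb)), nu,
                     pixel_size_um = config$pixel_size_um)
  truth <- segmentation_result(cell_lab, nuc_lab, cyt_lab,
                               seeds = cbind(row = as.integer(round(centers[, 1])),
                                             col = as.integer(round(centers[, 2]))))
  truth$noiseless <- base
  truth$cells <- data.frame(cell_id = seq_len(config$n_cells),
                            row = centers[, 1], col = centers[, 2],
                            radius = radii, scale = scales)
  truth$baseline <- list(offset = offset, slope = slope,
                         gx = gx, gy = gy, wv_amp = wv_amp)
  structure(list(cube = cube, truth = truth, class_label = class_label,
                 seed = as.integer(seed)),
            class = "phantom_tile")
}

# deterministic per-tile seed derivation, kept inside 32-bit range
tile_seed <- function(seed, class_index, tile_index) {
  as.integer((as.numeric(seed) %% 1e6) * 1000 +
               class_index * 211 + tile_index * 7)
}

#' Generate a multi-tile phantom study
#'
#' Builds a manifest of tiles (per class) with deterministic per-tile
#' seeds. Tiles are not kept in memory: they are regenerated on demand
#' from their seed via [study_tile()], or, when `dir` is given, written
#' to disk as ENVI cubes plus truth label tables and re-read from there.
#'
#' @param config a [phantom_config()].
#' @param n_tiles_per_class tiles per class.
#' @param seed study seed from which tile seeds are derived.
#' @param dir optional output directory for ENVI cubes, truth masks and
#'   a manifest CSV.
#' @return a list of class `phantom_study` with `manifest` (tile id,
#'   sample id, class, seed, path) and `config`.
#' @export
generate_study <- function(config, n_tiles_per_class = 2L, seed = 0L,
                           dir = NULL) {
  classes <- config$class_labels
  man <- expand.grid(tile = seq_len(n_tiles_per_class),
                     class_label = classes, stringsAsFactors = FALSE)
  man <- data.frame(tile_id = seq_len(nrow(man)),
                    sample_id = paste0(man$class_label, "_tile",
                                       man$tile),
                    class_label = man$class_label,
                    seed = mapply(tile_seed, seed,
                                  match(man$class_label, classes),
                                  man$tile),
                    path = NA_character_)
  study <- structure(list(manifest = man, config = config,
                          dir = dir), class = "phantom_study")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(man))) {
      tile <- generate_tile(config, man$class_label[i], man$seed[i])
      hdr <- file.path(dir, paste0(man$sample_id[i], ".hdr"))
      write_envi_cube(tile$cube, hdr)
      for (seg in c("cell", "nucleus", "cytoplasm"))
        utils::write.csv(tile$truth[[paste0(seg, "_labels")]],
                         file.path(dir, paste0(man$sample_id[i], "_",
                                               seg, "_truth.csv")),
                         row.names = FALSE)
      study$manifest$path[i] <- hdr
    }
    utils::write.csv(study$manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  study
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf("<phantom_study> %d tiles (%s)%s\n", nrow(x$manifest),
              paste(unique(x$manifest$class_label), collapse = " vs "),
              if (is.null(x$dir)) "" else paste0(" in ", x$dir)))
  invisible(x)
}

#' Materialize one tile of a study
#'
#' Reads the tile from disk when the study was written out, otherwise
#' regenerates it deterministically from its recorded seed.
#'
#' @param study a `phantom_study`.
#' @param i manifest row index.
#' @return a `phantom_tile` (for disk-backed studies the truth component
#'   is omitted; the cube is read back from ENVI).
#' @export
study_tile <- function(study, i) {
  row <- study$manifest[i, ]
  if (!is.na(row$path)) {
    cube <- read_envi_cube(row$path)
    structure(list(cube = cube, truth = NULL,
                   class_label = row$class_label, seed = row$seed),
              class = "phantom_tile")
  } else {
    generate_tile(study$config, row$class_label, row$seed)
  }
}
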