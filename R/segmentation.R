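# Subcellular segmentation of hyperspectral FTIR tiles: amide-I band
# integration, local Otsu thresholding, seeded watershed, nucleus/cytoplasm
# derivation, and per-segment mean spectrum extraction.

#' Segmentation parameters
#'
#' @param band_lo,band_hi amide-I integration window in cm^-1
#'   (default 1630-1670, the protein C=O stretch that gives the strongest
#'   cell/background contrast).
#' @param otsu_disk_radius_px radius of the disk neighbourhood for local
#'   Otsu thresholding, in pixels.
#' @param min_object_px connected components smaller than this are treated
#'   as debris and removed (default 16).
#' @param erosion_radius_px Euclidean erosion radius applied to nucleus and
#'   cytoplasm segments (default 2 px) to sharpen segment boundaries.
#' @param nucleus_strategy `"global_otsu"` (default): nuclei are in-cell
#'   pixels above a second Otsu threshold computed over cell-foreground
#'   intensities only; `"local_otsu"`: a second local-Otsu pass with
#'   `nucleus_disk_radius_px`.
#' @param nucleus_disk_radius_px disk radius for the `"local_otsu"` nucleus
#'   strategy.
#' @param n_bins histogram bins for Otsu thresholding (default 256).
#' @return a list of class `segmentation_config`.
#' @export
segmentation_config <- function(band_lo = 1630, band_hi = 1670,
                                otsu_disk_radius_px = 25,
                                min_object_px = 16L,
                                erosion_radius_px = 2,
                                nucleus_strategy = c("global_otsu",
                                                     "local_otsu"),
                                nucleus_disk_radius_px = 8,
                                n_bins = 256L) {
  stopifnot(band_lo < band_hi, otsu_disk_radius_px >= 1,
            erosion_radius_px >= 0, min_object_px >= 0)
  structure(list(band_lo = band_lo, band_hi = band_hi,
                 otsu_disk_radius_px = otsu_disk_radius_px,
                 min_object_px = as.integer(min_object_px),
                 erosion_radius_px = erosion_radius_px,
                 nucleus_strategy = match.arg(nucleus_strategy),
                 nucleus_disk_radius_px = nucleus_disk_radius_px,
                 n_bins = as.integer(n_bins)),
            class = "segmentation_config")
}

#' Integrate a cube over a wavenumber band
#'
#' Per-pixel trapezoidal integral of absorbance over the closed window
#' `[lo, hi]` with respect to wavenumber, giving a high-contrast 2-D
#' intensity image (units absorbance * cm^-1). With the default amide-I
#' window this is the image used for all downstream thresholding.
#'
#' @param cube a [hyper_cube()].
#' @param lo,hi band limits in cm^-1.
#' @return a rows x cols numeric matrix.
#' @export
integrate_band <- function(cube, lo, hi) {
  stopifnot(inherits(cube, "hyper_cube"))
  idx <- axis_window(cube$wavenumber, lo, hi)
  if (length(idx) < 2L)
    stop("range error: band contains fewer than 2 axis points")
  nu <- cube$wavenumber[idx]
  # trapezoid weights; axis is stored descending, integral taken over
  # increasing wavenumber so the result is positive
  h <- abs(diff(nu))
  w <- c(h[1] / 2, (h[-1] + h[-length(h)]) / 2, h[length(h)] / 2)
  d <- dim(cube$data)
  pix <- matrix(cube$data[, , idx], nrow = d[1] * d[2])
  matrix(pix %*% w, nrow = d[1], ncol = d[2])
}

#' Otsu threshold of a numeric sample
#'
#' Histogram-based threshold maximizing the between-class variance.
#' Candidate thresholds are the interior bin edges of an `n_bins`
#' histogram; class statistics are computed from the actual values in
#' each class (not bin midpoints), so the result equals an exhaustive
#' search over all bin-edge splits. Ties are broken toward the lowest
#' qualifying edge. The partition convention is `value <= t` versus
#' `value > t`; foreground is taken as `value > t`.
#'
#' @param values numeric vector with at least two distinct values.
#' @param n_bins number of histogram bins (default 256).
#' @param breaks optional explicit bin edges (length `n_bins + 1`),
#'   overriding the min-max binning; values outside are clamped to the
#'   outer bins.
#' @return the threshold, a single numeric value.
#' @export
otsu_threshold <- function(values, n_bins = 256L, breaks = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("degenerate input: need >= 2 finite values")
  if (is.null(breaks)) {
    rng <- range(values)
    if (rng[1] == rng[2])
      stop("degenerate input: all values identical, no Otsu threshold")
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  } else {
    n_bins <- length(breaks) - 1L
  }
  idx <- findInterval(values, breaks, left.open = TRUE)
  idx <- pmin(pmax(idx, 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  sums <- numeric(n_bins)
  agg <- rowsum(values, idx)
  sums[as.integer(rownames(agg))] <- agg
  n0 <- cumsum(counts)[-n_bins]
  s0 <- cumsum(sums)[-n_bins]
  N <- length(values); S <- sum(values)
  valid <- n0 > 0L & n0 < N
  if (!any(valid))
    stop("degenerate input: all values fall in one histogram bin")
  vb <- rep(-Inf, n_bins - 1L)
  vb[valid] <- n0[valid] * (N - n0[valid]) *
    (s0[valid] / n0[valid] - (S - s0[valid]) / (N - n0[valid]))^2
  k <- which.max(vb)  # which.max returns the first (lowest) maximizer
  breaks[k + 1L]
}

disk_kernel <- function(radius) {
  r <- ceiling(radius)
  dr <- -r:r
  k <- outer(dr^2, dr^2, "+") <= radius^2
  storage.mode(k) <- "double"
  k
}

#' Local (dynamic) Otsu foreground mask
#'
#' Each pixel is compared with the Otsu threshold of its disk-shaped
#' neighbourhood (clipped at the image borders, no padding), which
#' tolerates non-uniform backgrounds. Histogram bins are fixed globally
#' over the image range; neighbourhood class statistics are accumulated
#' by convolution, bin by bin, so the per-pixel threshold is identical to
#' calling [otsu_threshold()] on the clipped neighbourhood with the same
#' global bins. Pixels whose neighbourhood is constant (all values in one
#' bin) get no threshold and are classed as background.
#'
#' @param image numeric matrix (e.g. from [integrate_band()]).
#' @param disk_radius_px neighbourhood radius in pixels (>= 1).
#' @param n_bins histogram bins (default 256).
#' @return a logical matrix, `TRUE` = foreground.
#' @export
local_otsu_mask <- function(image, disk_radius_px, n_bins = 256L) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (disk_radius_px < 1) stop("parameter error: disk radius must be >= 1")
  if (disk_radius_px >= max(dim(image)))
    stop("parameter error: disk radius larger than the image")
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warning("constant image: local Otsu mask is empty")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(image, breaks, left.open = TRUE)
  idx <- pmin(pmax(idx, 1L), n_bins)
  kern <- disk_kernel(disk_radius_px)
  pad <- ceiling(disk_radius_px)
  nr <- nrow(image); nc <- ncol(image)
  conv <- function(m) {
    # zero-pad so the kernel always fits; clipped-neighbourhood statistics
    # fall out naturally because padding contributes zero counts
    big <- matrix(0, nr + 2 * pad, nc + 2 * pad)
    big[pad + seq_len(nr), pad + seq_len(nc)] <- m
    EBImage::filter2(big, kern, boundary = 0)[pad + seq_len(nr),
                                              pad + seq_len(nc)]
  }
  ntot <- round(conv(matrix(1, nrow(image), ncol(image))))
  stot <- conv(image)
  cum_n <- matrix(0, nrow(image), ncol(image))
  cum_s <- matrix(0, nrow(image), ncol(image))
  best <- matrix(-Inf, nrow(image), ncol(image))
  thr <- matrix(NA_real_, nrow(image), ncol(image))
  for (b in seq_len(n_bins - 1L)) {
    ib <- matrix(as.numeric(idx == b), nrow(image), ncol(image))
    if (any(ib > 0)) {
      cum_n <- cum_n + round(conv(ib))
      cum_s <- cum_s + conv(ib * image)
    }
    valid <- cum_n > 0 & cum_n < ntot
    vb <- matrix(-Inf, nrow(image), ncol(image))
    vb[valid] <- cum_n[valid] * (ntot[valid] - cum_n[valid]) *
      (cum_s[valid] / cum_n[valid] -
         (stot[valid] - cum_s[valid]) / (ntot[valid] - cum_n[valid]))^2
    upd <- vb > best
    best[upd] <- vb[upd]
    thr[upd] <- breaks[b + 1L]
  }
  mask <- !is.na(thr) & image > thr
  if (!any(mask) && all(is.na(thr)))
    warning("all neighbourhoods degenerate: local Otsu mask is empty")
  mask
}

#' Remove connected components smaller than a pixel count
#'
#' @param mask logical matrix.
#' @param min_px minimum component area in pixels.
#' @return logical matrix with small components removed.
#' @export
remove_small_objects <- function(mask, min_px) {
  if (min_px <= 1L || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Detect watershed seed points from a nucleus mask
#'
#' One seed per connected component of area at least `min_object_px`,
#' placed at the component centroid rounded to the nearest pixel of the
#' component itself (so seeds always lie inside the mask, even for
#' non-convex components).
#'
#' @param nucleus_mask logical matrix.
#' @param min_object_px minimum component area.
#' @return an integer matrix with columns `row`, `col`; zero rows if the
#'   mask is empty.
#' @export
detect_seeds <- function(nucleus_mask, min_object_px = 16L) {
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("row", "col")))
  if (!any(nucleus_mask)) return(empty)
  lab <- EBImage::bwlabel(nucleus_mask * 1)
  px <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[lab > 0]
  areas <- tabulate(ids)
  keep <- which(areas >= min_object_px)
  if (length(keep) == 0L) return(empty)
  out <- matrix(0L, nrow = length(keep), ncol = 2,
                dimnames = list(NULL, c("row", "col")))
  for (j in seq_along(keep)) {
    k <- keep[j]
    pr <- px[ids == k, , drop = FALSE]
    cr <- mean(pr[, 1]); cc <- mean(pr[, 2])
    d2 <- (pr[, 1] - cr)^2 + (pr[, 2] - cc)^2
    out[j, ] <- as.integer(pr[which.min(d2), ])
  }
  out
}

#' Seeded watershed labelling of cells
#'
#' Floods basins from the seed points across the foreground mask on the
#' intensity manifold (bright cell centres become basins); pixels are
#' assigned to exactly one seed, ridge assignment is deterministic, and
#' mask components containing no seed remain background. Implemented with
#' the Voronoi-on-manifold propagation of `EBImage::propagate`.
#'
#' @param image numeric intensity matrix.
#' @param seeds integer matrix with columns `row`, `col`; seed `i` becomes
#'   label `i`.
#' @param region_mask logical matrix of candidate cell pixels; every seed
#'   must lie inside it.
#' @param lambda regularization of `EBImage::propagate`: larger values
#'   weight spatial distance over intensity differences.
#' @return an integer label matrix (0 = background).
#' @export
watershed_cells <- function(image, seeds, region_mask, lambda = 1e-4) {
  stopifnot(is.matrix(image), nrow(seeds) >= 1L)
  if (!all(dim(image) == dim(region_mask)))
    stop("image and mask shapes differ")
  inside <- region_mask[cbind(seeds[, 1], seeds[, 2])]
  if (!all(inside))
    stop("parameter error: seed(s) ",
         paste(which(!inside), collapse = ", "), " outside the region mask")
  seed_img <- matrix(0L, nrow(image), ncol(image))
  seed_img[cbind(seeds[, 1], seeds[, 2])] <- seq_len(nrow(seeds))
  lab <- EBImage::propagate(image, seed_img, mask = region_mask * 1,
                            lambda = lambda)
  matrix(as.integer(round(lab)), nrow(image), ncol(image))
}

# Euclidean erosion: pixels whose distance to the nearest background pixel
# is < radius are removed (distance-transform definition).
erode_disk <- function(mask, radius) {
  if (radius <= 0 || !any(mask)) return(mask)
  d <- EBImage::distmap(mask * 1)
  mask & (d >= radius)
}

#' Derive nucleus and cytoplasm segments from cell labels
#'
#' For each cell `k`: nucleus = nucleus mask within the cell, cytoplasm =
#' cell minus nucleus; both are then eroded by a Euclidean disk of radius
#' `erosion_radius_px` (pixels closer than the radius to the segment
#' boundary are removed) to sharpen nucleus/cytoplasm and cell-cell
#' delineation. Cells whose eroded nucleus or cytoplasm ends up empty are
#' flagged, not silently dropped.
#'
#' @param cell_labels integer label matrix of whole cells.
#' @param nucleus_mask logical matrix of nucleus pixels.
#' @param erosion_radius_px erosion radius (default 2).
#' @param seeds optional seed matrix to carry through to the result.
#' @return a `segmentation_result`: list with `cell_labels`,
#'   `nucleus_labels`, `cytoplasm_labels`, `seeds` and a `flags`
#'   data.frame (`cell_id`, `reason`).
#' @export
derive_segments <- function(cell_labels, nucleus_mask, erosion_radius_px = 2,
                            seeds = NULL) {
  if (!all(dim(cell_labels) == dim(nucleus_mask)))
    stop("label/mask shape mismatch")
  ids <- sort(unique(cell_labels[cell_labels > 0]))
  nuc <- matrix(0L, nrow(cell_labels), ncol(cell_labels))
  cyt <- matrix(0L, nrow(cell_labels), ncol(cell_labels))
  nuc_raw <- matrix(0L, nrow(cell_labels), ncol(cell_labels))
  cyt_raw <- matrix(0L, nrow(cell_labels), ncol(cell_labels))
  flags <- list()
  for (k in ids) {
    cell_k <- cell_labels == k
    nuc_k <- cell_k & nucleus_mask
    cyt_k <- cell_k & !nuc_k
    nuc_raw[nuc_k] <- k
    cyt_raw[cyt_k] <- k
    if (!any(nuc_k))
      flags[[length(flags) + 1L]] <- data.frame(cell_id = k,
                                                reason = "nucleus absent")
    nuc_e <- erode_disk(nuc_k, erosion_radius_px)
    cyt_e <- erode_disk(cyt_k, erosion_radius_px)
    if (any(nuc_k) && !any(nuc_e))
      flags[[length(flags) + 1L]] <-
        data.frame(cell_id = k, reason = "nucleus empty after erosion")
    if (!any(cyt_e))
      flags[[length(flags) + 1L]] <-
        data.frame(cell_id = k, reason = "cytoplasm empty after erosion")
    nuc[nuc_e] <- k
    cyt[cyt_e] <- k
  }
  res <- segmentation_result(cell_labels, nuc, cyt, seeds = seeds,
                             flags = if (length(flags)) do.call(rbind, flags)
                                     else data.frame(cell_id = integer(0),
                                                     reason = character(0)))
  # pre-erosion per-cell partitions: the detection output, kept for
  # evaluation against truth masks (erosion is a spectra-extraction step)
  res$nucleus_labels_raw <- nuc_raw
  res$cytoplasm_labels_raw <- cyt_raw
  res
}

#' Per-cell intersection-over-union against truth masks
#'
#' Matches every truth cell with the predicted label of largest overlap
#' and reports the IoU of the pair; unmatched truth cells score 0.
#' Nucleus and cytoplasm are scored on the pre-erosion detection
#' partitions when available.
#'
#' @param truth,pred `segmentation_result` objects on the same grid
#'   (e.g. phantom truth vs [segment_cube()] output).
#' @return a data.frame with one row per truth cell and columns
#'   `cell_id`, `iou_cell`, `iou_nucleus`.
#' @export
evaluate_segmentation <- function(truth, pred) {
  stopifnot(inherits(truth, "segmentation_result"),
            inherits(pred, "segmentation_result"))
  match_iou <- function(truth_lab, pred_lab, ids) {
    vapply(ids, function(k) {
      tk <- truth_lab == k
      ov <- table(pred_lab[tk & pred_lab > 0])
      if (!length(ov)) return(0)
      pk <- pred_lab == as.integer(names(ov)[which.max(ov)])
      sum(tk & pk) / sum(tk | pk)
    }, numeric(1))
  }
  ids <- sort(unique(truth$cell_labels[truth$cell_labels > 0]))
  pred_nuc <- if (!is.null(pred$nucleus_labels_raw)) pred$nucleus_labels_raw
              else pred$nucleus_labels
  data.frame(cell_id = ids,
             iou_cell = match_iou(truth$cell_labels, pred$cell_labels, ids),
             iou_nucleus = match_iou(truth$nucleus_labels, pred_nuc, ids))
}

#' Bundle cell/nucleus/cytoplasm label images
#'
#' @param cell_labels,nucleus_labels,cytoplasm_labels integer label
#'   matrices sharing one shape; for every cell id its nucleus and
#'   cytoplasm pixels must lie inside the cell and not overlap each other.
#' @param seeds optional seed coordinate matrix.
#' @param flags optional data.frame of per-cell warnings.
#' @return an object of class `segmentation_result`.
#' @export
segmentation_result <- function(cell_labels, nucleus_labels,
                                cytoplasm_labels, seeds = NULL,
                                flags = NULL) {
  stopifnot(all(dim(cell_labels) == dim(nucleus_labels)),
            all(dim(cell_labels) == dim(cytoplasm_labels)))
  if (any((nucleus_labels > 0) & (nucleus_labels != cell_labels)))
    stop("nucleus pixels must lie inside their cell")
  if (any((cytoplasm_labels > 0) & (cytoplasm_labels != cell_labels)))
    stop("cytoplasm pixels must lie inside their cell")
  if (any(nucleus_labels > 0 & cytoplasm_labels > 0))
    stop("nucleus and cytoplasm segments overlap")
  structure(list(cell_labels = cell_labels,
                 nucleus_labels = nucleus_labels,
                 cytoplasm_labels = cytoplasm_labels,
                 seeds = seeds,
                 flags = flags),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  ids <- unique(x$cell_labels[x$cell_labels > 0])
  cat(sprintf("<segmentation_result> %d cells on a %d x %d grid\n",
              length(ids), nrow(x$cell_labels), ncol(x$cell_labels)))
  if (!is.null(x$flags) && nrow(x$flags))
    cat(sprintf("  %d flag(s): %s\n", nrow(x$flags),
                paste(unique(x$flags$reason), collapse = "; ")))
  invisible(x)
}

#' Extract per-segment mean spectra from a cube
#'
#' For each cell and each non-empty segment kind (whole cell, nucleus,
#' cytoplasm) the unweighted arithmetic mean of the member-pixel
#' absorbance vectors. Whole-cell means use the uneroded cell mask.
#' Empty segments are skipped (they are listed in the segmentation
#' flags).
#'
#' @param cube a [hyper_cube()].
#' @param seg a `segmentation_result` spatially aligned with the cube.
#' @param sample_id,class_label provenance recorded on every record.
#' @return a [spectra_set()] with `cell_id`, `segment`, `n_pixels` metadata.
#' @export
extract_mean_spectra <- function(cube, seg, sample_id = "sample",
                                 class_label = "unknown") {
  stopifnot(inherits(cube, "hyper_cube"),
            inherits(seg, "segmentation_result"))
  d <- dim(cube$data)
  if (!all(d[1:2] == dim(seg$cell_labels)))
    stop("cube and segmentation are not spatially aligned")
  pix <- matrix(cube$data, nrow = d[1] * d[2])
  rows <- list(); meta <- list()
  for (kind in c("cell", "nucleus", "cytoplasm")) {
    lab <- seg[[paste0(kind, "_labels")]]
    idx <- which(lab > 0)
    if (length(idx) == 0L) next
    ids <- lab[idx]
    sums <- rowsum(pix[idx, , drop = FALSE], ids)
    counts <- tabulate(ids)[as.integer(rownames(sums))]
    means <- sums / counts
    for (j in seq_len(nrow(means))) {
      rows[[length(rows) + 1L]] <- means[j, ]
      meta[[length(meta) + 1L]] <-
        data.frame(cell_id = as.integer(rownames(sums)[j]), segment = kind,
                   sample_id = sample_id, class_label = class_label,
                   n_pixels = counts[j])
    }
  }
  if (length(rows) == 0L) stop("segmentation contains no labelled pixels")
  spectra_set(do.call(rbind, rows), cube$wavenumber, do.call(rbind, meta))
}

#' Segment a hyperspectral cube end to end
#'
#' Convenience wrapper running the full segmentation chain: amide-I band
#' integration, local Otsu cell mask, debris removal, nucleus detection,
#' seed extraction, seeded watershed, and nucleus/cytoplasm derivation
#' with erosion.
#'
#' @param cube a [hyper_cube()].
#' @param config a [segmentation_config()].
#' @return a `segmentation_result` with the intensity image attached as
#'   attribute `"intensity"`.
#' @export
segment_cube <- function(cube, config = segmentation_config()) {
  intensity <- integrate_band(cube, config$band_lo, config$band_hi)
  cell_mask <- local_otsu_mask(intensity, config$otsu_disk_radius_px,
                               config$n_bins)
  cell_mask <- remove_small_objects(cell_mask, config$min_object_px)
  if (!any(cell_mask)) stop("segmentation found no foreground")
  nuc_mask <- switch(config$nucleus_strategy,
    global_otsu = {
      thr <- otsu_threshold(intensity[cell_mask], config$n_bins)
      cell_mask & intensity > thr
    },
    local_otsu = cell_mask & local_otsu_mask(intensity,
                                             config$nucleus_disk_radius_px,
                                             config$n_bins))
  nuc_mask <- remove_small_objects(nuc_mask, config$min_object_px)
  seeds <- detect_seeds(nuc_mask, config$min_object_px)
  if (nrow(seeds) == 0L) stop("no nucleus seeds detected")
  cells <- watershed_cells(intensity, seeds, cell_mask)
  res <- derive_segments(cells, nuc_mask, config$erosion_radius_px,
                         seeds = seeds)
  attr(res, "intensity") <- intensity
  res
}
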