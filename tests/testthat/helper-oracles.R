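# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive each quantity from its definition, by loops and
# exhaustive search, so they share no code path with the implementation.

# exhaustive Otsu: try every interior bin edge, split the actual values,
# compute the between-class variance directly; first maximum wins
oracle_otsu <- function(values, n_bins = 256L, breaks = NULL) {
  if (is.null(breaks))
    breaks <- seq(min(values), max(values), length.out = n_bins + 1L)
  best <- -Inf; best_t <- NA_real_
  for (t in breaks[2:(length(breaks) - 1L)]) {
    lo <- values[values <= t]; hi <- values[values > t]
    if (!length(lo) || !length(hi)) next
    vb <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (vb > best) { best <- vb; best_t <- t }
  }
  best_t
}

# naive silhouette widths, O(n^2) loops straight from the definition
oracle_silhouette <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (g in setdiff(unique(labels), labels[i])) {
      idx <- which(labels == g)
      b <- min(b, mean(vapply(idx, function(j) d(i, j), numeric(1))))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

# definitional QT metrics for one spectrum, loops and explicit windows
oracle_qt_metrics <- function(wavenumber, absorbance) {
  fd_range <- function(lo, hi) {
    idx <- which(wavenumber >= lo & wavenumber <= hi)
    d <- numeric(length(idx) - 1L)
    for (k in seq_along(d))
      d[k] <- (absorbance[idx[k + 1L]] - absorbance[idx[k]]) /
        (wavenumber[idx[k + 1L]] - wavenumber[idx[k]])
    max(d) - min(d)
  }
  s1 <- fd_range(1600, 1700); s2 <- fd_range(960, 1260)
  nn <- fd_range(2000, 2100); wvc <- fd_range(1837, 1847)
  c(qt_absorbance = mean(absorbance), S1 = s1, S2 = s2, N = nn,
    WVC = wvc,
    snr1 = if (nn > 0) s1 / nn else NA_real_,
    snr2 = if (nn > 0) s2 / nn else NA_real_,
    swr1 = if (wvc > 0) s1 / wvc else NA_real_,
    swr2 = if (wvc > 0) s2 / wvc else NA_real_)
}

# brute-force Euclidean erosion: keep a foreground pixel iff its minimum
# distance to any background pixel is >= radius
oracle_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(fg))) {
    dmin <- sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
    if (dmin >= radius) out[fg[i, 1], fg[i, 2]] <- TRUE
  }
  out
}

# 4-connected component labelling by flood fill (independent of EBImage)
oracle_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- cur
      r <- (p - 1L) %% nrow(mask) + 1L
      cc <- (p - 1L) %/% nrow(mask) + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        nr <- r + d[1]; nc <- cc + d[2]
        if (nr >= 1 && nr <= nrow(mask) && nc >= 1 && nc <= ncol(mask) &&
            mask[nr, nc] && lab[nr, nc] == 0L)
          queue <- c(queue, (nc - 1L) * nrow(mask) + nr)
      }
    }
  }
  lab
}

# a filled disk mask on an r x c grid
disk_mask <- function(rows, cols, center, radius) {
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

# small random smooth-ish spectrum on the standard axis
random_spectrum <- function(nu, seed) {
  set.seed(seed)
  y <- 0.02 + 0.3 * runif(1) +
    0.5 * runif(1) * exp(-(nu - runif(1, 1000, 3800))^2 /
                           (2 * runif(1, 10, 80)^2)) +
    rnorm(length(nu), sd = 0.005)
  y - min(y) + 0.01
}

# reduced phantom geometry used for fast pipeline-level tests
small_phantom_config <- function(n_cells = 8, cell_radius_px = c(5, 8),
                                 ...) {
  phantom_config(rows = 64, cols = 64, n_cells = n_cells,
                 cell_radius_px = cell_radius_px, ...)
}

small_seg_config <- function(...) {
  segmentation_config(otsu_disk_radius_px = 15, min_object_px = 8, ...)
}

small_pipeline_config <- function(seed = 0, ...) {
  pipeline_config(seg = small_seg_config(), n_permutations = 199,
                  k_nn = 3L, seed = seed, ...)
}
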