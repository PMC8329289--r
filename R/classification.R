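# Classification and statistics: PCA/UMAP embedding of preprocessed
# spectra, silhouette scoring with a label permutation test, and
# k-nearest-neighbour classification under k-fold cross validation with
# confusion-matrix metrics (accuracy, sensitivity, specificity; the
# disease class is the positive class).

#' PCA embedding of spectra
#'
#' Column-mean-centred data projected onto the top right-singular
#' directions. Component signs are fixed so that each loading's
#' largest-magnitude entry is positive, making the embedding
#' deterministic. Explained-variance fractions are relative to the total
#' variance.
#'
#' @param spectra numeric matrix, one row per spectrum.
#' @param n_components number of components (default 2); must be at most
#'   `min(n - 1, p)`.
#' @return an `embedding_result`: list with `method`, `coordinates`
#'   (n x d scores), `loadings` (d x p), `explained_variance`, `center`,
#'   `params`.
#' @export
pca_embed <- function(spectra, n_components = 2L) {
  spectra <- as.matrix(spectra)
  n <- nrow(spectra); p <- ncol(spectra)
  if (n < 2L) stop("need at least 2 spectra")
  if (n_components > min(n - 1L, p))
    stop("parameter error: n_components exceeds min(n - 1, p)")
  pc <- stats::prcomp(spectra, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  sco <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(method = "pca",
                 coordinates = unname(sco),
                 loadings = unname(t(rot)),
                 explained_variance = ev[seq_len(n_components)],
                 center = pc$center,
                 seed = NA_integer_,
                 params = list(n_components = n_components)),
            class = "embedding_result")
}

#' UMAP embedding of spectra
#'
#' Two-dimensional uniform manifold approximation and projection, the
#' non-linear neighbourhood-preserving embedding used for cluster
#' display and silhouette scoring. Deterministic for a fixed seed
#' (single-threaded optimization). Coordinates are unitless.
#'
#' @param spectra numeric matrix, one row per spectrum; `nrow` must
#'   exceed `n_neighbors`.
#' @param n_neighbors local neighbourhood size (default 15).
#' @param min_dist minimum embedding distance (default 0.1).
#' @param seed random seed (default 0).
#' @param n_components embedding dimension (default 2).
#' @return an `embedding_result` (no loadings for UMAP).
#' @export
umap_embed <- function(spectra, n_neighbors = 15L, min_dist = 0.1,
                       seed = 0L, n_components = 2L) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) <= n_neighbors)
    stop("parameter error: need more spectra than n_neighbors")
  coords <- uwot::umap(spectra, n_neighbors = n_neighbors,
                       min_dist = min_dist, n_components = n_components,
                       seed = as.integer(seed), n_threads = 1,
                       verbose = FALSE)
  structure(list(method = "umap",
                 coordinates = unname(coords),
                 loadings = NULL,
                 explained_variance = NULL,
                 center = NULL,
                 seed = as.integer(seed),
                 params = list(n_neighbors = n_neighbors,
                               min_dist = min_dist,
                               n_components = n_components)),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %s, %d x %d coordinates\n", x$method,
              nrow(x$coordinates), ncol(x$coordinates)))
  invisible(x)
}

# silhouette widths from a precomputed full distance matrix
silhouette_from_dist <- function(D, labels) {
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 2L) stop("silhouette undefined for a single label")
  sizes <- table(labels)
  # M[i, g] = sum of distances from point i to all points of group g
  M <- t(rowsum(D, labels))
  a <- numeric(nrow(D)); b <- numeric(nrow(D))
  for (i in seq_len(nrow(D))) {
    g <- labels[i]
    ng <- sizes[[g]]
    a[i] <- if (ng > 1L) M[i, g] / (ng - 1L) else 0
    others <- setdiff(groups, g)
    b[i] <- min(M[i, others] / as.numeric(sizes[others]))
  }
  s <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
  # singleton clusters contribute 0 by convention
  s[labels %in% names(sizes)[sizes == 1L]] <- 0
  s
}

#' Silhouette score of labelled points
#'
#' Per point `i`: `a(i)` = mean Euclidean distance to the other points of
#' its own cluster (cohesion; 0 for singleton clusters, whose width is
#' defined as 0), `b(i)` = the smallest over other clusters of the mean
#' distance to that cluster (separation), and
#' `s(i) = (b - a) / max(a, b)`. The score `S` is the mean width, on a
#' -1..1 scale; higher means points sit closer to their own cluster than
#' to the nearest other cluster.
#'
#' @param points numeric matrix of coordinates (n x d), n >= 3.
#' @param labels cluster labels, at least two distinct values.
#' @return a `cluster_report`: list with `S`, per-point `widths`,
#'   `labels`.
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 points")
  if (length(labels) != nrow(points))
    stop("labels must match the number of points")
  D <- as.matrix(stats::dist(points))
  w <- silhouette_from_dist(D, labels)
  structure(list(S = mean(w), widths = w, labels = as.character(labels)),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> S = %.3f over %d points", x$S,
              length(x$widths)))
  if (!is.null(x$permutation_p))
    cat(sprintf(", permutation p = %.4g (B = %d)", x$permutation_p,
                x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Label permutation test of cluster separation
#'
#' Computes the observed silhouette score, then permutes the class
#' labels uniformly `n_permutations` times (coordinates fixed) and
#' reports `p = (1 + #\{S_perm >= S_obs\}) / (n_permutations + 1)`, the
#' add-one estimate that can never be exactly zero. With perfectly
#' separated classes and B = 999, p = 0.001.
#'
#' @param points numeric coordinate matrix.
#' @param labels class labels.
#' @param n_permutations number of permutations (>= 19; default 999).
#' @param seed random seed.
#' @return a `cluster_report` with `S`, `widths`, `permutation_p`,
#'   `n_permutations`, `seed`.
#' @export
permutation_test <- function(points, labels, n_permutations = 999L,
                             seed = 0L) {
  if (n_permutations < 19L) stop("need at least 19 permutations")
  points <- as.matrix(points)
  D <- as.matrix(stats::dist(points))
  w <- silhouette_from_dist(D, labels)
  s_obs <- mean(w)
  set.seed(as.integer(seed))
  s_perm <- vapply(seq_len(n_permutations), function(b)
    mean(silhouette_from_dist(D, sample(labels))), numeric(1))
  p <- (1 + sum(s_perm >= s_obs)) / (n_permutations + 1)
  structure(list(S = s_obs, widths = w, labels = as.character(labels),
                 permutation_p = p,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "cluster_report")
}

#' Confusion-matrix metrics
#'
#' Accuracy = (TP + TN) / (TP + TN + FP + FN), the fraction of correct
#' assignments; sensitivity = TP / (TP + FN), the true-positive rate;
#' specificity = TN / (TN + FP), the true-negative rate. Each is scored
#' from best (1.0) to worst (0). An undefined rate (zero denominator) is
#' reported as `NA`, never silently as 0.
#'
#' @param TP,TN,FP,FN non-negative counts, positive total.
#' @return list with `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(TP, TN, FP, FN) {
  counts <- c(TP, TN, FP, FN)
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("total count is zero")
  list(accuracy = (TP + TN) / total,
       sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_)
}

#' k-nearest-neighbour classification with k-fold cross validation
#'
#' The data are randomly shuffled (seeded) and split into `k_folds`
#' near-equal subsets; for each fold a kNN model (Euclidean distance,
#' majority vote among the `k_nn` nearest training points) trained on
#' the remaining folds predicts the held-out fold. Held-out predictions
#' are pooled into one confusion matrix with the disease class as
#' positive.
#'
#' @param features numeric matrix, one row per spectrum.
#' @param labels class labels (two or more; metrics assume two).
#' @param k_nn number of neighbours (default 5).
#' @param k_folds number of folds (default 3).
#' @param seed random seed for the shuffle.
#' @param positive the positive (disease) class label; defaults to the
#'   alphabetically first label, so set it explicitly for real data.
#' @return a `confusion_report`: list with counts `TP`, `TN`, `FP`,
#'   `FN`, metrics `accuracy`, `sensitivity`, `specificity`, per-point
#'   `assignments`, and the settings used.
#' @export
knn_crossval <- function(features, labels, k_nn = 5L, k_folds = 3L,
                         seed = 0L, positive = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  n <- nrow(features)
  if (length(labels) != n) stop("labels must match rows of features")
  if (n < k_folds) stop("need at least k_folds spectra")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes")
  if (is.null(positive)) positive <- classes[1]
  if (!positive %in% classes) stop("positive class not present in labels")
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(k_folds), n)
  pred <- character(n)
  for (f in seq_len(k_folds)) {
    test <- which(fold == f)
    train <- which(fold != f)
    if (k_nn >= length(train))
      stop("parameter error: k_nn must be smaller than the training size")
    if (length(unique(labels[train])) < length(classes))
      warning("fold ", f, " training set is missing a class")
    pred[test] <- as.character(class::knn(features[train, , drop = FALSE],
                                          features[test, , drop = FALSE],
                                          factor(labels[train]),
                                          k = k_nn))
  }
  is_pos <- labels == positive
  pred_pos <- pred == positive
  TP <- sum(is_pos & pred_pos); FN <- sum(is_pos & !pred_pos)
  TN <- sum(!is_pos & !pred_pos); FP <- sum(!is_pos & pred_pos)
  met <- confusion_metrics(TP, TN, FP, FN)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 accuracy = met$accuracy,
                 sensitivity = met$sensitivity,
                 specificity = met$specificity,
                 assignments = data.frame(index = seq_len(n), fold = fold,
                                          truth = labels,
                                          predicted = pred),
                 k_nn = as.integer(k_nn), k_folds = as.integer(k_folds),
                 seed = as.integer(seed), positive = positive),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf(paste0("<confusion_report> A = %.3f, SEN = %.3f, ",
                     "SPEC = %.3f (TP %d, TN %d, FP %d, FN %d)\n"),
              x$accuracy, x$sensitivity, x$specificity,
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}
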