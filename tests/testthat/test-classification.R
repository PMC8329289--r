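# Embeddings, silhouette/permutation statistics, kNN cross validation
# and confusion metrics.

test_that("PCA recovers a rank-1 direction with all variance on PC1", {
  set.seed(21)
  v <- rnorm(40); v <- v / sqrt(sum(v^2))
  x <- outer(rnorm(30), v) + matrix(5, 30, 40)   # variation only along v
  emb <- pca_embed(x, 2)
  cosine <- abs(sum(emb$loadings[1, ] * v))
  expect_gte(cosine, 0.999)
  expect_equal(emb$explained_variance[1], 1, tolerance = 1e-12)
  expect_equal(colMeans(emb$coordinates), c(0, 0), tolerance = 1e-10)
})

test_that("PCA is invariant to row duplication and reconstructs its input", {
  set.seed(22)
  x <- matrix(rnorm(15 * 8), 15)
  e1 <- pca_embed(x, 3)
  e2 <- pca_embed(rbind(x, x), 3)
  expect_equal(abs(e1$loadings), abs(e2$loadings), tolerance = 1e-8)
  full <- pca_embed(x, 8)
  recon <- full$coordinates %*% full$loadings +
    matrix(full$center, 15, 8, byrow = TRUE)
  expect_equal(recon, x, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_embed(x, 15), "parameter error")
})

test_that("component signs are fixed deterministically", {
  set.seed(23)
  x <- matrix(rnorm(20 * 6), 20)
  e <- pca_embed(x, 4)
  for (j in 1:4)
    expect_gt(e$loadings[j, which.max(abs(e$loadings[j, ]))], 0)
})

test_that("UMAP is deterministic for a fixed seed and validates n", {
  set.seed(24)
  x <- matrix(rnorm(40 * 10), 40)
  e1 <- umap_embed(x, n_neighbors = 10, seed = 5)
  e2 <- umap_embed(x, n_neighbors = 10, seed = 5)
  expect_identical(e1$coordinates, e2$coordinates)
  expect_error(umap_embed(x[1:10, ], n_neighbors = 10), "parameter error")
})

test_that("UMAP separates well-separated classes and not a single blob", {
  set.seed(25)
  a <- matrix(rnorm(40 * 12, 0, 0.5), 40)
  b <- matrix(rnorm(40 * 12, 30, 0.5), 40)
  emb <- umap_embed(rbind(a, b), n_neighbors = 15, seed = 1)
  lab <- rep(c("a", "b"), each = 40)
  expect_gte(silhouette_score(emb$coordinates, lab)$S, 0.8)
  blob <- matrix(rnorm(60 * 12), 60)
  emb0 <- umap_embed(blob, n_neighbors = 15, seed = 1)
  expect_lte(silhouette_score(emb0$coordinates,
                              rep(c("a", "b"), 30))$S, 0.2)
})

test_that("silhouette matches hand values and the definitional oracle", {
  pts <- matrix(c(0, 0, 10, 10), ncol = 1)
  rep1 <- silhouette_score(pts, c("A", "A", "B", "B"))
  expect_equal(rep1$S, 1)
  expect_equal(rep1$widths, rep(1, 4))
  for (s in 1:30) {
    set.seed(s)
    n <- 40
    pts <- matrix(rnorm(n * 3), n)
    labs <- sample(letters[1:sample(2:4, 1)], n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    expect_equal(silhouette_score(pts, labs)$widths,
                 oracle_silhouette(pts, labs), tolerance = 1e-12)
  }
  expect_error(silhouette_score(matrix(rnorm(10), 5), rep("A", 5)),
               "single label")
})

test_that("silhouette agrees with the cluster package on random data", {
  skip_if_not_installed("cluster")
  set.seed(77)
  pts <- matrix(rnorm(50 * 2), 50)
  labs <- sample(c(1, 2, 3), 50, replace = TRUE)
  ours <- silhouette_score(pts, labs)
  ref <- cluster::silhouette(labs, stats::dist(pts))
  expect_equal(mean(ref[, "sil_width"]), ours$S, tolerance = 1e-12)
})

test_that("two interleaved identical clusters score non-positive", {
  set.seed(26)
  pts <- matrix(rnorm(60 * 2), 60)
  expect_lte(silhouette_score(rbind(pts, pts),
                              rep(c("A", "B"), each = 60))$S, 0)
})

test_that("permutation p follows the add-one formula", {
  pts <- rbind(matrix(rnorm(20, 0, 0.1), 10),
               matrix(rnorm(20, 50, 0.1), 10))
  labs <- rep(c("A", "B"), each = 10)
  r19 <- permutation_test(pts, labs, 19, seed = 1)
  expect_equal(r19$permutation_p, 0.05)       # all permutations worse
  r199 <- permutation_test(pts, labs, 199, seed = 1)
  expect_equal(r199$permutation_p, 1 / 200)
  expect_gte(r199$permutation_p, 1 / (r199$n_permutations + 1))
  expect_error(permutation_test(pts, labs, 5), "19")
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(27)
  rejections <- 0L
  for (r in 1:200) {
    pts <- matrix(rnorm(24 * 2), 24)
    labs <- rep(c("A", "B"), each = 12)
    p <- permutation_test(pts, labs, 99, seed = r)$permutation_p
    if (p <= 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / 200, 0.01)
  expect_lte(rejections / 200, 0.10)
})

test_that("kNN cross validation is perfect on well-separated classes", {
  set.seed(28)
  x <- rbind(matrix(rnorm(60 * 5, 0, 1), 60),
             matrix(rnorm(60 * 5, 20, 1), 60))
  labs <- rep(c("HD", "WT"), each = 60)
  rep1 <- knn_crossval(x, labs, k_nn = 5, k_folds = 3, seed = 2,
                       positive = "HD")
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$specificity, 1)
  expect_equal(rep1$TP + rep1$TN + rep1$FP + rep1$FN, 120)
})

test_that("swapping class names swaps sensitivity and specificity exactly", {
  set.seed(29)
  x <- matrix(rnorm(90 * 4), 90)
  x[1:45, 1] <- x[1:45, 1] + 1.2
  labs <- rep(c("HD", "WT"), each = 45)
  swapped <- ifelse(labs == "HD", "WT", "HD")
  r1 <- knn_crossval(x, labs, 5, 3, seed = 3, positive = "HD")
  r2 <- knn_crossval(x, swapped, 5, 3, seed = 3, positive = "WT")
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(r1$sensitivity, r2$sensitivity)
  expect_equal(r1$specificity, r2$specificity)
  expect_equal(r1$TP, r2$TP)
})

test_that("uninformative features give chance-level accuracy", {
  set.seed(30)
  accs <- sapply(1:10, function(s) {
    x <- matrix(rnorm(60 * 6), 60)   # features independent of labels
    knn_crossval(x, rep(c("HD", "WT"), 30), 5, 3, seed = s,
                 positive = "HD")$accuracy
  })
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("kNN parameter validation and fold warnings work", {
  x <- matrix(rnorm(12 * 2), 12)
  labs <- rep(c("A", "B"), 6)
  expect_error(knn_crossval(x, labs, k_nn = 10, k_folds = 3),
               "parameter error")
  expect_error(knn_crossval(x, rep("A", 12), 3, 3), "two classes")
  skew <- c(rep("A", 11), "B")
  expect_warning(knn_crossval(x, skew, 1, 3, seed = 1), "missing a class")
})

test_that("confusion metrics match the defining arithmetic", {
  m <- confusion_metrics(95, 99, 1, 5)
  expect_equal(m$accuracy, 0.97)
  expect_equal(m$sensitivity, 0.95)
  expect_equal(m$specificity, 0.99)
  perfect <- confusion_metrics(10, 10, 0, 0)
  expect_equal(unlist(perfect), c(1, 1, 1), ignore_attr = TRUE)
  degenerate <- confusion_metrics(0, 10, 0, 10)
  expect_equal(degenerate$accuracy, 0.5)
  expect_equal(degenerate$specificity, 1)
  expect_equal(degenerate$sensitivity, 0)
  set.seed(31)
  for (i in 1:100) {
    v <- rpois(4, 20)
    if (sum(v) == 0) v[1] <- 1
    m <- confusion_metrics(v[1], v[2], v[3], v[4])
    expect_identical(m$accuracy, (v[1] + v[2]) / sum(v))
    expect_identical(m$sensitivity,
                     if (v[1] + v[4] > 0) v[1] / (v[1] + v[4]) else NA_real_)
    expect_identical(m$specificity,
                     if (v[2] + v[3] > 0) v[2] / (v[2] + v[3]) else NA_real_)
  }
  expect_true(is.na(confusion_metrics(0, 5, 3, 0)$sensitivity))
  expect_error(confusion_metrics(0, 0, 0, 0), "zero")
  expect_error(confusion_metrics(-1, 2, 3, 4), "non-negative")
})
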