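# Band integration, Otsu thresholding (global and local), seed detection,
# seeded watershed, segment derivation with erosion, mean-spectrum
# extraction.

test_that("integrate_band matches closed-form trapezoids", {
  nu <- seq(1670, 1630, by = -2)  # 21 points, width 40
  ones <- hyper_cube(array(1, c(1, 1, 21)), nu)
  expect_equal(integrate_band(ones, 1630, 1670)[1, 1], 40)
  zeros <- hyper_cube(array(0, c(1, 1, 21)), nu)
  expect_equal(integrate_band(zeros, 1630, 1670)[1, 1], 0)
  ramp <- hyper_cube(array((nu - 1630) / 40, c(1, 1, 21)), nu)
  expect_equal(integrate_band(ramp, 1630, 1670)[1, 1], 20, tolerance = 1e-9)
})

test_that("integrate_band is linear in the cube", {
  set.seed(42)
  nu <- seq(1700, 1600, by = -4)
  x <- array(runif(3 * 3 * 26), c(3, 3, 26))
  y <- array(runif(3 * 3 * 26), c(3, 3, 26))
  a <- 2.5; b <- -0.7
  lhs <- integrate_band(hyper_cube(a * x + b * y + 2, nu), 1620, 1680)
  rhs <- a * integrate_band(hyper_cube(x, nu), 1620, 1680) +
    b * integrate_band(hyper_cube(y, nu), 1620, 1680) +
    integrate_band(hyper_cube(array(2, dim(x)), nu), 1620, 1680)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("otsu_threshold separates a bimodal sample and matches brute force", {
  v <- c(rep(0, 50), rep(10, 50))
  t0 <- otsu_threshold(v, 256)
  expect_gt(t0, 0); expect_lt(t0, 10)
  expect_true(all(v[v <= t0] == 0) && all(v[v > t0] == 10))
  for (s in 1:30) {
    set.seed(s)
    v <- switch(1 + s %% 3,
                runif(100),
                c(rnorm(60, 0, 1), rnorm(40, 5, 0.5)),
                rexp(80))
    expect_equal(otsu_threshold(v, 64), oracle_otsu(v, 64))
  }
  expect_error(otsu_threshold(rep(3, 10)), "degenerate")
})

test_that("local Otsu equals the per-pixel clipped-neighbourhood oracle", {
  set.seed(11)
  img <- matrix(runif(24 * 20), 24, 20)
  img[8:16, 6:14] <- img[8:16, 6:14] + 2
  radius <- 5; n_bins <- 32
  mask <- local_otsu_mask(img, radius, n_bins)
  breaks <- seq(min(img), max(img), length.out = n_bins + 1)
  oracle <- matrix(FALSE, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) for (cc in seq_len(ncol(img))) {
    rs <- max(1, r - radius):min(nrow(img), r + radius)
    cs <- max(1, cc - radius):min(ncol(img), cc + radius)
    sel <- outer(rs - r, cs - cc, function(a, b) a^2 + b^2) <= radius^2
    vals <- img[rs, cs][sel]
    t0 <- tryCatch(otsu_threshold(vals, breaks = breaks),
                   error = function(e) NA_real_)
    oracle[r, cc] <- !is.na(t0) && img[r, cc] > t0
  }
  expect_identical(mask, oracle)
})

test_that("local Otsu recovers a bright disk on flat background", {
  img <- matrix(0, 60, 60)
  img[disk_mask(60, 60, c(30, 30), 10)] <- 1
  mask <- local_otsu_mask(img, 15)
  truth <- disk_mask(60, 60, c(30, 30), 10)
  expect_true(all(mask[truth]))                 # foreground contains the disk
  halo <- disk_mask(60, 60, c(30, 30), 11.5)
  expect_true(!any(mask[!halo]))                # background beyond 1 px band
})

test_that("with objects everywhere in reach, local Otsu matches global Otsu", {
  set.seed(5)
  img <- matrix(rep(c(0, 10), each = 450), 30, 30) +
    outer(seq(0, 1, length.out = 30), seq(0, 1, length.out = 30), "+") / 2
  local <- local_otsu_mask(img, 29)
  t_global <- otsu_threshold(as.vector(img), 256)
  expect_identical(local, img > t_global)
})

test_that("degenerate local Otsu inputs produce an empty mask with warning", {
  expect_warning(m <- local_otsu_mask(matrix(1, 10, 10), 3), "constant")
  expect_false(any(m))
  expect_error(local_otsu_mask(matrix(runif(25), 5, 5), 7), "parameter error")
})

test_that("detect_seeds places one centroid seed per component", {
  m <- disk_mask(80, 80, c(20, 20), 5) | disk_mask(80, 80, c(60, 60), 5)
  seeds <- detect_seeds(m, 10)
  expect_equal(seeds[order(seeds[, 1]), ],
               matrix(c(20L, 20L, 60L, 60L), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(nrow(detect_seeds(matrix(FALSE, 5, 5), 1)), 0)
})

test_that("a bridged dumbbell yields one seed at the in-mask point nearest the centroid", {
  m <- disk_mask(60, 60, c(30, 12), 6) | disk_mask(60, 60, c(30, 44), 6)
  m[30, 12:44] <- TRUE  # 1-px bridge
  seeds <- detect_seeds(m, 10)
  expect_equal(nrow(seeds), 1)
  lab <- oracle_components(m)
  expect_equal(max(lab), 1)
  px <- which(lab == 1, arr.ind = TRUE)
  cen <- colMeans(px)
  d2 <- (px[, 1] - cen[1])^2 + (px[, 2] - cen[2])^2
  expect_equal(unname(seeds[1, ]), unname(px[which.min(d2), ]))
})

test_that("watershed splits a uniform rectangle at the bisector", {
  mask <- matrix(FALSE, 30, 50)
  mask[6:25, 6:45] <- TRUE
  seeds <- rbind(c(15L, 18L), c(15L, 33L))
  lab <- watershed_cells(matrix(1, 30, 50), seeds, mask)
  expect_setequal(unique(lab[mask]), c(1L, 2L))
  expect_true(all(lab[!mask] == 0L))
  a1 <- sum(lab == 1); a2 <- sum(lab == 2)
  expect_lt(abs(a1 - a2) / (a1 + a2), 0.05)
  split_cols <- range(which(colSums(lab == 1) > 0))
  expect_lte(abs(split_cols[2] - 25), 1)  # bisector between cols 25/26
})

test_that("watershed trivial cases: single seed, disjoint components, bad seed", {
  mask <- disk_mask(40, 40, c(20, 20), 10)
  lab <- watershed_cells(matrix(runif(1600), 40, 40),
                         matrix(c(20L, 20L), 1), mask)
  expect_true(all(lab[mask] == 1L) && all(lab[!mask] == 0L))
  m2 <- disk_mask(40, 40, c(10, 10), 5) | disk_mask(40, 40, c(30, 30), 5)
  lab2 <- watershed_cells(matrix(1, 40, 40),
                          rbind(c(10L, 10L), c(30L, 30L)), m2)
  expect_identical(lab2 == 1L, disk_mask(40, 40, c(10, 10), 5))
  expect_identical(lab2 == 2L, disk_mask(40, 40, c(30, 30), 5))
  expect_error(watershed_cells(matrix(1, 40, 40),
                               matrix(c(2L, 2L), 1), m2),
               "outside")
})

test_that("derive_segments reproduces the distance-transform erosion oracle", {
  cell <- disk_mask(40, 40, c(20, 20), 10)
  nucleus <- disk_mask(40, 40, c(20, 20), 5)
  seg <- derive_segments(matrix(as.integer(cell), 40, 40), nucleus, 2)
  expect_identical(seg$nucleus_labels == 1L,
                   oracle_erode(nucleus, 2))
  expect_identical(seg$cytoplasm_labels == 1L,
                   oracle_erode(cell & !nucleus, 2))
  # eroded nucleus sits inside the uneroded one, roughly two pixels in
  expect_true(all((seg$nucleus_labels == 1L) <= nucleus))
  expect_true(all(disk_mask(40, 40, c(20, 20), 2.5)[seg$nucleus_labels != 1L] == FALSE))
})

test_that("erosion 0 gives the exact disjoint partition of the cell", {
  cell <- disk_mask(30, 30, c(15, 15), 8)
  nucleus <- disk_mask(30, 30, c(15, 15), 4)
  seg <- derive_segments(matrix(as.integer(cell), 30, 30), nucleus, 0)
  expect_identical((seg$nucleus_labels == 1L) | (seg$cytoplasm_labels == 1L),
                   cell)
  expect_false(any(seg$nucleus_labels > 0 & seg$cytoplasm_labels > 0))
})

test_that("a cell without nucleus keeps its eroded cytoplasm and is flagged", {
  cell <- disk_mask(30, 30, c(15, 15), 8)
  seg <- derive_segments(matrix(as.integer(cell), 30, 30),
                         matrix(FALSE, 30, 30), 2)
  expect_identical(seg$cytoplasm_labels == 1L, oracle_erode(cell, 2))
  expect_true(any(seg$flags$reason == "nucleus absent"))
  expect_error(derive_segments(matrix(0L, 3, 3), matrix(FALSE, 4, 4)),
               "mismatch")
})

test_that("segmentation_result enforces the segment set algebra", {
  cell <- matrix(c(1L, 1L, 0L, 0L), 2)
  expect_error(segmentation_result(cell, matrix(c(0L, 2L, 0L, 0L), 2),
                                   matrix(0L, 2, 2)), "inside")
  expect_error(segmentation_result(cell, matrix(c(1L, 0L, 0L, 0L), 2),
                                   matrix(c(1L, 0L, 0L, 0L), 2)), "overlap")
})

test_that("extract_mean_spectra equals the brute-force pixel mean", {
  set.seed(9)
  nu <- seq(2000, 1802, by = -2)
  cube <- hyper_cube(array(runif(10 * 10 * 100), c(10, 10, 100)), nu)
  cell <- matrix(0L, 10, 10); cell[3:8, 3:8] <- 1L
  nucmask <- matrix(FALSE, 10, 10); nucmask[5:6, 5:6] <- TRUE
  seg <- derive_segments(cell, nucmask, 0)
  recs <- extract_mean_spectra(cube, seg, "s", "WT")
  pix <- matrix(cube$data, nrow = 100)
  for (kind in c("cell", "nucleus", "cytoplasm")) {
    lab <- seg[[paste0(kind, "_labels")]]
    idx <- which(lab == 1L)
    manual <- numeric(100)
    for (p in idx) manual <- manual + pix[p, ]
    manual <- manual / length(idx)
    got <- recs$absorbance[recs$meta$segment == kind, ]
    expect_equal(as.vector(got), manual, tolerance = 1e-12)
    expect_equal(recs$meta$n_pixels[recs$meta$segment == kind],
                 length(idx))
  }
})

test_that("a segment of identical pixel spectra has that spectrum as mean", {
  nu <- seq(1500, 1402, by = -2)
  s <- runif(50)
  cube <- hyper_cube(array(rep(s, each = 16), c(4, 4, 50)), nu)
  seg <- derive_segments(matrix(1L, 4, 4), matrix(FALSE, 4, 4), 0)
  recs <- extract_mean_spectra(cube, seg)
  expect_equal(as.vector(recs$absorbance[recs$meta$segment == "cell", ]), s)
})
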