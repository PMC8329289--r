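# Quality-test metrics, cutoff calibration and accept/reject screening.

std_axis <- seq(4000, 800, by = -2)

test_that("first_derivative_range is zero for constant and linear spectra", {
  s_const <- ir_spectrum(std_axis, rep(0.7, length(std_axis)))
  s_lin <- ir_spectrum(std_axis, 0.1 + 2e-4 * std_axis)
  expect_equal(first_derivative_range(s_const, 1600, 1700), 0)
  expect_equal(first_derivative_range(s_lin, 1600, 1700), 0, tolerance = 1e-12)
  expect_error(first_derivative_range(s_const, 1600, 1601), "range error")
})

test_that("a triangular spike of height h gives derivative range 2h/d", {
  d <- 2; h <- 0.35
  y <- rep(0, length(std_axis))
  y[std_axis == 1650] <- h   # single-point spike at the window centre
  s <- ir_spectrum(std_axis, y)
  expect_equal(first_derivative_range(s, 1600, 1700), 2 * h / d,
               tolerance = 1e-12)
})

test_that("a flat spectrum degenerates: zero statistics, non-finite ratios", {
  m <- compute_qt_metrics(ir_spectrum(std_axis, rep(0.5, length(std_axis))))
  expect_equal(m$qt_absorbance, 0.5)
  expect_equal(unlist(m[c("S1", "S2", "N", "WVC")]), rep(0, 4),
               ignore_attr = TRUE)
  expect_true(all(is.na(unlist(m[c("snr1", "snr2", "swr1", "swr2")]))))
  # a flat spectrum is auto-rejected once thresholds exist
  calib <- compute_qt_metrics(
    spectra_set(t(sapply(1:20, function(s) random_spectrum(std_axis, s))),
                std_axis))
  thr <- calibrate_qt(calib)
  expect_false(apply_qt(m, thr)$results$pass)
  expect_match(apply_qt(m, thr)$results$reasons, "nonfinite_ratio")
})

test_that("QT metrics equal the definitional oracle on random spectra", {
  for (s in 1:50) {
    y <- random_spectrum(std_axis, s)
    m <- compute_qt_metrics(ir_spectrum(std_axis, y))
    o <- oracle_qt_metrics(std_axis, y)
    expect_equal(unlist(m[1, ]), o, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("an isolated water-vapor line drives WVC but not S1/S2", {
  y <- 0.1 + 0.05 * exp(-(std_axis - 1842)^2 / (2 * 1.0^2))
  m <- compute_qt_metrics(ir_spectrum(std_axis, y))
  expect_gt(m$WVC, 0)
  expect_equal(m$S1, 0, tolerance = 1e-15)
  expect_equal(m$S2, 0, tolerance = 1e-15)
  expect_equal(m$swr1, 0, tolerance = 1e-15)
  expect_equal(m$swr2, 0, tolerance = 1e-15)
  expect_true(is.na(m$snr1))  # silent-region noise is exactly zero here
})

test_that("calibration arithmetic: mean +/- 5 sd for A, +/- 1 sd for ratios", {
  fake <- data.frame(qt_absorbance = 1:5, S1 = 1, S2 = 1, N = 1, WVC = 1,
                     snr1 = c(10, 11, 12, 13, 14), snr2 = c(10, 12, 14, 12, 12),
                     swr1 = 2:6, swr2 = 2:6)
  thr <- calibrate_qt(fake)
  expect_equal(thr$a_lo, 3 - 5 * sd(1:5), tolerance = 1e-12)
  expect_equal(thr$a_hi, 3 + 5 * sd(1:5), tolerance = 1e-12)
  expect_equal(thr$a_lo, -4.9057, tolerance = 1e-4)
  expect_equal(thr$a_hi, 10.9057, tolerance = 1e-4)
  sub <- calibrate_qt(fake[c(1, 3, 5), ])
  expect_equal(sub$ratios$snr1$lo, 10)   # {10,12,14}: mean 12, sd 2
  expect_equal(sub$ratios$snr1$hi, 14)
  expect_equal(thr$n_calibration, 5L)
})

test_that("identical calibration spectra give degenerate flagged thresholds", {
  fake <- data.frame(qt_absorbance = rep(2, 3), S1 = 1, S2 = 1, N = 1,
                     WVC = 1, snr1 = 5, snr2 = 5, swr1 = 5, swr2 = 5)
  expect_warning(thr <- calibrate_qt(fake), "degenerate")
  expect_true(thr$degenerate)
  expect_equal(thr$a_lo, thr$a_hi)
  expect_equal(thr$ratios$snr1$lo, thr$ratios$snr1$hi)
})

test_that("absorbance bounds are inclusive and violations are named", {
  fake <- data.frame(qt_absorbance = c(1, 2, 3, 4, 5), S1 = 1, S2 = 1,
                     N = 1, WVC = 1, snr1 = c(10, 11, 12, 13, 14),
                     snr2 = c(10, 11, 12, 13, 14), swr1 = 2:6, swr2 = 2:6)
  thr <- calibrate_qt(fake)
  at_hi <- fake[3, ]; at_hi$qt_absorbance <- thr$a_hi
  expect_true(apply_qt(at_hi, thr)$results$pass)
  beyond <- fake[3, ]; beyond$qt_absorbance <- thr$a_mean + 6 * thr$a_sd
  res <- apply_qt(beyond, thr)$results
  expect_false(res$pass)
  expect_match(res$reasons, "absorbance")
  expect_error(apply_qt(fake, list()), "state error")
})

test_that("rejection needs BOTH ratios of a pair outside under the default mode", {
  fake <- data.frame(qt_absorbance = rnorm(20, 1, 0.01), S1 = 1, S2 = 1,
                     N = 1, WVC = 1,
                     snr1 = rnorm(20, 100, 5), snr2 = rnorm(20, 50, 5),
                     swr1 = rnorm(20, 40, 5), swr2 = rnorm(20, 20, 5))
  thr <- calibrate_qt(fake)
  probe <- fake[1, ]
  probe$snr1 <- thr$ratios$snr1$lo - 50      # one ratio far out
  probe$snr2 <- thr$ratios$snr2$mean         # the other at its mean
  probe$swr1 <- thr$ratios$swr1$mean
  probe$swr2 <- thr$ratios$swr2$mean
  probe$qt_absorbance <- thr$a_mean
  expect_true(apply_qt(probe, thr)$results$pass)
  probe$snr2 <- thr$ratios$snr2$lo - 20      # now both are out
  expect_false(apply_qt(probe, thr)$results$pass)
  expect_match(apply_qt(probe, thr)$results$reasons, "snr")
})

test_that("positive scaling scales the statistics and fixes the ratios", {
  y <- random_spectrum(std_axis, 99)
  c0 <- 3.7
  m1 <- compute_qt_metrics(ir_spectrum(std_axis, y))
  m2 <- compute_qt_metrics(ir_spectrum(std_axis, c0 * y))
  for (nm in c("qt_absorbance", "S1", "S2", "N", "WVC"))
    expect_equal(m2[[nm]], c0 * m1[[nm]], tolerance = 1e-12)
  for (nm in c("snr1", "snr2", "swr1", "swr2"))
    expect_equal(m2[[nm]], m1[[nm]], tolerance = 1e-12)
})

test_that("metrics are invariant to the axis storage direction", {
  y <- random_spectrum(std_axis, 123)
  m_desc <- compute_qt_metrics(ir_spectrum(std_axis, y))
  m_asc <- compute_qt_metrics(ir_spectrum(rev(std_axis), rev(y)))
  expect_equal(m_desc, m_asc, tolerance = 1e-12)
})

test_that("apply_qt is monotone in qt_absorbance", {
  fake <- data.frame(qt_absorbance = rnorm(30, 1, 0.05), S1 = 1, S2 = 1,
                     N = 1, WVC = 1, snr1 = rnorm(30, 100, 5),
                     snr2 = rnorm(30, 50, 3), swr1 = rnorm(30, 40, 4),
                     swr2 = rnorm(30, 20, 2))
  thr <- calibrate_qt(fake)
  x <- fake[1, ]
  x$qt_absorbance <- thr$a_mean + 4.9 * thr$a_sd
  x[c("snr1", "snr2", "swr1", "swr2")] <-
    lapply(thr$ratios, function(r) r$mean)
  expect_true(apply_qt(x, thr)$results$pass)
  y2 <- x; y2$qt_absorbance <- thr$a_mean + 2 * thr$a_sd  # closer to mean
  expect_true(apply_qt(y2, thr)$results$pass)
})

test_that("injected low-SNR spectra are rejected after calibration", {
  # noise at the level of per-segment mean spectra (pixel noise averaged
  # over tens of pixels), the population the quality test screens
  set.seed(202)
  base <- band_model(std_axis, default_band_table("cytoplasm"),
                     baseline_offset = 0.03)$absorbance
  clean <- t(sapply(1:200, function(i)
    base + rnorm(length(std_axis), sd = 3e-4)))
  noisy <- t(sapply(1:20, function(i)
    base + rnorm(length(std_axis), sd = 20 * 3e-4)))
  m_clean <- compute_qt_metrics(spectra_set(clean, std_axis))
  m_noisy <- compute_qt_metrics(spectra_set(noisy, std_axis))
  thr <- calibrate_qt(m_clean)
  expect_true(all(!apply_qt(m_noisy, thr)$results$pass))
  expect_gte(apply_qt(m_clean, thr)$pass_fraction, 0.6)
})
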