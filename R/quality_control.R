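# Spectral quality testing: per-spectrum absorbance / signal-to-noise /
# water-vapor statistics, calibration of cutoffs on a reference set, and
# accept/reject screening. Operates on raw (pre-derivative) spectra; the
# first derivative used here is the plain successive-difference quotient,
# not Savitzky-Golay, because quality testing precedes smoothing in the
# pipeline order.

# max - min of the discrete first derivative over a closed window
fdr_window <- function(wavenumber, absorbance, lo, hi) {
  idx <- axis_window(wavenumber, lo, hi)
  if (length(idx) < 3L)
    stop(sprintf("range error: fewer than 3 axis points in [%g, %g]", lo, hi))
  d <- diff(absorbance[idx]) / diff(wavenumber[idx])
  max(d) - min(d)
}

#' First-derivative range of a spectrum over a window
#'
#' The difference between the maximum and minimum of the discrete first
#' derivative (successive absorbance differences divided by successive
#' wavenumber differences) over the closed window `[lo, hi]`. This is the
#' signal operator behind the S1/S2/N/WVC quality statistics; it is zero
#' for constant and linear spectra and invariant to the axis storage
#' direction.
#'
#' @param spectrum an [ir_spectrum()].
#' @param lo,hi window bounds in cm^-1.
#' @return a non-negative scalar.
#' @export
first_derivative_range <- function(spectrum, lo, hi) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  fdr_window(spectrum$wavenumber, spectrum$absorbance, lo, hi)
}

# the fixed QT windows (cm^-1)
.qt_windows <- list(S1 = c(1600, 1700),   # amide I
                    S2 = c(960, 1260),    # sugar-ring / phosphate
                    N = c(2000, 2100),    # silent region -> noise
                    WVC = c(1837, 1847))  # water-vapor rotational lines

#' Compute quality-test metrics for spectra
#'
#' Per spectrum: `qt_absorbance` = mean absorbance over the full retained
#' range; `S1` and `S2` = first-derivative ranges over the amide-I
#' (1600-1700 cm^-1) and sugar-ring (960-1260 cm^-1) bands; `N` = the same
#' operator over the spectroscopically silent 2000-2100 cm^-1 region
#' (noise); `WVC` = over 1837-1847 cm^-1 where water-vapor lines absorb;
#' and the ratios `snr1 = S1/N`, `snr2 = S2/N`, `swr1 = S1/WVC`,
#' `swr2 = S2/WVC`. A zero denominator yields a non-finite ratio, which
#' [apply_qt()] auto-rejects.
#'
#' @param x an [ir_spectrum()] or [spectra_set()]; the axis must cover at
#'   least 960-2100 cm^-1.
#' @return a data.frame with one row per spectrum (class `qt_metrics`).
#' @export
compute_qt_metrics <- function(x) UseMethod("compute_qt_metrics")

#' @export
compute_qt_metrics.ir_spectrum <- function(x) {
  compute_qt_metrics(spectra_set(matrix(x$absorbance, nrow = 1),
                                 x$wavenumber))
}

#' @export
compute_qt_metrics.spectra_set <- function(x) {
  nu <- x$wavenumber
  if (min(nu) > 960 || max(nu) < 2100)
    stop("axis must cover at least 960-2100 cm^-1 for quality testing")
  n <- n_spectra(x)
  out <- data.frame(qt_absorbance = rowMeans(x$absorbance),
                    S1 = numeric(n), S2 = numeric(n), N = numeric(n),
                    WVC = numeric(n))
  for (stat in names(.qt_windows)) {
    w <- .qt_windows[[stat]]
    idx <- axis_window(nu, w[1], w[2])
    if (length(idx) < 3L)
      stop(sprintf("range error: fewer than 3 axis points in [%g, %g] (%s)",
                   w[1], w[2], stat))
    dn <- diff(nu[idx])
    dmat <- (x$absorbance[, idx[-1], drop = FALSE] -
             x$absorbance[, idx[-length(idx)], drop = FALSE]) /
      rep(dn, each = n)
    out[[stat]] <- apply(dmat, 1, max) - apply(dmat, 1, min)
  }
  ratio <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  out$snr1 <- ratio(out$S1, out$N)
  out$snr2 <- ratio(out$S2, out$N)
  out$swr1 <- ratio(out$S1, out$WVC)
  out$swr2 <- ratio(out$S2, out$WVC)
  class(out) <- c("qt_metrics", "data.frame")
  out
}

#' Calibrate quality-test cutoffs from a reference set
#'
#' Absorbance bounds are the calibration mean +/- 5 standard deviations;
#' each SNR/SWR ratio gets the interval mean +/- 1 standard deviation
#' (sample sd, n-1 denominator). Spectra with non-finite ratios are
#' excluded from calibration. If all calibration values of a statistic
#' are identical the thresholds are degenerate (lo = hi) and flagged.
#'
#' @param metrics a `qt_metrics` data.frame from [compute_qt_metrics()].
#' @param mode rejection mode for the ratio checks: `"two_sided"`
#'   (default; reject outside `[mean - sd, mean + sd]`) or `"low_only"`
#'   (reject only below `mean - sd`).
#' @param combine how the two ratios of a pair must offend to reject:
#'   `"both"` (default) or `"any"`.
#' @param a_sd_mult,ratio_sd_mult standard-deviation multipliers for the
#'   absorbance and ratio intervals (defaults 5 and 1).
#' @return an object of class `qt_thresholds`.
#' @export
calibrate_qt <- function(metrics, mode = c("two_sided", "low_only"),
                         combine = c("both", "any"),
                         a_sd_mult = 5, ratio_sd_mult = 1) {
  mode <- match.arg(mode); combine <- match.arg(combine)
  ratio_names <- c("snr1", "snr2", "swr1", "swr2")
  ok <- rowSums(!is.finite(as.matrix(metrics[ratio_names]))) == 0
  m <- metrics[ok, , drop = FALSE]
  if (nrow(m) < 2L)
    stop("need >= 2 spectra with finite metrics to calibrate")
  a_mean <- mean(m$qt_absorbance); a_sd <- sd(m$qt_absorbance)
  ratios <- lapply(ratio_names, function(nm) {
    mu <- mean(m[[nm]]); s <- sd(m[[nm]])
    list(mean = mu, sd = s, lo = mu - ratio_sd_mult * s,
         hi = mu + ratio_sd_mult * s)
  })
  names(ratios) <- ratio_names
  degenerate <- a_sd == 0 || any(vapply(ratios, function(r) r$sd == 0,
                                        logical(1)))
  if (degenerate)
    warning("degenerate thresholds: zero standard deviation in calibration")
  structure(list(a_mean = a_mean, a_sd = a_sd,
                 a_lo = a_mean - a_sd_mult * a_sd,
                 a_hi = a_mean + a_sd_mult * a_sd,
                 ratios = ratios, mode = mode, combine = combine,
                 a_sd_mult = a_sd_mult, ratio_sd_mult = ratio_sd_mult,
                 degenerate = degenerate, n_calibration = nrow(m)),
            class = "qt_thresholds")
}

#' @export
print.qt_thresholds <- function(x, ...) {
  cat(sprintf("<qt_thresholds> n = %d, A in [%.4g, %.4g], mode %s/%s\n",
              x$n_calibration, x$a_lo, x$a_hi, x$mode, x$combine))
  invisible(x)
}

#' Apply calibrated quality-test cutoffs
#'
#' A spectrum passes when (1) its mean absorbance lies inside
#' `[a_lo, a_hi]` (bounds inclusive), (2) the SNR pair and (3) the SWR
#' pair survive the configured rejection rule, and all four ratios are
#' finite (non-finite ratios auto-reject).
#'
#' @param metrics a `qt_metrics` data.frame.
#' @param thresholds a `qt_thresholds` object from [calibrate_qt()].
#' @return a `qt_report`: list with `results` (per-spectrum `pass` flag
#'   and comma-separated `reasons`) and `pass_fraction`.
#' @export
apply_qt <- function(metrics, thresholds) {
  if (!inherits(thresholds, "qt_thresholds"))
    stop("state error: thresholds must come from calibrate_qt()")
  n <- nrow(metrics)
  outside <- function(x, r) {
    out <- x < r$lo | (thresholds$mode == "two_sided" & x > r$hi)
    out | !is.finite(x)
  }
  pair_fail <- function(o1, o2)
    if (thresholds$combine == "both") o1 & o2 else o1 | o2
  finite_ok <- rowSums(!is.finite(as.matrix(
    metrics[c("snr1", "snr2", "swr1", "swr2")]))) == 0
  a_ok <- metrics$qt_absorbance >= thresholds$a_lo &
    metrics$qt_absorbance <= thresholds$a_hi
  snr_fail <- pair_fail(outside(metrics$snr1, thresholds$ratios$snr1),
                        outside(metrics$snr2, thresholds$ratios$snr2))
  swr_fail <- pair_fail(outside(metrics$swr1, thresholds$ratios$swr1),
                        outside(metrics$swr2, thresholds$ratios$swr2))
  pass <- finite_ok & a_ok & !snr_fail & !swr_fail
  reasons <- character(n)
  for (i in seq_len(n)) {
    r <- c(if (!finite_ok[i]) "nonfinite_ratio",
           if (!a_ok[i]) "absorbance",
           if (snr_fail[i]) "snr",
           if (swr_fail[i]) "swr")
    reasons[i] <- paste(r, collapse = ",")
  }
  structure(list(results = data.frame(pass = pass, reasons = reasons),
                 pass_fraction = mean(pass),
                 n = n, n_pass = sum(pass)),
            class = "qt_report")
}

#' @export
print.qt_report <- function(x, ...) {
  cat(sprintf("<qt_report> %d/%d spectra passed (%.1f%%)\n",
              x$n_pass, x$n, 100 * x$pass_fraction))
  invisible(x)
}
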