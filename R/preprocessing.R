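# Preprocessing of quality-passed raw spectra: crop to the analysis
# range, fused Savitzky-Golay smoothing + second differentiation, and
# vector (unit Euclidean norm) normalization. The second derivative
# removes constant and linear baselines and sharpens overlapping bands
# (absorption peaks become minima); vector normalization removes
# sample-thickness scaling.

#' Preprocessing parameters
#'
#' @param range_lo,range_hi analysis window in cm^-1 (default 900-4000).
#' @param sg_window_points Savitzky-Golay window length, odd (default 21).
#' @param sg_polyorder local polynomial order (default 2).
#' @param norm normalization, currently `"l2"` (unit Euclidean norm).
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(range_lo = 900, range_hi = 4000,
                              sg_window_points = 21L, sg_polyorder = 2L,
                              norm = "l2") {
  sg_window_points <- as.integer(sg_window_points)
  sg_polyorder <- as.integer(sg_polyorder)
  if (sg_window_points %% 2L == 0L || sg_window_points <= sg_polyorder)
    stop("sg_window_points must be odd and greater than sg_polyorder")
  if (sg_polyorder < 2L)
    stop("second differentiation needs sg_polyorder >= 2")
  stopifnot(range_lo < range_hi, norm == "l2")
  structure(list(range_lo = range_lo, range_hi = range_hi,
                 sg_window_points = sg_window_points,
                 sg_polyorder = sg_polyorder,
                 derivative_order = 2L, norm = norm),
            class = "preprocess_config")
}

check_uniform_axis <- function(wavenumber, tol = 0.01) {
  h <- diff(wavenumber)
  hm <- mean(h)
  if (max(abs(h - hm)) > tol * abs(hm))
    stop("axis spacing non-uniform beyond ", tol * 100,
         "% tolerance; resample before differentiating")
  abs(hm)
}

# central-row SG second-derivative coefficients, scaled to d^2/d(nu)^2
sg_second_deriv_coef <- function(window, polyorder, step) {
  f <- signal::sgolay(p = polyorder, n = window, m = 2, ts = step)
  as.numeric(f[(window + 1L) / 2L, ])
}

#' Savitzky-Golay second derivative
#'
#' Second derivative of absorbance with respect to wavenumber via a
#' least-squares local polynomial fit over a sliding window; smoothing
#' and differentiation are fused in one convolution, mathematically
#' identical to smooth-then-differentiate with the same window and
#' order. The output is trimmed to the interior points where the window
#' fits entirely (no edge extrapolation), so the result has
#' `length - window + 1` points and the axis is trimmed to match.
#' Results are with respect to cm^-1 (spacing-aware), and invariant to
#' the axis storage direction.
#'
#' @param x an [ir_spectrum()] or [spectra_set()] with uniform axis
#'   spacing (within 1%).
#' @param window_points window length, odd.
#' @param polyorder polynomial order (>= 2).
#' @return same class as `x`, differentiated and trimmed.
#' @export
savgol_second_derivative <- function(x, window_points = 21L,
                                     polyorder = 2L)
  UseMethod("savgol_second_derivative")

#' @export
savgol_second_derivative.ir_spectrum <- function(x, window_points = 21L,
                                                 polyorder = 2L) {
  s <- savgol_second_derivative(
    spectra_set(matrix(x$absorbance, nrow = 1), x$wavenumber),
    window_points, polyorder)
  ir_spectrum(s$wavenumber, as.vector(s$absorbance))
}

#' @export
savgol_second_derivative.spectra_set <- function(x, window_points = 21L,
                                                 polyorder = 2L) {
  window_points <- as.integer(window_points)
  p <- length(x$wavenumber)
  if (window_points %% 2L == 0L)
    stop("window_points must be odd")
  if (window_points > p)
    stop("window (", window_points, ") exceeds spectrum length (", p, ")")
  step <- check_uniform_axis(x$wavenumber)
  cc <- sg_second_deriv_coef(window_points, polyorder, step)
  out_len <- p - window_points + 1L
  out <- matrix(0, nrow = nrow(x$absorbance), ncol = out_len)
  for (k in seq_len(window_points))
    out <- out + cc[k] * x$absorbance[, k:(k + out_len - 1L), drop = FALSE]
  half <- (window_points - 1L) / 2L
  spectra_set(out, x$wavenumber[(half + 1L):(p - half)], x$meta)
}

#' Vector normalization to unit Euclidean norm
#'
#' @param x an [ir_spectrum()] or [spectra_set()].
#' @return same class as `x`, each spectrum divided by its L2 norm.
#' @export
vector_normalize <- function(x) UseMethod("vector_normalize")

#' @export
vector_normalize.ir_spectrum <- function(x) {
  nrm <- sqrt(sum(x$absorbance^2))
  if (nrm == 0) stop("degenerate input: cannot normalize a zero spectrum")
  ir_spectrum(x$wavenumber, x$absorbance / nrm)
}

#' @export
vector_normalize.spectra_set <- function(x) {
  nrm <- sqrt(rowSums(x$absorbance^2))
  if (any(nrm == 0))
    stop("degenerate input: zero spectrum at row ",
         which(nrm == 0)[1])
  spectra_set(x$absorbance / nrm, x$wavenumber, x$meta)
}

#' Full spectral preprocessing chain
#'
#' Crop to the analysis range, Savitzky-Golay second derivative, vector
#' normalization, in that order. Normalization is applied over the full
#' retained range, not per display sub-region. The configuration is
#' recorded in the `"preprocess_config"` attribute of the result.
#'
#' @param x an [ir_spectrum()] or [spectra_set()] covering the range.
#' @param config a [preprocess_config()].
#' @return same class as `x`, preprocessed.
#' @export
preprocess <- function(x, config = preprocess_config()) {
  out <- crop_to_range(x, config$range_lo, config$range_hi)
  out <- savgol_second_derivative(out, config$sg_window_points,
                                  config$sg_polyorder)
  out <- vector_normalize(out)
  attr(out, "preprocess_config") <- config
  out
}

#' Display-region views of a preprocessed spectrum
#'
#' Crops to the lipid-rich (2800-3050 cm^-1) and fingerprint
#' (900-1800 cm^-1) regions used for plotting. Views are plain crops of
#' the input (not renormalized).
#'
#' @param x an [ir_spectrum()] or [spectra_set()].
#' @return a list with elements `lipid` and `fingerprint`.
#' @export
display_regions <- function(x) {
  list(lipid = crop_to_range(x, 2800, 3050),
       fingerprint = crop_to_range(x, 900, 1800))
}
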