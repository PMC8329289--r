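# ---- wavenumber axis -------------------------------------------------------

#' Validate a wavenumber axis
#'
#' A wavenumber axis is a strictly monotone numeric vector in cm^-1,
#' ascending or descending, with at least two points and no missing values.
#' Internally the package stores axes in descending order (4000 -> 800),
#' the usual display convention in mid-IR spectroscopy.
#'
#' @param values numeric vector of wavenumbers in cm^-1.
#' @return the validated numeric vector, invisibly unchanged.
#' @export
wavenumber_axis <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("wavenumber axis must be numeric with length >= 2")
  if (any(!is.finite(values)))
    stop("wavenumber axis contains non-finite values")
  d <- diff(values)
  if (any(d == 0) || !(all(d > 0) || all(d < 0)))
    stop("wavenumber axis must be strictly monotone with no duplicates")
  values
}

axis_step <- function(axis) mean(abs(diff(axis)))

axis_is_descending <- function(axis) axis[1] > axis[length(axis)]

# indices of axis points inside the closed interval [lo, hi]
axis_window <- function(axis, lo, hi) {
  if (!(lo < hi)) stop("range error: lo must be < hi")
  idx <- which(axis >= lo & axis <= hi)
  if (length(idx) == 0L)
    stop(sprintf("range error: [%g, %g] cm^-1 does not intersect the axis", lo, hi))
  idx
}

# ---- spectrum --------------------------------------------------------------

#' Construct a single IR spectrum
#'
#' @param wavenumber wavenumber axis in cm^-1 (strictly monotone).
#' @param absorbance absorbance values (unitless), same length as the axis.
#' @return an object of class `ir_spectrum`: a list with elements
#'   `wavenumber` and `absorbance`, stored with a descending axis.
#' @export
ir_spectrum <- function(wavenumber, absorbance) {
  wavenumber <- wavenumber_axis(wavenumber)
  if (!is.numeric(absorbance) || length(absorbance) != length(wavenumber))
    stop("absorbance must be numeric and match the axis length")
  if (any(!is.finite(absorbance)))
    stop("absorbance contains NaN/Inf values")
  if (!axis_is_descending(wavenumber)) {
    wavenumber <- rev(wavenumber)
    absorbance <- rev(absorbance)
  }
  structure(list(wavenumber = as.numeric(wavenumber),
                 absorbance = as.numeric(absorbance)),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %d points, %.1f..%.1f cm^-1\n",
              length(x$wavenumber), x$wavenumber[1],
              x$wavenumber[length(x$wavenumber)]))
  invisible(x)
}

# ---- spectra set -----------------------------------------------------------

#' Construct a set of spectra sharing one wavenumber axis
#'
#' The working container for extracted per-segment mean spectra: an
#' n-spectra x n-points absorbance matrix plus per-spectrum metadata
#' (cell id, segment kind, sample id, class label, pixel count).
#'
#' @param absorbance numeric matrix, one row per spectrum.
#' @param wavenumber shared wavenumber axis, length `ncol(absorbance)`.
#' @param meta data.frame with one row per spectrum; recognised columns are
#'   `cell_id`, `segment` (one of "cell", "nucleus", "cytoplasm"),
#'   `sample_id`, `class_label`, `n_pixels`. Missing columns are filled
#'   with defaults.
#' @return an object of class `spectra_set`.
#' @export
spectra_set <- function(absorbance, wavenumber, meta = NULL) {
  if (is.null(dim(absorbance))) absorbance <- matrix(absorbance, nrow = 1L)
  wavenumber <- wavenumber_axis(wavenumber)
  if (ncol(absorbance) != length(wavenumber))
    stop("absorbance columns must match the axis length")
  if (any(!is.finite(absorbance)))
    stop("absorbance contains NaN/Inf values")
  n <- nrow(absorbance)
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(n))
  if (nrow(meta) != n) stop("meta must have one row per spectrum")
  defaults <- list(cell_id = seq_len(n), segment = "cell",
                   sample_id = "sample", class_label = "unknown",
                   n_pixels = 1L)
  for (nm in names(defaults))
    if (is.null(meta[[nm]])) meta[[nm]] <- defaults[[nm]]
  bad <- !meta$segment %in% c("cell", "nucleus", "cytoplasm")
  if (any(bad)) stop("segment must be one of cell/nucleus/cytoplasm")
  if (any(meta$n_pixels < 1L)) stop("n_pixels must be >= 1")
  if (!axis_is_descending(wavenumber)) {
    wavenumber <- rev(wavenumber)
    absorbance <- absorbance[, rev(seq_along(wavenumber)), drop = FALSE]
  }
  structure(list(wavenumber = as.numeric(wavenumber),
                 absorbance = unname(as.matrix(absorbance)),
                 meta = meta),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d points, %.1f..%.1f cm^-1\n",
              nrow(x$absorbance), ncol(x$absorbance),
              x$wavenumber[1], x$wavenumber[length(x$wavenumber)]))
  if (nrow(x$meta))
    print(utils::head(x$meta, 4L))
  invisible(x)
}

#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$absorbance[i, , drop = FALSE], x$wavenumber,
              x$meta[i, , drop = FALSE])
}

#' Number of spectra in a set
#' @param x a `spectra_set`.
#' @return integer count of spectra.
#' @export
n_spectra <- function(x) nrow(x$absorbance)

# ---- hyperspectral cube ----------------------------------------------------

#' Construct a hyperspectral cube
#'
#' One focal-plane-array field of view: a rows x cols x bands absorbance
#' array with its wavenumber axis and the physical pixel pitch.
#'
#' @param data numeric array `rows x cols x bands`.
#' @param wavenumber wavenumber axis, length `dim(data)[3]`.
#' @param pixel_size_um physical pixel pitch in micrometres (default 5.5,
#'   the projected pixel size of a 128 x 128 FPA tile at 15x magnification).
#' @return an object of class `hyper_cube`.
#' @export
hyper_cube <- function(data, wavenumber, pixel_size_um = 5.5) {
  if (length(dim(data)) != 3L) stop("data must be a 3-D array")
  wavenumber <- wavenumber_axis(wavenumber)
  if (dim(data)[3] != length(wavenumber))
    stop("third array dimension must match the axis length")
  if (any(!is.finite(data))) stop("cube contains NaN/Inf values")
  if (!axis_is_descending(wavenumber)) {
    wavenumber <- rev(wavenumber)
    data <- data[, , rev(seq_along(wavenumber)), drop = FALSE]
  }
  structure(list(data = data, wavenumber = as.numeric(wavenumber),
                 pixel_size_um = pixel_size_um),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> %d x %d px (%.1f um), %d bands %.1f..%.1f cm^-1\n",
              d[1], d[2], x$pixel_size_um, d[3],
              x$wavenumber[1], x$wavenumber[length(x$wavenumber)]))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$data)

# ---- ENVI cube reader/writer -----------------------------------------------

# ENVI data type codes used here: 4 = 32-bit float, 5 = 64-bit float
.envi_sizes <- c("4" = 4L, "5" = 8L)

envi_raw_path <- function(header_path) {
  base <- sub("\\.hdr$", "", header_path)
  for (ext in c(".raw", ".dat", ".img", "")) {
    p <- paste0(base, ext)
    if (file.exists(p) && p != header_path) return(p)
  }
  paste0(base, ".raw")
}

parse_envi_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^\\s*", key,
                                        "\\s*=\\s*([^\\n{]+)"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2L) return(NA_character_)
    trimws(m[2])
  }
  get_list <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?si)", key, "\\s*=\\s*\\{([^}]*)\\}"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2L) return(NULL)
    vals <- strsplit(m[2], "[,\\s]+")[[1]]
    as.numeric(vals[nzchar(vals)])
  }
  hdr <- list(
    samples    = as.integer(get_scalar("samples")),
    lines      = as.integer(get_scalar("lines")),
    bands      = as.integer(get_scalar("bands")),
    data_type  = as.integer(get_scalar("data type")),
    interleave = tolower(get_scalar("interleave")),
    byte_order = as.integer(get_scalar("byte order")),
    offset     = as.integer(get_scalar("header offset")),
    pixel_size = as.numeric(get_scalar("pixel size um")),
    wavelength = get_list("wavelength")
  )
  if (anyNA(c(hdr$samples, hdr$lines, hdr$bands)))
    stop("format error: ENVI header missing samples/lines/bands")
  if (is.null(hdr$wavelength))
    stop("format error: ENVI header has no wavelength (wavenumber) list")
  if (length(hdr$wavelength) != hdr$bands)
    stop("format error: wavelength list length does not match bands")
  if (!hdr$interleave %in% c("bsq", "bil", "bip"))
    stop("format error: unsupported interleave '", hdr$interleave, "'")
  if (!as.character(hdr$data_type) %in% names(.envi_sizes))
    stop("format error: unsupported ENVI data type ", hdr$data_type)
  if (is.na(hdr$offset)) hdr$offset <- 0L
  hdr
}

#' Read an ENVI header/raster hyperspectral cube
#'
#' Supports BSQ/BIL/BIP interleaves, 32- and 64-bit floats, both byte
#' orders, and takes the wavenumber axis from the header `wavelength`
#' block. The raster file is located next to the header (`.raw`, `.dat`,
#' `.img` or extensionless).
#'
#' @param header_path path to the `.hdr` file.
#' @return a [hyper_cube()].
#' @export
read_envi_cube <- function(header_path) {
  if (!file.exists(header_path)) stop("I/O error: no such header: ", header_path)
  hdr <- parse_envi_header(header_path)
  raw_path <- envi_raw_path(header_path)
  if (!file.exists(raw_path)) stop("I/O error: raster file not found for ", header_path)
  n <- hdr$samples * hdr$lines * hdr$bands
  size <- .envi_sizes[[as.character(hdr$data_type)]]
  expected <- hdr$offset + as.numeric(n) * size
  actual <- file.size(raw_path)
  if (actual != expected)
    stop(sprintf("format error: raster is %d bytes but header implies %d",
                 actual, as.integer(expected)))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  if (hdr$offset > 0L) readBin(con, "raw", n = hdr$offset)
  endian <- if (identical(hdr$byte_order, 1L)) "big" else "little"
  vals <- readBin(con, "double", n = n, size = size, endian = endian)
  if (any(!is.finite(vals)))
    stop("format error: raster contains NaN/Inf values")
  # ENVI order (fastest..slowest): BSQ sample,line,band; BIL sample,band,line;
  # BIP band,sample,line. R fills the first array index fastest.
  arr <- switch(hdr$interleave,
    bsq = aperm(array(vals, c(hdr$samples, hdr$lines, hdr$bands)), c(2, 1, 3)),
    bil = aperm(array(vals, c(hdr$samples, hdr$bands, hdr$lines)), c(3, 1, 2)),
    bip = aperm(array(vals, c(hdr$bands, hdr$samples, hdr$lines)), c(3, 2, 1)))
  px <- if (is.na(hdr$pixel_size)) 5.5 else hdr$pixel_size
  hyper_cube(arr, hdr$wavelength, pixel_size_um = px)
}

#' Write a hyperspectral cube as ENVI header + raster
#'
#' @param cube a [hyper_cube()].
#' @param header_path output `.hdr` path; the raster is written next to it
#'   with a `.raw` extension.
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type `"double"` (64-bit, lossless round-trip) or `"float"`.
#' @return the header path, invisibly.
#' @export
write_envi_cube <- function(cube, header_path,
                            interleave = c("bsq", "bil", "bip"),
                            data_type = c("double", "float")) {
  stopifnot(inherits(cube, "hyper_cube"))
  interleave <- match.arg(interleave)
  data_type <- match.arg(data_type)
  d <- dim(cube$data)
  code <- if (data_type == "double") 5L else 4L
  size <- .envi_sizes[[as.character(code)]]
  hdr <- c("ENVI",
           "description = { spectrapheno hyperspectral cube }",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           paste0("data type = ", code),
           paste0("interleave = ", interleave),
           "byte order = 0",
           paste0("pixel size um = ", format(cube$pixel_size_um, digits = 17)),
           "wavelength units = Wavenumber (cm-1)",
           paste0("wavelength = { ",
                  paste(format(cube$wavenumber, digits = 17, trim = TRUE,
                               scientific = FALSE), collapse = ", "),
                  " }"))
  ok <- tryCatch({ writeLines(hdr, header_path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("I/O error: cannot write header ", header_path)
  perm <- switch(interleave, bsq = c(2, 1, 3), bil = c(2, 3, 1),
                 bip = c(3, 2, 1))
  vals <- as.vector(aperm(cube$data, perm))
  raw_path <- paste0(sub("\\.hdr$", "", header_path), ".raw")
  con <- file(raw_path, "wb")
  on.exit(close(con))
  writeBin(vals, con, size = size, endian = "little")
  invisible(header_path)
}

# ---- spectra tables --------------------------------------------------------

.meta_keys <- c("sample_id", "class_label", "segment", "cell_id", "n_pixels")

#' Read a delimited spectra table
#'
#' Format: optional metadata rows whose first field is `#sample_id`,
#' `#class_label`, `#segment`, `#cell_id` or `#n_pixels`; then a header
#' row (`wavenumber`, spectrum ids...); then one numeric row per
#' wavenumber, first column the axis, remaining columns one spectrum each.
#'
#' @param path path to a comma- or tab-delimited file.
#' @param sep field separator, `","` by default.
#' @return a [spectra_set()].
#' @export
read_spectra_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L) stop("format error: table too short")
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L)
    stop(sprintf("format error: ragged rows (row %d has %d fields, expected %d)",
                 which(widths != widths[1])[1], widths[widths != widths[1]][1],
                 widths[1]))
  ncols <- widths[1]
  if (ncols < 2L) stop("format error: need a wavenumber column plus spectra")
  is_meta <- startsWith(lines, "#")
  meta_rows <- fields[is_meta]
  body <- fields[!is_meta]
  header <- body[[1]]
  ids <- header[-1]
  body <- body[-1]
  m <- matrix(NA_real_, nrow = length(body), ncol = ncols)
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf(
        "format error: non-numeric or non-finite cell at data row %d, column '%s'",
        i, if (bad[1] == 1L) "wavenumber" else ids[bad[1] - 1L]))
    m[i, ] <- v
  }
  meta <- data.frame(row.names = seq_along(ids))
  for (row in meta_rows) {
    key <- sub("^#", "", row[1])
    if (!key %in% .meta_keys) next
    vals <- row[-1]
    if (key %in% c("cell_id", "n_pixels")) vals <- as.integer(vals)
    meta[[key]] <- vals
  }
  spectra_set(t(m[, -1, drop = FALSE]), m[, 1], meta)
}

#' Write a spectra set as a delimited table
#'
#' Inverse of [read_spectra_table()]: metadata rows, a header row, then
#' one row per wavenumber.
#'
#' @param x a `spectra_set`.
#' @param path output path.
#' @param sep field separator.
#' @return the path, invisibly.
#' @export
write_spectra_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "spectra_set"))
  n <- n_spectra(x)
  ids <- paste0("spec_", seq_len(n))
  fmt <- function(v) format(v, digits = 15, trim = TRUE, scientific = TRUE)
  out <- character(0)
  for (key in .meta_keys)
    out <- c(out, paste(c(paste0("#", key), as.character(x$meta[[key]])),
                        collapse = sep))
  out <- c(out, paste(c("wavenumber", ids), collapse = sep))
  # apply over rows yields a points x spectra character matrix
  block <- cbind(fmt(x$wavenumber),
                 if (n == 1L) fmt(as.vector(x$absorbance))
                 else apply(x$absorbance, 1, fmt))
  out <- c(out, apply(block, 1, paste, collapse = sep))
  ok <- tryCatch({ writeLines(out, path); TRUE }, error = function(e) FALSE)
  if (!ok) stop("I/O error: cannot write ", path)
  invisible(path)
}

# ---- cropping --------------------------------------------------------------

#' Crop to a closed wavenumber interval
#'
#' Retains exactly the axis points with `lo <= v <= hi` (closed at both
#' ends), preserving storage order. Errors if the interval misses the axis.
#'
#' @param x an `ir_spectrum`, `spectra_set` or `hyper_cube`.
#' @param lo,hi interval bounds in cm^-1, `lo < hi`.
#' @return object of the same class, restricted to the window.
#' @export
crop_to_range <- function(x, lo, hi) UseMethod("crop_to_range")

#' @export
crop_to_range.ir_spectrum <- function(x, lo, hi) {
  idx <- axis_window(x$wavenumber, lo, hi)
  # a one-point crop is a legitimate degenerate result: bypass the
  # length >= 2 axis validation, storage order is inherited anyway
  structure(list(wavenumber = x$wavenumber[idx],
                 absorbance = x$absorbance[idx]),
            class = "ir_spectrum")
}

#' @export
crop_to_range.spectra_set <- function(x, lo, hi) {
  idx <- axis_window(x$wavenumber, lo, hi)
  out <- x
  out$wavenumber <- x$wavenumber[idx]
  out$absorbance <- x$absorbance[, idx, drop = FALSE]
  out
}

#' @export
crop_to_range.hyper_cube <- function(x, lo, hi) {
  idx <- axis_window(x$wavenumber, lo, hi)
  hyper_cube(x$data[, , idx, drop = FALSE], x$wavenumber[idx],
             x$pixel_size_um)
}
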