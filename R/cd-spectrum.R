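#' Construct a CD (or absorbance) spectrum
#'
#' A spectrum is a tibble with columns `wavelength` (nm, strictly increasing)
#' and `signal` (ellipticity in mdeg or molar units, or absorbance), carrying
#' sample metadata as attributes. Duplicate wavelengths are averaged and rows
#' are sorted on construction.
#'
#' @param wavelength Numeric wavelengths in nm (>= 2 distinct values).
#' @param signal Numeric signal, same length as `wavelength`, finite.
#' @param sample_id,cation,temperature,units Metadata: sample label, cation
#'   condition ("K" or "Na"), temperature in degrees C, and a units tag
#'   (e.g. "mdeg"). All optional.
#' @return A tibble of class `cd_spectrum`.
#' @examples
#' cd_spectrum(c(240, 265, 290), c(-3.1, 10.2, 4.0), sample_id = "s1")
#' @export
cd_spectrum <- function(wavelength, signal, sample_id = NA_character_,
                        cation = NA_character_, temperature = NA_real_,
                        units = "mdeg") {
  wavelength <- as.numeric(wavelength)
  signal <- as.numeric(signal)
  if (length(wavelength) != length(signal)) {
    abort("`wavelength` and `signal` must have the same length.")
  }
  if (anyNA(wavelength) || anyNA(signal) ||
      any(!is.finite(wavelength)) || any(!is.finite(signal))) {
    abort("spectrum values must be finite and non-missing.")
  }
  if (anyDuplicated(wavelength)) {
    agg <- tapply(signal, wavelength, mean)
    wavelength <- as.numeric(names(agg))
    signal <- as.numeric(agg)
  }
  ord <- order(wavelength)
  wavelength <- wavelength[ord]
  signal <- signal[ord]
  if (length(wavelength) < 2L) {
    abort("a spectrum needs at least 2 distinct wavelengths.")
  }
  out <- tibble(wavelength = wavelength, signal = signal)
  class(out) <- c("cd_spectrum", class(out))
  attr(out, "meta") <- list(sample_id = sample_id, cation = cation,
                            temperature = temperature, units = units)
  out
}

spectrum_meta <- function(spectrum) attr(spectrum, "meta") %||% list()

#' Read a two-column spectrum or melting file
#'
#' Reads delimited text with two numeric columns (x, signal); the delimiter is
#' auto-detected among comma, tab and semicolon and one header line is
#' tolerated. Non-numeric rows beyond the header, fewer than 2 usable points,
#' or non-finite values are rejected with a message naming the offending line.
#'
#' @param path File path.
#' @inheritParams cd_spectrum
#' @return A [cd_spectrum()] (sorted, duplicates averaged).
#' @export
read_cd_spectrum <- function(path, sample_id = NA_character_,
                             cation = NA_character_, temperature = NA_real_,
                             units = "mdeg") {
  xy <- read_two_column(path, what = "spectrum")
  cd_spectrum(xy$x, xy$y, sample_id = sample_id, cation = cation,
              temperature = temperature, units = units)
}

# shared two-column reader for spectra and melting curves
read_two_column <- function(path, what = "file") {
  if (!file.exists(path)) abort(paste0(what, " file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(paste0("empty ", what, " file: ", path))
  delim <- detect_delim(lines)
  parse_line <- function(ln) {
    parts <- if (delim == " ") strsplit(trimws(ln), "\\s+")[[1]]
             else trimws(strsplit(ln, delim, fixed = TRUE)[[1]])
    suppressWarnings(as.numeric(parts[1:2]))
  }
  parsed <- lapply(lines, parse_line)
  numeric_ok <- vapply(parsed, function(p) !anyNA(p), TRUE)
  start <- 1L
  if (!numeric_ok[1L]) start <- 2L  # tolerate a single header line
  if (start > length(lines)) {
    abort(paste0("no data rows in ", path, " (header only)."))
  }
  bad <- which(!numeric_ok[start:length(lines)])
  if (length(bad)) {
    abort(paste0("non-numeric row at line ", bad[1L] + start - 1L,
                 " of ", path, ": '", lines[bad[1L] + start - 1L], "'"))
  }
  x <- vapply(parsed[start:length(lines)], `[`, 0, 1L)
  y <- vapply(parsed[start:length(lines)], `[`, 0, 2L)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    i <- which(!is.finite(x) | !is.finite(y))[1L]
    abort(paste0("non-finite value at line ", i + start - 1L, " of ", path))
  }
  if (length(x) < 2L) abort(paste0("fewer than 2 usable points in ", path))
  list(x = x, y = y)
}

detect_delim <- function(lines) {
  probe <- head(lines, 5L)
  counts <- vapply(c(",", "\t", ";"), function(d) {
    sum(vapply(probe, function(ln) {
      p <- gregexpr(d, ln, fixed = TRUE)[[1]]
      if (p[1L] == -1L) 0L else length(p)
    }, 0L))
  }, 0)
  cands <- names(counts)[counts > 0]
  if (length(cands) == 0L) " " else cands[which.max(counts[cands])]
}

#' Interpolate a spectrum at a wavelength
#'
#' Linear interpolation between the two bracketing grid points; exact grid
#' hits return the stored value. Queries outside the grid by at most `margin`
#' nm return the nearest endpoint value (flagged when used internally);
#' farther queries are an error.
#'
#' @param spectrum A [cd_spectrum()].
#' @param wavelength Query wavelengths in nm (vectorised).
#' @param margin Extrapolation tolerance in nm (default 2).
#' @return Numeric signal values.
#' @export
spectrum_value_at <- function(spectrum, wavelength, margin = 2) {
  vapply(wavelength,
         function(w) value_at_impl(spectrum, w, margin)$value, 0)
}

value_at_impl <- function(spectrum, w, margin = 2) {
  wl <- spectrum$wavelength
  lo <- wl[1L]
  hi <- wl[length(wl)]
  if (w < lo - margin || w > hi + margin) {
    abort(sprintf(
      "wavelength %.6g nm outside spectrum range [%.6g, %.6g] by more than %g nm",
      w, lo, hi, margin))
  }
  if (w < lo || w > hi) {
    return(list(value = if (w < lo) spectrum$signal[1L]
                        else spectrum$signal[length(wl)],
                extrapolated = TRUE))
  }
  v <- approx(wl, spectrum$signal, xout = w, method = "linear", ties = mean)$y
  list(value = v, extrapolated = FALSE)
}

#' Difference spectrum (TDS / IDS)
#'
#' Pointwise `minuend - subtrahend` on the union grid of the overlapping
#' wavelength range, both spectra evaluated by linear interpolation. The
#' thermal difference spectrum (TDS) is unfolded(high T) minus folded(low T)
#' absorbance and the isothermal difference spectrum (IDS) folded minus
#' unfolded at one temperature; this operation is agnostic to the roles.
#'
#' @param minuend,subtrahend [cd_spectrum()] objects with overlapping ranges.
#' @param normalize If `TRUE`, scale so that the maximum absolute value is 1.
#' @return A [cd_spectrum()] on the intersection grid.
#' @export
difference_spectrum <- function(minuend, subtrahend, normalize = FALSE) {
  lo <- max(min(minuend$wavelength), min(subtrahend$wavelength))
  hi <- min(max(minuend$wavelength), max(subtrahend$wavelength))
  if (lo > hi) abort("spectra have no overlapping wavelength range.")
  grid <- sort(unique(c(
    minuend$wavelength[minuend$wavelength >= lo & minuend$wavelength <= hi],
    subtrahend$wavelength[subtrahend$wavelength >= lo & subtrahend$wavelength <= hi]
  )))
  if (length(grid) < 2L) abort("wavelength overlap has fewer than 2 points.")
  d <- spectrum_value_at(minuend, grid, margin = 0) -
    spectrum_value_at(subtrahend, grid, margin = 0)
  if (normalize) {
    m <- max(abs(d))
    if (m > 0) d <- d / m
  }
  meta <- spectrum_meta(minuend)
  cd_spectrum(grid, d, sample_id = meta$sample_id, cation = meta$cation,
              units = paste0("diff_", meta$units %||% "mdeg"))
}

#' Plot a spectrum
#'
#' @param object A [cd_spectrum()].
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.cd_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength, .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)", y = "Signal",
                  title = spectrum_meta(object)$sample_id)
}
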