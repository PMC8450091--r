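#' Construct a UV-melting curve
#'
#' @param temperature Temperatures in degrees C, strictly increasing after
#'   sorting, >= 5 points.
#' @param absorbance Absorbance at the monitored wavelength, finite.
#' @param sample_id Sample label.
#' @param wavelength Monitored wavelength in nm (default 295, the standard
#'   G-quadruplex melting wavelength, hypochromic on unfolding).
#' @param cation Cation condition ("K" or "Na").
#' @return A tibble of class `melting_curve` with columns `temperature`,
#'   `absorbance` and metadata attributes.
#' @export
melting_curve <- function(temperature, absorbance, sample_id = NA_character_,
                          wavelength = 295, cation = NA_character_) {
  temperature <- as.numeric(temperature)
  absorbance <- as.numeric(absorbance)
  if (length(temperature) != length(absorbance)) {
    abort("`temperature` and `absorbance` must have the same length.")
  }
  if (any(!is.finite(temperature)) || any(!is.finite(absorbance))) {
    abort("melting-curve values must be finite.")
  }
  ord <- order(temperature)
  temperature <- temperature[ord]
  absorbance <- absorbance[ord]
  if (length(temperature) < 5L) abort("a melting curve needs >= 5 points.")
  if (any(diff(temperature) <= 0)) {
    abort("temperatures must be strictly increasing (no duplicates).")
  }
  out <- tibble(temperature = temperature, absorbance = absorbance)
  class(out) <- c("melting_curve", class(out))
  attr(out, "meta") <- list(sample_id = sample_id, wavelength = wavelength,
                            cation = cation)
  out
}

#' Read a melting curve from a two-column file
#'
#' @param path Delimited file with (temperature, absorbance) columns; the
#'   delimiter is auto-detected and one header line is tolerated.
#' @inheritParams melting_curve
#' @return A [melting_curve()].
#' @export
read_melting_curve <- function(path, sample_id = NA_character_,
                               wavelength = 295, cation = NA_character_) {
  xy <- read_two_column(path, what = "melting")
  melting_curve(xy$x, xy$y, sample_id = sample_id, wavelength = wavelength,
                cation = cation)
}

#' First derivative of a melting curve
#'
#' Central finite differences of the (optionally moving-average smoothed)
#' absorbance with respect to temperature; the endpoints use one-sided
#' differences. Smoothing uses a centred moving average whose window shrinks
#' at the edges.
#'
#' @param curve A [melting_curve()].
#' @param smooth_window Odd integer >= 1; 1 means no smoothing. The default 5
#'   damps the noise amplification inherent in differentiation.
#' @return A tibble with columns `temperature` and `dA_dT`.
#' @export
melting_derivative <- function(curve, smooth_window = 5L) {
  stopifnot(inherits(curve, "melting_curve"))
  w <- as.integer(smooth_window)
  if (is.na(w) || w < 1L || w %% 2L == 0L) {
    abort("`smooth_window` must be an odd integer >= 1.")
  }
  n <- nrow(curve)
  if (w >= n) abort("`smooth_window` must be smaller than the number of points.")
  a <- moving_average(curve$absorbance, w)
  t <- curve$temperature
  d <- numeric(n)
  d[1L] <- (a[2L] - a[1L]) / (t[2L] - t[1L])
  d[n] <- (a[n] - a[n - 1L]) / (t[n] - t[n - 1L])
  i <- 2:(n - 1L)
  d[i] <- (a[i + 1L] - a[i - 1L]) / (t[i + 1L] - t[i - 1L])
  tibble(temperature = t, dA_dT = d)
}

moving_average <- function(x, w) {
  if (w == 1L) return(x)
  h <- (w - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    mean(x[lo:hi])
  }, 0)
}

#' Melting temperature by first-derivative analysis
#'
#' Tm is the temperature of the global extremum of the first derivative of
#' the melting curve, refined off the grid by a three-point parabolic fit
#' through the peak. The extremum is located on |dA/d(1/T)| = |dA/dT| T^2
#' (T in kelvin) rather than |dA/dT| itself: a two-state transition is
#' symmetric in inverse temperature, so the inverse-coordinate peak falls on
#' the transition midpoint, whereas the plain dA/dT peak is biased a few
#' tenths of a degree low. Because the absolute derivative is used, the sign
#' convention of the transition (hypo- vs hyperchromic) never matters, and
#' Tm is invariant to affine transforms of the absorbance.
#'
#' Flags: `multiple-extrema` when more than one separate derivative region
#' reaches 90% of the global peak (ambiguous or multiphasic transition),
#' `edge-extremum` when the extremum sits at the first or last interior grid
#' point, and `low-amplitude` when the derivative peak barely rises above the
#' baseline derivative level (max |dA/dT| < 3 x median |dA/dT|), as for a
#' near-linear curve with no transition.
#'
#' @inheritParams melting_derivative
#' @return An object of class `g4_melting_fit`: a list with `tm` (degrees C),
#'   `direction` ("hyperchromic" or "hypochromic", the sign of dA/dT at the
#'   transition), `derivative` (tibble), `flags` (character vector) and
#'   `sample_id`. Use [tidy()] for a one-row tibble.
#' @examples
#' cv <- synth_melting(tm_true = 55, dH = -40, noise_sd = 0)
#' compute_tm(cv)$tm
#' @export
compute_tm <- function(curve, smooth_window = 5L) {
  deriv <- melting_derivative(curve, smooth_window)
  n <- nrow(deriv)
  interior <- 2:(n - 1L)
  # |dA/d(1/T)| = |dA/dT| T^2: symmetric in 1/T for a two-state transition
  ad <- abs(deriv$dA_dT) * (deriv$temperature + 273.15)^2
  i <- interior[which.max(ad[interior])]
  flags <- character()

  # parabolic refinement over the contiguous run of points within 60% of the
  # peak; wide-support least squares is far less noise-sensitive than a
  # three-point vertex, which is kept as the fallback for narrow peaks
  t <- deriv$temperature
  top <- which(ad >= 0.6 * ad[i])
  runs <- split(top, cumsum(c(1L, diff(top) > 1L)))
  top <- runs[[which(vapply(runs, function(r) i %in% r, TRUE))]]
  tm <- NA_real_
  if (length(top) >= 4L) {
    co <- stats::coef(stats::lm(ad[top] ~ t[top] + I(t[top]^2)))
    if (is.finite(co[3]) && co[3] < 0) tm <- -co[2] / (2 * co[3])
  }
  if (!is.finite(tm) || tm < t[max(1L, min(top) - 1L)] ||
      tm > t[min(n, max(top) + 1L)]) {
    y0 <- ad[i - 1L]; y1 <- ad[i]; y2 <- ad[i + 1L]
    denom <- y0 - 2 * y1 + y2
    offset <- if (abs(denom) > .Machine$double.eps * max(ad, 1)) {
      max(-1, min(1, 0.5 * (y0 - y2) / denom))
    } else 0
    step <- if (offset >= 0) t[i + 1L] - t[i] else t[i] - t[i - 1L]
    tm <- t[i] + offset * abs(step)
  }
  tm <- max(t[1L], min(t[n], tm))

  # competing extrema: separate |dA/dT| regions reaching 90% of the maximum,
  # where regions only count as separate if the valley between them drops
  # below 70% — noise jitter within one broad transition is not a second one
  adu <- abs(deriv$dA_dT)
  peak_u <- max(adu[interior])
  high <- which(adu >= 0.9 * peak_u)
  if (length(high) > 1L) {
    gaps <- which(diff(high) > 1L)
    n_regions <- 1L
    for (g in gaps) {
      valley <- min(adu[high[g]:high[g + 1L]])
      if (valley < 0.7 * peak_u) n_regions <- n_regions + 1L
    }
    if (n_regions > 1L) flags <- c(flags, "multiple-extrema")
  }
  if (i == interior[1L] || i == interior[length(interior)]) {
    flags <- c(flags, "edge-extremum")
  }
  if (ad[i] < 3 * median(ad)) flags <- c(flags, "low-amplitude")

  structure(
    list(tm = tm,
         direction = if (deriv$dA_dT[i] >= 0) "hyperchromic" else "hypochromic",
         derivative = deriv, flags = flags,
         sample_id = attr(curve, "meta")$sample_id %||% NA_character_),
    class = "g4_melting_fit"
  )
}

#' @export
print.g4_melting_fit <- function(x, ...) {
  cat("<g4_melting_fit> ", x$sample_id, "\n", sep = "")
  cat(sprintf("  Tm = %.2f degC (%s)\n", x$tm, x$direction))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname compute_tm
#' @param x A `g4_melting_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.g4_melting_fit <- function(x, ...) {
  tibble(sample_id = x$sample_id, tm = x$tm, direction = x$direction,
         flags = paste(x$flags, collapse = ","))
}

#' Pairwise melting-temperature change
#'
#' Delta-Tm = Tm(flanked) - Tm(bare); negative values mean the flanking
#' nucleotides destabilise the structure.
#'
#' @param tm_flanked,tm_bare Tm values in degrees C, or `g4_melting_fit`
#'   objects.
#' @return Numeric delta-Tm in degrees C (vectorised).
#' @examples
#' delta_tm(43.5, 60.0)
#' @export
delta_tm <- function(tm_flanked, tm_bare) {
  as_tm <- function(x) {
    if (inherits(x, "g4_melting_fit")) x$tm else as.numeric(x)
  }
  as_tm(tm_flanked) - as_tm(tm_bare)
}

#' Plot a melting curve with its derivative peak
#'
#' @param curve A [melting_curve()].
#' @param fit Optional `g4_melting_fit` from [compute_tm()]; its Tm is drawn
#'   as a vertical line.
#' @return A ggplot.
#' @export
plot_melting_curve <- function(curve, fit = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$temperature, .data$absorbance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Temperature (°C)", y = "Absorbance")
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_vline(xintercept = fit$tm, linetype = "dashed")
  }
  p
}
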