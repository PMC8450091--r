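#' Conformation index r of a CD spectrum
#'
#' Computes r = CD265 / (|CD265| + CD290), where CD265 and CD290 are the
#' ellipticities at 265 and 290 nm read off the spectrum by linear
#' interpolation (no smoothing or band integration, so r is exactly the
#' point-ellipticity ratio). The index summarises the topology ensemble of an
#' intramolecular G-quadruplex: predominantly parallel folds have a strong
#' positive 265 nm band (r >= 0.5), antiparallel folds a negative 265 nm band
#' with a positive 290 nm band (r < 0), and hybrids sit in between
#' (0 <= r < 0.5).
#'
#' Quality flags rather than hard failures record the awkward cases:
#' `small-denominator` when |CD265| + CD290 is below `eps_rel` times the
#' spectrum's maximum absolute signal (r is then undefined), `negative-290`
#' when CD290 < 0 (r is computed as-is), `out-of-range-r` when |r| > 1, and
#' `extrapolated` when 265 or 290 nm fell outside the grid by at most
#' `margin` nm and the nearest endpoint was used.
#'
#' @param spectrum A [cd_spectrum()] covering (or nearly covering) 265 and
#'   290 nm.
#' @param eps_rel Relative denominator tolerance: denominators at or below
#'   `eps_rel * max(|signal|)` are treated as zero (default 1e-6). Relative,
#'   so the result is unit-independent.
#' @param margin Interpolation margin in nm passed to the band reader.
#' @return A one-row tibble: `sample_id`, `r`, `cd265`, `cd290`, `label`
#'   (parallel / hybrid / antiparallel / undefined) and `flags`
#'   (comma-separated, empty when clean).
#' @examples
#' sp <- cd_spectrum(seq(230, 310, 5), cos((seq(230, 310, 5) - 264) / 12))
#' conformation_index(sp)
#' @export
conformation_index <- function(spectrum, eps_rel = 1e-6, margin = 2) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  v265 <- value_at_impl(spectrum, 265, margin)
  v290 <- value_at_impl(spectrum, 290, margin)
  cd265 <- v265$value
  cd290 <- v290$value
  flags <- character()
  if (isTRUE(v265$extrapolated) || isTRUE(v290$extrapolated)) {
    flags <- c(flags, "extrapolated")
  }
  if (cd290 < 0) flags <- c(flags, "negative-290")
  denom <- abs(cd265) + cd290
  eps <- eps_rel * max(abs(spectrum$signal))
  if (abs(denom) <= eps) {
    flags <- c(flags, "small-denominator")
    r <- NA_real_
  } else {
    r <- cd265 / denom
    if (abs(r) > 1) flags <- c(flags, "out-of-range-r")
  }
  tibble(
    sample_id = spectrum_meta(spectrum)$sample_id %||% NA_character_,
    r = r, cd265 = cd265, cd290 = cd290,
    label = classify_r(r),
    flags = paste(flags, collapse = ",")
  )
}

#' Classify a conformation index value
#'
#' Thresholds are closed exactly as conventionally printed: parallel iff
#' r >= 0.5, hybrid iff 0 <= r < 0.5, antiparallel iff r < 0. Non-finite r
#' maps to "undefined".
#'
#' @param r Numeric conformation index values (vectorised).
#' @return Character vector in
#'   `{"parallel", "hybrid", "antiparallel", "undefined"}`.
#' @examples
#' classify_r(c(0.6, 0.27, -0.13, 0.5, 0))
#' @export
classify_r <- function(r) {
  out <- rep("undefined", length(r))
  fin <- is.finite(r)
  out[fin & r >= 0.5] <- "parallel"
  out[fin & r >= 0 & r < 0.5] <- "hybrid"
  out[fin & r < 0] <- "antiparallel"
  out
}
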