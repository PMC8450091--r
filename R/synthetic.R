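#' Gaussian-band basis model for synthetic CD spectra
#'
#' Synthetic CD spectra are built as sums of Gaussian bands, one basis curve
#' per topology. The default bands reproduce the qualitative signatures CD
#' reads for G-quadruplexes: a dominant positive band near 265 nm for the
#' parallel fold, a positive 290 nm band with a negative 265 nm trough for
#' the antiparallel fold, and both a 290 nm shoulder and a 268 nm peak for
#' hybrids. Amplitudes are arbitrary units; only their ratios matter to the
#' conformation index r, and the constructor refuses models whose pure bases
#' do not classify correctly (parallel r >= 0.9, antiparallel r < 0, hybrid
#' 0 <= r < 0.5).
#'
#' @param bands Named list (`parallel`, `antiparallel`, `hybrid`) of data
#'   frames with columns `center` (nm), `width` (nm, Gaussian sigma) and
#'   `amplitude` (signed). Defaults as described.
#' @param wl_range Wavelength range in nm (default 220-320).
#' @param step Grid step in nm (default 1).
#' @return An object of class `cd_basis_model`.
#' @examples
#' m <- cd_basis_model()
#' conformation_index(basis_spectrum("parallel", m))
#' @export
cd_basis_model <- function(bands = NULL, wl_range = c(220, 320), step = 1) {
  if (is.null(bands)) {
    bands <- list(
      parallel = data.frame(center = c(264, 242), width = c(9, 8),
                            amplitude = c(1.00, -0.45)),
      antiparallel = data.frame(center = c(292, 265, 245),
                                width = c(10, 9, 8),
                                amplitude = c(0.70, -0.55, 0.35)),
      hybrid = data.frame(center = c(290, 268, 242), width = c(10, 9, 8),
                          amplitude = c(0.65, 0.55, -0.35))
    )
  }
  if (!all(c("parallel", "antiparallel", "hybrid") %in% names(bands))) {
    abort("`bands` must name parallel, antiparallel and hybrid topologies.")
  }
  model <- structure(list(bands = bands, wl_range = wl_range, step = step),
                     class = "cd_basis_model")
  # self-consistency gate: each pure basis must land in its own r class
  rp <- conformation_index(basis_spectrum("parallel", model))$r
  ra <- conformation_index(basis_spectrum("antiparallel", model))$r
  rh <- conformation_index(basis_spectrum("hybrid", model))$r
  if (!(is.finite(rp) && rp >= 0.9)) {
    abort(sprintf("parallel basis must give r >= 0.9 (got %.3f).", rp))
  }
  if (!(is.finite(ra) && ra < 0)) {
    abort(sprintf("antiparallel basis must give r < 0 (got %.3f).", ra))
  }
  if (!(is.finite(rh) && rh >= 0 && rh < 0.5)) {
    abort(sprintf("hybrid basis must give 0 <= r < 0.5 (got %.3f).", rh))
  }
  model
}

#' Evaluate a pure-topology basis spectrum
#'
#' @param topology `"parallel"`, `"antiparallel"` or `"hybrid"`.
#' @param model A [cd_basis_model()] (built on the fly when omitted — note
#'   the constructor itself calls this, so internal callers pass an
#'   unvalidated model list).
#' @return A [cd_spectrum()] on the model grid.
#' @export
basis_spectrum <- function(topology, model = cd_basis_model()) {
  if (!topology %in% names(model$bands)) {
    abort(paste0("unknown topology '", topology, "'."))
  }
  wl <- seq(model$wl_range[1], model$wl_range[2], by = model$step)
  b <- model$bands[[topology]]
  sig <- rep(0, length(wl))
  for (i in seq_len(nrow(b))) {
    sig <- sig + b$amplitude[i] * exp(-((wl - b$center[i])^2) / (2 * b$width[i]^2))
  }
  cd_spectrum(wl, sig, sample_id = paste0("basis_", topology), units = "a.u.")
}

#' Mix topology basis spectra into an ensemble spectrum
#'
#' Ensemble CD spectra are modelled as convex combinations of the pure
#' topology bases — the standard assumption that CD is linear in the
#' population fractions — plus independent Gaussian noise per grid point.
#'
#' @param fractions Numeric triple `(parallel, hybrid, antiparallel)` on the
#'   simplex (non-negative, summing to 1 within 1e-9).
#' @param model A [cd_basis_model()].
#' @param noise_sd Standard deviation of the additive noise, in the basis
#'   amplitude units (default 0).
#' @param seed Optional integer seed for reproducible noise.
#' @param sample_id Sample label for the result.
#' @return A [cd_spectrum()].
#' @examples
#' mix_spectra(c(0.5, 0.3, 0.2))
#' @export
mix_spectra <- function(fractions, model = cd_basis_model(), noise_sd = 0,
                        seed = NULL, sample_id = NA_character_) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions < -1e-9) ||
      abs(sum(fractions) - 1) > 1e-9) {
    abort("`fractions` must be a non-negative triple summing to 1 (within 1e-9).")
  }
  fractions <- pmax(fractions, 0)
  sp <- basis_spectrum("parallel", model)
  sh <- basis_spectrum("hybrid", model)
  sa <- basis_spectrum("antiparallel", model)
  sig <- fractions[1] * sp$signal + fractions[2] * sh$signal +
    fractions[3] * sa$signal
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(seed)
    }
    sig <- sig + rnorm(length(sig), 0, noise_sd)
  }
  cd_spectrum(sp$wavelength, sig, sample_id = sample_id, units = "a.u.")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Simulate a two-state UV-melting curve
#'
#' Van't Hoff two-state model: the folded fraction is
#' `theta(T) = 1 / (1 + exp[(dH/R) (1/T - 1/Tm)])` with temperatures in
#' kelvin, `R = 1.987e-3` kcal/(mol K) and `dS = dH/Tm` implied, so
#' `theta(Tm) = 1/2` exactly and, for `dH < 0`, theta decreases with
#' temperature. The absorbance is the theta-weighted mix of linear folded and
#' unfolded baselines plus optional Gaussian noise. The defaults describe
#' melting monitored at 295 nm, where unfolding is hypochromic (folded
#' baseline above unfolded).
#'
#' @param tm_true True melting temperature in degrees C.
#' @param dH Van't Hoff enthalpy of folding in kcal/mol, negative.
#' @param grid Temperature grid in degrees C (>= 5 points; default 20-95 by
#'   0.5).
#' @param baseline_folded,baseline_unfolded Length-2 numeric
#'   `(intercept, slope per degC)` baselines, evaluated at the grid.
#' @param noise_sd Absorbance noise standard deviation (default 0).
#' @param seed Optional integer seed.
#' @param sample_id Sample label.
#' @return A [melting_curve()].
#' @examples
#' cv <- synth_melting(55, -40, noise_sd = 0)
#' compute_tm(cv)$tm
#' @export
synth_melting <- function(tm_true, dH, grid = seq(20, 95, by = 0.5),
                          baseline_folded = c(1.0, -2e-4),
                          baseline_unfolded = c(0.7, 2e-4),
                          noise_sd = 0, seed = NULL,
                          sample_id = NA_character_) {
  if (length(grid) < 5L) abort("temperature grid needs >= 5 points.")
  if (!(dH < 0)) abort("`dH` must be negative (enthalpy of folding).")
  if (tm_true < min(grid) || tm_true > max(grid)) {
    abort("`tm_true` must lie within the temperature grid.")
  }
  R <- 1.987e-3  # kcal / (mol K)
  TK <- grid + 273.15
  TmK <- tm_true + 273.15
  theta <- 1 / (1 + exp((dH / R) * (1 / TK - 1 / TmK)))
  af <- baseline_folded[1] + baseline_folded[2] * grid
  au <- baseline_unfolded[1] + baseline_unfolded[2] * grid
  a <- theta * af + (1 - theta) * au
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(seed)
    }
    a <- a + rnorm(length(a), 0, noise_sd)
  }
  melting_curve(grid, a, sample_id = sample_id, wavelength = 295)
}

#' Flanking-effect generative model
#'
#' Encodes the planted ground truth of a synthetic flanking experiment: each
#' sequence category (by shortest-loop position) has a baseline topology
#' fraction triple `(parallel, hybrid, antiparallel)`, and adding flanks
#' shifts probability mass toward the parallel fraction. The shift is
#' `(shift5 * s(L5) + shift3 * s(L3)) * sensitivity[category]` with the
#' saturation `s(L) = 1 - 2^(-L)`, so the first flanking nucleotide carries
#' half of the maximal effect — the length dependence observed at the 5' end.
#' `shift5 > shift3` encodes the 5' > 3' asymmetry, and the damped `1bc`
#' sensitivity encodes the weaker parallelization when the first loop is the
#' shortest.
#'
#' @param baselines Named list of fraction triples per category (`1bc`,
#'   `a1c`, `ab1`, `none`), each on the simplex. Defaults: `1bc` (0.15,
#'   0.45, 0.40), `a1c` (0.70, 0.20, 0.10), `ab1` (0.35, 0.45, 0.20),
#'   `none` (0.30, 0.40, 0.30).
#' @param shift5 Maximal increase in parallel fraction from a long 5' flank
#'   (default 0.35).
#' @param shift3 Maximal 3' increment, smaller than `shift5` (default 0.05).
#' @param sensitivity Named per-category multipliers on the shift (defaults
#'   `1bc` 0.6, others 1).
#' @param baseline_jitter SD of Gaussian jitter applied to a sequence's
#'   baseline triple before renormalisation (default 0.05).
#' @param noise_sd Spectral noise SD passed to [mix_spectra()] (default 0.02).
#' @return An object of class `flanking_effect_model`.
#' @export
flanking_effect_model <- function(baselines = NULL, shift5 = 0.35,
                                  shift3 = 0.05,
                                  sensitivity = c(`1bc` = 0.6, a1c = 1,
                                                  ab1 = 1, none = 1),
                                  baseline_jitter = 0.05, noise_sd = 0.02) {
  if (is.null(baselines)) {
    baselines <- list(`1bc` = c(0.15, 0.45, 0.40),
                      a1c = c(0.70, 0.20, 0.10),
                      ab1 = c(0.35, 0.45, 0.20),
                      none = c(0.30, 0.40, 0.30))
  }
  for (nm in names(baselines)) {
    f <- baselines[[nm]]
    if (length(f) != 3L || any(f < 0) || abs(sum(f) - 1) > 1e-9) {
      abort(paste0("baseline for '", nm, "' is not on the simplex."))
    }
  }
  if (!(shift5 >= shift3 && shift3 >= 0)) {
    abort("need shift5 >= shift3 >= 0 (the 5' end dominates the effect).")
  }
  structure(list(baselines = baselines, shift5 = shift5, shift3 = shift3,
                 sensitivity = sensitivity, baseline_jitter = baseline_jitter,
                 noise_sd = noise_sd),
            class = "flanking_effect_model")
}

saturation <- function(L) 1 - 2^(-L)

#' Apply the flanking shift to a fraction triple
#'
#' Moves `(shift5 * s(L5) + shift3 * s(L3)) * sensitivity` of probability
#' mass into the parallel fraction, clipped so the triple stays on the
#' simplex; the mass is taken from the hybrid and antiparallel fractions in
#' proportion to their size.
#'
#' @param fractions `(parallel, hybrid, antiparallel)` triple on the simplex.
#' @param L5,L3 Flank lengths in nucleotides.
#' @param model A [flanking_effect_model()].
#' @param category Shortest-loop category (for the sensitivity multiplier).
#' @return The shifted triple.
#' @export
apply_flank_shift <- function(fractions, L5, L3, model, category = "none") {
  sens <- if (category %in% names(model$sensitivity)) {
    unname(model$sensitivity[[category]])
  } else 1
  delta <- (model$shift5 * saturation(L5) + model$shift3 * saturation(L3)) * sens
  delta <- min(delta, 1 - fractions[1])  # cannot exceed the simplex
  nonpar <- fractions[2] + fractions[3]
  if (nonpar <= 0 || delta <= 0) return(fractions)
  take <- delta * fractions[2:3] / nonpar
  out <- c(fractions[1] + delta, fractions[2:3] - take)
  pmin(pmax(out, 0), 1) / sum(pmin(pmax(out, 0), 1))
}

#' Simulate a whole flanking-effect experiment
#'
#' For each design pair (bare and flanked variant of the same loop triple), a
#' baseline topology-fraction triple is drawn from the design's category
#' baseline (with jitter), the flanked member's triple is shifted toward
#' parallel per the model, and CD spectra are produced by [mix_spectra()]
#' with noise. Optionally the spectra, a manifest and the ground-truth table
#' are written to disk in the same CSV formats the pipeline reads.
#'
#' @param designs A tibble of bare designs as returned by
#'   [enumerate_group()] (columns `name`, `a`, `b`, `c`, `category`), one row
#'   per pair; the flanked variant is derived from `flank_scheme`.
#' @param effect A [flanking_effect_model()].
#' @param flank_scheme Flank scheme of the flanked member (default `"DT2"`).
#' @param cation Cation tag recorded in the manifest (default `"K"`).
#' @param seed Integer seed; the whole experiment is reproducible given it.
#' @param dir Optional directory; when given, per-sample spectrum CSVs plus
#'   `manifest.csv` and `truth.csv` are written there.
#' @param basis A [cd_basis_model()].
#' @return A list with `manifest` (tibble: sample_id, name, condition
#'   bare/flanked, pair_id, group_id, category, cation, flank5, flank3,
#'   sequence, spectrum file or in-memory spectrum), `spectra` (named list of
#'   [cd_spectrum()]), and `truth` (tibble of planted fractions and the true
#'   parallel-fraction change per pair).
#' @export
synth_experiment <- function(designs, effect = flanking_effect_model(),
                             flank_scheme = "DT2", cation = "K", seed = 1L,
                             dir = NULL, basis = cd_basis_model()) {
  needed <- c("name", "a", "b", "c", "category")
  if (!all(needed %in% names(designs))) {
    abort("`designs` needs columns name, a, b, c, category (bare designs).")
  }
  if (nrow(designs) == 0L) abort("no designs supplied.")
  if (all(c("flank5", "flank3") %in% names(designs)) &&
      any(nzchar(designs$flank5) | nzchar(designs$flank3))) {
    abort("`designs` must be the bare members of each pair; the flanked variants are derived from `flank_scheme`.")
  }
  fl <- parse_flank_scheme(flank_scheme)
  if (!fl$end5 && !fl$end3) abort("flanked condition must add flanks; got WO.")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  rows <- list()
  spectra <- list()
  truth <- list()
  for (i in seq_len(nrow(designs))) {
    d <- designs[i, ]
    base_fr <- effect$baselines[[d$category]] %||% effect$baselines[["none"]]
    fr_bare <- jitter_simplex(base_fr, effect$baseline_jitter)
    L5 <- if (fl$end5) fl$k else 0L
    L3 <- if (fl$end3) fl$k else 0L
    fr_flank <- apply_flank_shift(fr_bare, L5, L3, effect, d$category)

    bare <- g4_design(c(d$a, d$b, d$c))
    flanked <- g4_design(c(d$a, d$b, d$c),
                         flank5 = strrep("T", L5), flank3 = strrep("T", L3))
    ids <- paste0(d$name, c("_WO", paste0("_", flank_scheme)))
    sp_bare <- mix_spectra(fr_bare, basis, noise_sd = effect$noise_sd,
                           sample_id = ids[1])
    sp_flank <- mix_spectra(fr_flank, basis, noise_sd = effect$noise_sd,
                            sample_id = ids[2])
    spectra[[ids[1]]] <- sp_bare
    spectra[[ids[2]]] <- sp_flank
    rows[[length(rows) + 1L]] <- tibble(
      sample_id = ids,
      name = c(g4_name(bare), g4_name(flanked)),
      condition = c("bare", "flanked"),
      scheme = c("WO", flank_scheme),
      pair_id = d$name, group_id = paste(sort(c(d$a, d$b, d$c)), collapse = ""),
      category = d$category, cation = cation,
      flank5 = c("", flanked$flank5), flank3 = c("", flanked$flank3),
      sequence = c(g4_sequence(bare), g4_sequence(flanked))
    )
    truth[[length(truth) + 1L]] <- tibble(
      pair_id = d$name, category = d$category,
      parallel_bare = fr_bare[1], hybrid_bare = fr_bare[2],
      antiparallel_bare = fr_bare[3],
      parallel_flanked = fr_flank[1], hybrid_flanked = fr_flank[2],
      antiparallel_flanked = fr_flank[3],
      delta_parallel = fr_flank[1] - fr_bare[1]
    )
  }
  manifest <- dplyr::bind_rows(rows)
  truth <- dplyr::bind_rows(truth)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- vapply(manifest$sample_id, function(id) {
      f <- file.path(dir, paste0(id, ".csv"))
      readr::write_csv(as_tibble(spectra[[id]])[, c("wavelength", "signal")], f)
      f
    }, "")
    manifest$spectrum_file <- unname(files)
    readr::write_csv(manifest, file.path(dir, "manifest.csv"))
    readr::write_csv(truth, file.path(dir, "truth.csv"))
  }
  list(manifest = manifest, spectra = spectra, truth = truth)
}

jitter_simplex <- function(fractions, sd) {
  if (sd <= 0) return(fractions)
  f <- pmax(fractions + rnorm(3L, 0, sd), 0)
  if (sum(f) == 0) f <- c(1, 1, 1)
  f / sum(f)
}

#' Random library of bare designs for simulations
#'
#' Samples loop triples uniformly from the model-library constraint set
#' (each loop 1-6 nt, total loop length 7-13 nt) without replacement when
#' possible.
#'
#' @param n Number of designs.
#' @param seed Integer seed.
#' @return A tibble in the [enumerate_group()] layout.
#' @export
sample_design_table <- function(n, seed = 1L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  all_triples <- expand.grid(a = 1:6, b = 1:6, c = 1:6,
                             KEEP.OUT.ATTRS = FALSE)
  tot <- all_triples$a + all_triples$b + all_triples$c
  all_triples <- all_triples[tot >= 7 & tot <= 13, ]
  idx <- if (n <= nrow(all_triples)) sample(nrow(all_triples), n)
         else sample(nrow(all_triples), n, replace = TRUE)
  picked <- all_triples[idx, ]
  tibble(
    name = paste0(picked$a, picked$b, picked$c),
    a = as.integer(picked$a), b = as.integer(picked$b),
    c = as.integer(picked$c),
    flank5 = "", flank3 = "",
    sequence = vapply(seq_len(nrow(picked)), function(i) {
      g4_sequence(g4_design(c(picked$a[i], picked$b[i], picked$c[i])))
    }, ""),
    category = shortest_loop_category(picked$a, picked$b, picked$c)
  )
}
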