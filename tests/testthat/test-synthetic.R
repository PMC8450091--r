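test_that("pure basis spectra classify into their own topology class", {
  m <- cd_basis_model()
  expect_gte(conformation_index(basis_spectrum("parallel", m))$r, 0.9)
  expect_lt(conformation_index(basis_spectrum("antiparallel", m))$r, 0)
  rh <- conformation_index(basis_spectrum("hybrid", m))$r
  expect_gte(rh, 0)
  expect_lt(rh, 0.5)
  expect_error(basis_spectrum("z-dna", m), "unknown topology")
})

test_that("the basis constructor rejects misclassifying band sets", {
  bad <- list(
    parallel = data.frame(center = 290, width = 10, amplitude = 1),  # not 265
    antiparallel = data.frame(center = 292, width = 10, amplitude = 0.7),
    hybrid = data.frame(center = 290, width = 10, amplitude = 0.65)
  )
  expect_error(cd_basis_model(bad), "parallel basis")
})

test_that("mixtures are convex combinations of the bases", {
  m <- cd_basis_model()
  pure <- mix_spectra(c(1, 0, 0), m)
  expect_equal(pure$signal, basis_spectrum("parallel", m)$signal)

  half <- mix_spectra(c(0.5, 0, 0.5), m)
  expect_equal(half$signal,
               (basis_spectrum("parallel", m)$signal +
                  basis_spectrum("antiparallel", m)$signal) / 2)

  expect_error(mix_spectra(c(0.5, 0.2, 0.2), m), "simplex|summing")
  expect_error(mix_spectra(c(1.2, -0.2, 0), m), "simplex|summing|non-negative")
})

test_that("r increases monotonically along the parallel-antiparallel edge", {
  m <- cd_basis_model()
  f <- seq(0, 1, by = 0.02)
  rs <- vapply(f, function(p) {
    conformation_index(mix_spectra(c(p, 0, 1 - p), m))$r
  }, 0)
  expect_true(all(diff(rs) > 0))
})

test_that("mixture r lies between the r values of its components", {
  m <- cd_basis_model()
  set.seed(37)
  for (i in 1:15) {
    f1 <- rexp(3); f1 <- f1 / sum(f1)
    f2 <- rexp(3); f2 <- f2 / sum(f2)
    lam <- runif(1)
    rm1 <- conformation_index(mix_spectra(f1, m))$r
    rm2 <- conformation_index(mix_spectra(f2, m))$r
    rmix <- conformation_index(mix_spectra(lam * f1 + (1 - lam) * f2, m))$r
    expect_gte(rmix, min(rm1, rm2) - 1e-9)
    expect_lte(rmix, max(rm1, rm2) + 1e-9)
  }
})

test_that("generator outputs are bitwise reproducible under a seed", {
  m <- cd_basis_model()
  s1 <- mix_spectra(c(0.3, 0.4, 0.3), m, noise_sd = 0.05, seed = 11)
  s2 <- mix_spectra(c(0.3, 0.4, 0.3), m, noise_sd = 0.05, seed = 11)
  expect_identical(s1$signal, s2$signal)

  c1 <- synth_melting(55, -40, noise_sd = 0.002, seed = 11)
  c2 <- synth_melting(55, -40, noise_sd = 0.002, seed = 11)
  expect_identical(c1$absorbance, c2$absorbance)

  des <- sample_design_table(12, seed = 5)
  e1 <- synth_experiment(des, seed = 5)
  e2 <- synth_experiment(des, seed = 5)
  expect_identical(e1$truth, e2$truth)
  expect_identical(e1$spectra[[1]]$signal, e2$spectra[[1]]$signal)
})

test_that("the two-state model melts halfway exactly at Tm", {
  grid <- c(30, 40, 55, 60, 70)
  cv <- synth_melting(55, -40, grid = grid, noise_sd = 0,
                      baseline_folded = c(1, 0), baseline_unfolded = c(0, 0))
  # with baselines 1 and 0 the absorbance IS the folded fraction
  expect_equal(cv$absorbance[grid == 55], 0.5)
  expect_error(synth_melting(55, -40, grid = c(40, 50, 60)), ">= 5")
  expect_error(synth_melting(55, 40), "negative")
  expect_error(synth_melting(10, -40, grid = seq(20, 90, 5)), "within")
})

test_that("steeper enthalpy narrows the derivative peak", {
  fwhm <- function(dh) {
    cv <- synth_melting(55, dh, grid = seq(20, 90, 0.1), noise_sd = 0,
                        baseline_folded = c(1, 0), baseline_unfolded = c(0, 0))
    d <- abs(diff(cv$absorbance) / diff(cv$temperature))
    mid <- (cv$temperature[-1] + cv$temperature[-nrow(cv)]) / 2
    above <- mid[d >= max(d) / 2]
    max(above) - min(above)
  }
  expect_lt(fwhm(-60), fwhm(-30))
})

test_that("the flank shift follows its closed form and stays on the simplex", {
  eff <- flanking_effect_model(shift5 = 0.3, shift3 = 0.05,
                               sensitivity = c(none = 1))
  hybrid_baseline <- c(0.2, 0.6, 0.2)
  # saturation(2) = 3/4: 5' shift moves 0.3 * 3/4 = 0.225 into parallel
  shifted5 <- apply_flank_shift(hybrid_baseline, L5 = 2, L3 = 0, eff)
  expect_equal(shifted5[1] - hybrid_baseline[1], 0.3 * 0.75)
  shifted3 <- apply_flank_shift(hybrid_baseline, L5 = 0, L3 = 2, eff)
  expect_equal(shifted3[1] - hybrid_baseline[1], 0.05 * 0.75)

  set.seed(41)
  for (i in 1:20) {
    f <- rexp(3); f <- f / sum(f)
    out <- apply_flank_shift(f, sample(0:5, 1), sample(0:5, 1), eff)
    expect_true(all(out >= -1e-12))
    expect_equal(sum(out), 1, tolerance = 1e-12)
  }
  # the first nucleotide carries half of the maximal effect
  s1 <- apply_flank_shift(c(0, 1, 0), L5 = 1, L3 = 0, eff)[1]
  expect_equal(s1, 0.3 * 0.5)
})

test_that("the effect model enforces the 5' over 3' asymmetry", {
  expect_error(flanking_effect_model(shift5 = 0.1, shift3 = 0.2), "shift5")
  expect_error(flanking_effect_model(baselines = list(
    `1bc` = c(0.5, 0.6, -0.1), a1c = c(1, 0, 0), ab1 = c(1, 0, 0),
    none = c(1, 0, 0))), "simplex")
})

test_that("zero-shift experiments centre delta-r at zero", {
  des <- sample_design_table(40, seed = 3)
  eff <- flanking_effect_model(shift5 = 0, shift3 = 0, noise_sd = 0.02)
  ex <- synth_experiment(des, eff, seed = 3)
  expect_true(all(abs(ex$truth$delta_parallel) < 1e-12))
  cls <- run_classify(ex$manifest, spectra = ex$spectra)
  st <- run_stats(cls)
  expect_lt(abs(mean(st$pairs$delta_r)), 0.05)
})

test_that("experiments write pipeline-readable files with a truth table", {
  dir <- withr::local_tempdir()
  des <- sample_design_table(6, seed = 2)
  ex <- synth_experiment(des, seed = 2, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m), 12L)
  cls <- run_classify(m)
  expect_equal(nrow(cls), 12L)
  # file-based and in-memory routes agree
  cls_mem <- run_classify(ex$manifest, spectra = ex$spectra)
  expect_equal(cls$r, cls_mem$r, tolerance = 1e-9)
  # flanked members must not be supplied as "bare" designs
  expect_error(synth_experiment(enumerate_group(c(1, 3, 6), "DT2"), seed = 1),
               "bare")
})

test_that("recovered category ordering matches the planted model", {
  des <- sample_design_table(90, seed = 17)
  ex <- synth_experiment(des, flanking_effect_model(), seed = 17)
  cls <- run_classify(ex$manifest, spectra = ex$spectra)
  st <- run_stats(cls)
  est <- st$pairs |>
    dplyr::filter(category %in% c("1bc", "a1c", "ab1")) |>
    dplyr::group_by(category) |>
    dplyr::summarise(dr = mean(delta_r))

  # planted ordering: noiseless r computed from the true fraction triples
  m <- cd_basis_model()
  r_of <- function(f) conformation_index(mix_spectra(f, m))$r
  truth <- ex$truth |>
    dplyr::filter(category %in% c("1bc", "a1c", "ab1")) |>
    dplyr::rowwise() |>
    dplyr::mutate(dr_true = r_of(c(parallel_flanked, hybrid_flanked,
                                   antiparallel_flanked)) -
                    r_of(c(parallel_bare, hybrid_bare, antiparallel_bare))) |>
    dplyr::ungroup() |>
    dplyr::group_by(category) |>
    dplyr::summarise(dr = mean(dr_true))

  expect_equal(est$category[order(est$dr)], truth$category[order(truth$dr)])
})
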