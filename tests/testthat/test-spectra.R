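write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("two-column spectrum files read, sort and average duplicates", {
  p <- write_lines_tmp(c("wavelength,cd", "290,4.0", "240,-3.1", "265,10.2"))
  sp <- read_cd_spectrum(p, sample_id = "s1")
  expect_equal(sp$wavelength, c(240, 265, 290))
  expect_equal(sp$signal, c(-3.1, 10.2, 4.0))

  # tab and semicolon delimiters, no header
  pt <- write_lines_tmp(c("240\t1", "250\t2"))
  expect_equal(read_cd_spectrum(pt)$signal, c(1, 2))
  ps <- write_lines_tmp(c("240;1", "250;2"))
  expect_equal(read_cd_spectrum(ps)$signal, c(1, 2))

  # duplicate wavelengths averaged
  pd <- write_lines_tmp(c("240,1", "240,3", "250,2"))
  expect_equal(read_cd_spectrum(pd)$signal, c(2, 2))
})

test_that("defective spectrum files are rejected with the line named", {
  expect_error(read_cd_spectrum(write_lines_tmp("wavelength,cd")), "header only")
  expect_error(read_cd_spectrum(write_lines_tmp(c("240,1"))), "fewer than 2")
  expect_error(read_cd_spectrum(write_lines_tmp(c("240,1", "oops,2", "250,3"))),
               "line 2")
  expect_error(read_cd_spectrum(write_lines_tmp(c("240,1", "250,Inf"))),
               "non-finite")
  expect_error(read_cd_spectrum(tempfile()), "not found")
})

test_that("interpolation matches a brute-force oracle on random grids", {
  set.seed(21)
  for (i in 1:40) {
    sp <- random_spectrum()
    for (q in runif(5, min(sp$wavelength), max(sp$wavelength))) {
      expect_equal(spectrum_value_at(sp, q),
                   oracle_interp(sp$wavelength, sp$signal, q),
                   tolerance = 1e-12)
    }
    # exact grid hits return stored values
    j <- sample(nrow(sp), 1)
    expect_equal(spectrum_value_at(sp, sp$wavelength[j]), sp$signal[j])
  }
})

test_that("interpolation margin handles near and far out-of-range queries", {
  sp <- cd_spectrum(c(260, 270), c(0, 10))
  expect_equal(spectrum_value_at(sp, 265), 5)
  expect_equal(spectrum_value_at(sp, 271.5, margin = 2), 10)  # endpoint value
  expect_error(spectrum_value_at(sp, 290, margin = 2), "outside")
})

test_that("conformation index reproduces the defining ratio and flags", {
  mk <- function(cd265, cd290) {
    cd_spectrum(c(240, 265, 290), c(0, cd265, cd290))
  }
  res <- conformation_index(mk(10, 10))
  expect_equal(res$r, 0.5)
  expect_equal(res$label, "parallel")

  res <- conformation_index(mk(-5, 10))
  expect_equal(res$r, -1 / 3)
  expect_equal(res$label, "antiparallel")

  res <- conformation_index(mk(8, 0))
  expect_equal(res$r, 1.0)
  expect_equal(res$label, "parallel")

  # negative 290 band: computed as-is, flagged
  res <- conformation_index(mk(6, -2))
  expect_equal(res$r, 6 / 4)
  expect_match(res$flags, "negative-290")
  expect_match(res$flags, "out-of-range-r")

  # cancelling denominator: undefined with flag
  res <- conformation_index(mk(5, -5))
  expect_true(is.na(res$r))
  expect_equal(res$label, "undefined")
  expect_match(res$flags, "small-denominator")
})

test_that("classification thresholds are closed as printed", {
  expect_equal(classify_r(0.60), "parallel")
  expect_equal(classify_r(0.27), "hybrid")
  expect_equal(classify_r(-0.13), "antiparallel")
  expect_equal(classify_r(0.5), "parallel")
  expect_equal(classify_r(0), "hybrid")
  expect_equal(classify_r(-1e-12), "antiparallel")
  expect_equal(classify_r(NA_real_), "undefined")
})

test_that("every finite r maps to exactly one label", {
  set.seed(3)
  r <- c(runif(500, -2, 2), 0, 0.5, -0.5, 1, -1)
  lab <- classify_r(r)
  expect_true(all(lab %in% c("parallel", "hybrid", "antiparallel")))
  counts <- (lab == "parallel") + (lab == "hybrid") + (lab == "antiparallel")
  expect_true(all(counts == 1))
})

test_that("r is invariant to positive rescaling of the spectrum", {
  set.seed(5)
  for (i in 1:50) {
    sp <- random_spectrum()
    base <- conformation_index(sp)
    k <- exp(runif(1, -4, 4))
    scaled <- cd_spectrum(sp$wavelength, k * sp$signal)
    res <- conformation_index(scaled)
    if (is.na(base$r)) {
      expect_true(is.na(res$r))
    } else {
      expect_equal(res$r, base$r, tolerance = 1e-9)
      expect_equal(res$label, base$label)
    }
  }
})

test_that("difference spectra are antisymmetric and normalizable", {
  set.seed(9)
  a <- random_spectrum()
  b <- random_spectrum()
  ab <- difference_spectrum(a, b)
  ba <- difference_spectrum(b, a)
  expect_equal(ab$signal, -ba$signal)

  self <- difference_spectrum(a, a)
  expect_true(all(abs(self$signal) < 1e-12))

  nd <- difference_spectrum(a, b, normalize = TRUE)
  expect_equal(max(abs(nd$signal)), 1)

  lo <- cd_spectrum(c(200, 210), c(1, 2))
  hi <- cd_spectrum(c(300, 310), c(1, 2))
  expect_error(difference_spectrum(lo, hi), "overlap")
})
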