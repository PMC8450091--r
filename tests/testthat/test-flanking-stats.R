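test_that("delta-r is the signed difference and excludes undefined pairs", {
  expect_equal(pair_delta_r(0.60, -0.16), 0.76)
  expect_equal(pair_delta_r(0.3, 0.3), 0)
  expect_equal(pair_delta_r(0.2, 0.5), -pair_delta_r(0.5, 0.2))
  expect_true(is.na(pair_delta_r(NA_real_, 0.4)))
  expect_true(is.na(pair_delta_r(0.4, NaN)))
})

test_that("group spread uses the population divisor and matches the oracle", {
  expect_equal(group_sigma(c(0.5, 0.5, 0.5)), 0)
  expect_equal(group_sigma(c(0, 1)), 0.5)
  expect_error(group_sigma(numeric(0)), "non-empty")

  set.seed(13)
  for (i in 1:30) {
    v <- rnorm(sample(1:20, 1), sd = runif(1, 0.1, 10))
    expect_equal(group_sigma(v), oracle_sigma(v), tolerance = 1e-12)
  }
  # population divisor, not the n-1 sample one
  v <- c(1, 2, 3, 4)
  expect_equal(group_sigma(v), sqrt(mean((v - mean(v))^2)))
  expect_false(isTRUE(all.equal(group_sigma(v), sd(v))))
})

test_that("proportion tables give percentages to one decimal, summing to 100", {
  pt <- proportion_table(c("parallel", "parallel", "hybrid", "antiparallel"))
  expect_equal(pt$percent, c(50.0, 25.0, 25.0))
  expect_equal(sum(pt$proportion), 1)

  pt <- proportion_table(rep("parallel", 7))
  expect_equal(pt$percent, c(100, 0, 0))

  set.seed(17)
  for (i in 1:20) {
    labs <- sample(c("parallel", "hybrid", "antiparallel", "undefined"),
                   sample(3:50, 1), replace = TRUE)
    if (all(labs == "undefined")) next
    pt <- proportion_table(labs)
    expect_lt(abs(sum(pt$percent) - 100), 0.11)
    expect_equal(attr(pt, "n_undefined"), sum(labs == "undefined"))
  }
  expect_error(proportion_table(character(0)), "no classifications")
})

test_that("positive fractions count strict positives only", {
  pf <- positive_fraction(c(rep(1, 74), rep(-0.2, 17)))
  expect_equal(pf$percent, 81.3)
  expect_equal(pf$n, 91L)
  expect_equal(positive_fraction(c(2, 3))$percent, 100)
  expect_equal(positive_fraction(c(0, 0))$percent, 0)
  expect_error(positive_fraction(numeric(0)), "no differences")
  # positives and non-positives partition the count exactly
  set.seed(19)
  d <- rnorm(57)
  pf <- positive_fraction(d)
  expect_equal(pf$n_positive + sum(d <= 0), pf$n)
})

test_that("paired t-test agrees with a numerical t-density oracle", {
  set.seed(23)
  a <- rnorm(20) + 1
  b <- rnorm(20)
  res <- paired_t_test(a, b)
  orc <- oracle_paired_p(a, b)
  expect_equal(res$statistic, orc$statistic, tolerance = 1e-10)
  expect_equal(res$p_value, orc$p_value, tolerance = 1e-6)
  expect_equal(res$df, 19L)

  for (i in 1:10) {
    n <- sample(3:30, 1)
    a <- rnorm(n, sd = 2)
    b <- rnorm(n, mean = runif(1, -1, 1))
    res <- paired_t_test(a, b)
    orc <- oracle_paired_p(a, b)
    expect_equal(res$p_value, orc$p_value, tolerance = 1e-6)
  }
})

test_that("paired t-test is antisymmetric and handles degenerate inputs", {
  set.seed(29)
  a <- rnorm(12)
  b <- rnorm(12)
  f <- paired_t_test(a, b)
  r <- paired_t_test(b, a)
  expect_equal(f$statistic, -r$statistic)
  expect_equal(f$p_value, r$p_value)

  same <- paired_t_test(a, a)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, "ns")

  shifted <- paired_t_test(a + 1, a)
  expect_true(shifted$degenerate)
  expect_equal(shifted$p_value, 0)
  expect_equal(shifted$stars, "***")
})

test_that("star annotations follow the printed convention", {
  base <- c(0, 1, 0.5, 1.2, 0.8)
  # d = base+10 - base is constant-free: differences all 10 with tiny spread
  strong <- paired_t_test(base + 10 + c(0.01, -0.01, 0.02, -0.02, 0), base)
  expect_lt(strong$p_value, 0.001)
  expect_equal(strong$stars, "***")

  # differences (1, 1, 1, 1, -1): t = 1.5 on 4 df, p ~ 0.21
  weak <- paired_t_test(base + c(1, 1, 1, 1, -1), base)
  expect_gt(weak$p_value, 0.05)
  expect_equal(weak$stars, "ns")
})

test_that("classification matrices are long, label-consistent and traceable", {
  pairs <- tibble::tibble(
    pair_id = c("136", "244", "442"),
    r_bare = c(-0.16, 0.2, 0.55),
    r_flanked = c(0.60, 0.65, 0.7)
  )
  m <- classification_matrix(pairs, cation = "K")
  expect_equal(nrow(m), 6L)
  expect_equal(m$label, classify_r(m$r))
  expect_setequal(unique(m$cation), "K")
  expect_setequal(m$sequence, pairs$pair_id)

  empty <- classification_matrix(pairs[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("group_report summarises by group with population spread", {
  df <- tibble::tibble(
    grp = rep(c("136", "244"), c(6, 3)),
    r = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.9, 0.9, 0.9)
  )
  rep <- group_report(df, r, grp)
  expect_equal(rep$n, c(6L, 3L))
  expect_equal(rep$sigma[2], 0)
  expect_equal(rep$sigma[1], oracle_sigma(df$r[1:6]))
})
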