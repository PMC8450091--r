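# Independent oracles used across the suite. They deliberately avoid the
# package's own code paths (and the corresponding base shortcuts) so that
# implementation and check stay on separate routes.

# brute-force bracketing linear interpolation
oracle_interp <- function(x, y, q) {
  if (q <= x[1]) return(y[1])
  if (q >= x[length(x)]) return(y[length(x)])
  j <- max(which(x <= q))
  if (x[j] == q) return(y[j])
  y[j] + (y[j + 1] - y[j]) * (q - x[j]) / (x[j + 1] - x[j])
}

# two-pass population spread by direct summation
oracle_sigma <- function(v) {
  mu <- sum(v) / length(v)
  acc <- 0
  for (x in v) acc <- acc + (x - mu)^2
  sqrt(acc / length(v))
}

# two-sided paired-t p-value via numerical integration of the t density
oracle_paired_p <- function(a, b) {
  d <- a - b
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  tstat <- m / (s / sqrt(n))
  df <- n - 1
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  tail <- stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-10)$value
  list(statistic = tstat, p_value = 2 * tail)
}

# distinct orderings of a length-3 multiset by explicit permutation dedup
oracle_n_orderings <- function(loops) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  nrow(unique(do.call(rbind, lapply(perms, function(p) loops[p]))))
}

random_spectrum <- function(n = 30, lo = 230, hi = 310) {
  wl <- sort(runif(n, lo, hi))
  wl <- wl[c(TRUE, diff(wl) > 1e-6)]
  while (length(wl) < 5) wl <- sort(runif(n, lo, hi))
  cd_spectrum(c(lo, wl, hi), rnorm(length(wl) + 2, 0, 5))
}
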