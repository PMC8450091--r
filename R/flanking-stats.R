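#' Pairwise change in the conformation index
#'
#' Delta-r = r(flanked) - r(bare); positive values indicate parallelization
#' of the topology ensemble by the flanking nucleotides.
#'
#' @param r_flanked,r_bare Conformation index values (vectorised). Pairs with
#'   a non-finite member yield `NA` (excluded upstream with a logged reason).
#' @return Numeric delta-r values.
#' @examples
#' pair_delta_r(0.60, -0.16)
#' @export
pair_delta_r <- function(r_flanked, r_bare) {
  out <- r_flanked - r_bare
  out[!is.finite(r_flanked) | !is.finite(r_bare)] <- NA_real_
  out
}

#' Population spread of a group
#'
#' sigma = sqrt(sum((x_i - mu)^2) / N), the population formula with divisor N
#' (not N - 1). Used for the within-group spread of r or Tm values of a
#' loop-permutation group, where the group is the whole population of
#' interest, not a sample from one.
#'
#' @param values Numeric vector, n >= 1, no missing values.
#' @return Non-negative scalar; 0 iff all members are equal.
#' @examples
#' group_sigma(c(0, 1))
#' @export
group_sigma <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) {
    abort("`values` must be a non-empty numeric vector without NA.")
  }
  mu <- mean(values)
  sqrt(sum((values - mu)^2) / length(values))
}

#' Per-group summary of r or Tm values
#'
#' @param data A data frame with one row per sequence.
#' @param value Column (tidy-select) holding the value to summarise.
#' @param group Column identifying the loop-permutation group.
#' @return A tibble with `group_id`, `n`, `mean` and `sigma` (population
#'   spread, [group_sigma()]).
#' @export
group_report <- function(data, value, group) {
  data |>
    dplyr::group_by(group_id = {{ group }}) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean({{ value }}),
      sigma = group_sigma({{ value }}),
      .groups = "drop"
    )
}

#' Topology proportion table
#'
#' Fractions of parallel, hybrid and antiparallel classifications among a set
#' of results. Undefined labels are excluded from the denominator and
#' reported via the `n_undefined` attribute.
#'
#' @param labels Character vector of labels from [classify_r()], or a data
#'   frame with a `label` column.
#' @return A tibble with `label`, `n`, `proportion` and `percent` (the
#'   percentage rounded to 1 decimal); proportions sum to 1.
#' @examples
#' proportion_table(c("parallel", "parallel", "hybrid", "antiparallel"))
#' @export
proportion_table <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  if (length(labels) == 0L) abort("no classifications supplied.")
  n_undef <- sum(labels == "undefined" | is.na(labels))
  labels <- labels[labels != "undefined" & !is.na(labels)]
  if (length(labels) == 0L) abort("all classifications are undefined.")
  lv <- c("parallel", "hybrid", "antiparallel")
  counts <- vapply(lv, function(l) sum(labels == l), 0L)
  counts <- unname(counts)
  out <- tibble(
    label = lv, n = as.integer(counts),
    proportion = counts / sum(counts),
    percent = round(100 * counts / sum(counts), 1)
  )
  attr(out, "n_undefined") <- n_undef
  out
}

#' Fraction of positive differences
#'
#' Counts strictly positive values (zeros are non-positive) and reports the
#' percentage to 1 decimal, the convention used for positive-delta-r
#' fractions.
#'
#' @param deltas Numeric vector, n >= 1; `NA` values are dropped.
#' @return A one-row tibble: `n_positive`, `n`, `fraction`, `percent`.
#' @examples
#' positive_fraction(c(rep(1, 74), rep(-1, 17)))  # 74 of 91 -> 81.3%
#' @export
positive_fraction <- function(deltas) {
  deltas <- deltas[!is.na(deltas)]
  if (length(deltas) == 0L) abort("no differences supplied.")
  np <- sum(deltas > 0)
  tibble(n_positive = as.integer(np), n = length(deltas),
         fraction = np / length(deltas),
         percent = round(100 * np / length(deltas), 1))
}

#' Paired two-sided t-test of flanked vs bare values
#'
#' Standard paired t statistic t = mean(d) / (sd(d) / sqrt(n)) with the
#' sample standard deviation (divisor n - 1) and a two-sided p-value from the
#' t distribution with n - 1 degrees of freedom. When the differences have
#' zero variance the statistic is undefined; the result is flagged degenerate
#' with p = 1 if the common difference is 0 and p = 0 otherwise.
#'
#' Significance stars follow the figure convention: `***` p < 0.001, `**`
#' p < 0.01, `*` p <= 0.05, `ns` p > 0.05.
#'
#' @param values_flanked,values_bare Equal-length numeric vectors paired by
#'   position (pair_id order), n >= 2.
#' @return An object of class `g4_test` with fields `statistic`, `p_value`,
#'   `n`, `df`, `mean_difference`, `stars`, `degenerate`, `method`. [tidy()]
#'   returns it as a one-row tibble.
#' @examples
#' paired_t_test(c(0.6, 0.8, 0.7), c(0.1, 0.3, 0.2))
#' @export
paired_t_test <- function(values_flanked, values_bare) {
  if (length(values_flanked) != length(values_bare)) {
    abort("paired vectors must have equal length.")
  }
  n <- length(values_flanked)
  if (n < 2L) abort("paired t-test needs n >= 2.")
  d <- values_flanked - values_bare
  if (anyNA(d)) abort("paired values must not contain NA.")
  degenerate <- sd(d) == 0
  if (degenerate) {
    statistic <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    ht <- t.test(values_flanked, values_bare, paired = TRUE,
                 alternative = "two.sided")
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(
    list(statistic = statistic, p_value = p, n = n, df = n - 1L,
         mean_difference = mean(d), stars = p_stars(p),
         degenerate = degenerate, method = "paired two-sided t-test"),
    class = "g4_test"
  )
}

p_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p <= 0.05) "*" else "ns"
}

#' @export
print.g4_test <- function(x, ...) {
  cat("<g4_test> ", x$method, "\n", sep = "")
  cat(sprintf("  t = %.4g, df = %d, p = %.3g %s%s\n", x$statistic, x$df,
              x$p_value, x$stars, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' @rdname paired_t_test
#' @param x A `g4_test`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.g4_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p_value = x$p_value,
         n = x$n, df = x$df, mean_difference = x$mean_difference,
         stars = x$stars, degenerate = x$degenerate)
}

#' @rdname paired_t_test
#' @exportS3Method generics::glance
glance.g4_test <- function(x, ...) tidy(x, ...)

#' Heat-map-ready classification matrix
#'
#' Pivots a pair table into long format (sequence, condition, r, label), one
#' row per cell of the topology heat map comparing bare and flanked
#' conditions under one cation.
#'
#' @param pairs A data frame with columns `pair_id`, `r_bare`, `r_flanked`
#'   and optionally `condition_bare` / `condition_flanked` labels (defaults
#'   "WO" and "W").
#' @param cation Optional cation tag copied onto every row.
#' @return A tibble with columns `sequence`, `condition`, `r`, `label` and
#'   (if given) `cation`; empty input yields an empty tibble.
#' @export
classification_matrix <- function(pairs, cation = NULL) {
  if (nrow(pairs) == 0L) {
    out <- tibble(sequence = character(), condition = character(),
                  r = numeric(), label = character())
    if (!is.null(cation)) out$cation <- character()
    return(out)
  }
  cb <- if ("condition_bare" %in% names(pairs)) pairs$condition_bare else "WO"
  cf <- if ("condition_flanked" %in% names(pairs)) pairs$condition_flanked else "W"
  out <- tibble(
    sequence = rep(pairs$pair_id, 2L),
    condition = c(rep_len(cb, nrow(pairs)), rep_len(cf, nrow(pairs))),
    r = c(pairs$r_bare, pairs$r_flanked)
  )
  out$label <- classify_r(out$r)
  if (!is.null(cation)) out$cation <- cation
  out
}

#' Plot the topology heat map
#'
#' Tiles sequences by condition, filled by topology class with the
#' conventional colours (parallel red, hybrid khaki, antiparallel blue).
#'
#' @param matrix_long Output of [classification_matrix()].
#' @return A ggplot.
#' @export
plot_classification_heatmap <- function(matrix_long) {
  ggplot2::ggplot(matrix_long,
                  ggplot2::aes(.data$condition, .data$sequence,
                               fill = .data$label)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(
      parallel = "firebrick", hybrid = "khaki3",
      antiparallel = "steelblue", undefined = "grey70")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Topology")
}

#' Plot delta-r per pair
#'
#' @param pairs A data frame with `pair_id` and `delta_r` columns.
#' @return A ggplot bar chart of delta-r, coloured by sign.
#' @export
plot_delta_r <- function(pairs) {
  ggplot2::ggplot(pairs,
                  ggplot2::aes(.data$pair_id, .data$delta_r,
                               fill = .data$delta_r > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "steelblue")) +
    ggplot2::labs(x = NULL, y = expression(Delta * r)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
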