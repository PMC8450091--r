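#' Read and validate a sample manifest
#'
#' The manifest links sample files to designs and conditions; the expected
#' columns are `sample_id`, `name_or_sequence` (a parsable library name or an
#' explicit sequence), `flank5`, `flank3`, `cation` (K/Na), `spectrum_file`,
#' `melting_file`, `pair_id` (links bare/flanked variants), `group_id`, and
#' `condition` (bare/flanked). Missing optional columns are filled with NA.
#'
#' @param path CSV manifest path.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(m)) abort("manifest must have a sample_id column.")
  optional <- c("name_or_sequence", "flank5", "flank3", "cation",
                "spectrum_file", "melting_file", "pair_id", "group_id",
                "condition")
  for (col in optional) if (!col %in% names(m)) m[[col]] <- NA_character_
  if (anyDuplicated(m$sample_id)) abort("manifest sample_id values must be unique.")
  m
}

#' Design a library and write FASTA plus a manifest skeleton
#'
#' Enumerates every requested loop-permutation group under every flank
#' scheme and (optionally) writes the rendered library as FASTA together
#' with a manifest skeleton whose file columns are left empty for the
#' experimenter to fill in.
#'
#' @param group_specs A list of loop multisets (each three positive
#'   integers), e.g. `list(c(1, 3, 6), c(2, 4, 4))`.
#' @param flank_schemes Character vector of schemes (see
#'   [enumerate_group()]), default `c("WO", "DT2")`.
#' @param dir Optional output directory for `library.fasta` and
#'   `manifest_skeleton.csv`.
#' @return A tibble of all designs with a `scheme` column.
#' @examples
#' run_design(list(c(1, 3, 6)), c("WO", "DT2"))
#' @export
run_design <- function(group_specs, flank_schemes = c("WO", "DT2"),
                       dir = NULL) {
  if (length(group_specs) == 0L) abort("no group specifications supplied.")
  designs <- purrr::map_dfr(group_specs, function(loops) {
    purrr::map_dfr(flank_schemes, function(sch) {
      out <- enumerate_group(loops, sch)
      out$scheme <- sch
      out$group_id <- paste(sort(as.integer(loops)), collapse = "")
      out
    })
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_design_fasta(designs, file.path(dir, "library.fasta"))
    skeleton <- tibble(
      sample_id = designs$name,
      name_or_sequence = designs$name,
      flank5 = designs$flank5, flank3 = designs$flank3,
      cation = "K", spectrum_file = "", melting_file = "",
      pair_id = paste0(designs$a, designs$b, designs$c),
      group_id = designs$group_id,
      condition = ifelse(designs$scheme == "WO", "bare", "flanked")
    )
    readr::write_csv(skeleton, file.path(dir, "manifest_skeleton.csv"))
  }
  designs
}

#' Classify every spectrum in a manifest
#'
#' Reads each sample's spectrum (from `spectrum_file`, or from an in-memory
#' `spectrum` list-column as produced by [synth_experiment()]) and computes
#' its conformation index. Per-row failures (missing or unreadable files) do
#' not stop the batch: the failing rows are reported in the `failures`
#' attribute and a warning.
#'
#' @param manifest Manifest tibble ([read_manifest()]), or the `manifest`
#'   element of [synth_experiment()] together with its `spectra`.
#' @param spectra Optional named list of [cd_spectrum()] keyed by sample_id,
#'   used instead of files.
#' @param eps_rel,margin Passed to [conformation_index()].
#' @return A tibble with one row per classified sample: manifest keys plus
#'   `r`, `cd265`, `cd290`, `label`, `flags`. Attribute `failures` is a
#'   tibble (sample_id, reason), empty on full success.
#' @export
run_classify <- function(manifest, spectra = NULL, eps_rel = 1e-6,
                         margin = 2) {
  if (nrow(manifest) == 0L) abort("empty manifest.")
  results <- list()
  failures <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      sp <- if (!is.null(spectra) && row$sample_id %in% names(spectra)) {
        spectra[[row$sample_id]]
      } else if (!is.null(manifest[["spectrum"]]) &&
                 !is.null(manifest[["spectrum"]][[i]])) {
        manifest[["spectrum"]][[i]]
      } else {
        read_cd_spectrum(row$spectrum_file, sample_id = row$sample_id,
                         cation = row$cation %||% NA_character_)
      }
      ci <- conformation_index(sp, eps_rel = eps_rel, margin = margin)
      ci$sample_id <- row$sample_id
      ci
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        tibble(sample_id = row$sample_id, reason = conditionMessage(res))
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  if (length(results) == 0L) abort("no spectrum in the manifest could be classified.")
  out <- dplyr::bind_rows(results)
  keep <- intersect(c("sample_id", "pair_id", "group_id", "condition",
                      "category", "cation", "scheme"), names(manifest))
  out <- dplyr::left_join(out, manifest[, keep, drop = FALSE], by = "sample_id")
  fail_tbl <- if (length(failures)) dplyr::bind_rows(failures) else
    tibble(sample_id = character(), reason = character())
  if (nrow(fail_tbl)) {
    warn(paste0(nrow(fail_tbl), " sample(s) failed to classify; see attr(, 'failures')."))
  }
  attr(out, "failures") <- fail_tbl
  out
}

#' Extract Tm for every melting curve in a manifest
#'
#' @inheritParams run_classify
#' @param curves Optional named list of [melting_curve()] keyed by sample_id.
#' @param smooth_window Passed to [compute_tm()].
#' @return A tibble (sample_id, tm, direction, flags) plus manifest keys;
#'   failures in the `failures` attribute as in [run_classify()].
#' @export
run_melt <- function(manifest, curves = NULL, smooth_window = 5L) {
  if (nrow(manifest) == 0L) abort("empty manifest.")
  results <- list()
  failures <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      cv <- if (!is.null(curves) && row$sample_id %in% names(curves)) {
        curves[[row$sample_id]]
      } else {
        read_melting_curve(row$melting_file, sample_id = row$sample_id)
      }
      fit <- compute_tm(cv, smooth_window = smooth_window)
      td <- tidy(fit)
      td$sample_id <- row$sample_id
      td
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        tibble(sample_id = row$sample_id, reason = conditionMessage(res))
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  if (length(results) == 0L) abort("no melting curve could be processed.")
  out <- dplyr::bind_rows(results)
  keep <- intersect(c("sample_id", "pair_id", "group_id", "condition",
                      "cation"), names(manifest))
  out <- dplyr::left_join(out, manifest[, keep, drop = FALSE], by = "sample_id")
  fail_tbl <- if (length(failures)) dplyr::bind_rows(failures) else
    tibble(sample_id = character(), reason = character())
  if (nrow(fail_tbl)) {
    warn(paste0(nrow(fail_tbl), " melting curve(s) failed; see attr(, 'failures')."))
  }
  attr(out, "failures") <- fail_tbl
  out
}

#' Flanking-effect statistics over a classified batch
#'
#' Builds the pair table (delta-r per pair_id), group reports (mean and
#' population spread of r per group and condition), topology proportion
#' tables for the bare and flanked conditions, the positive-delta-r
#' fraction, a paired t-test of flanked vs bare r, per-category breakdowns,
#' and optionally delta-Tm when melting results are supplied.
#'
#' @param classified Output of [run_classify()]; rows must carry `pair_id`
#'   and `condition` ("bare"/"flanked").
#' @param melting Optional output of [run_melt()] with the same pairing.
#' @param dir Optional directory; writes pairs.csv, groups.csv, tests.csv,
#'   proportions.csv and summary.json.
#' @return A list: `pairs`, `groups`, `proportions` (bare and flanked),
#'   `tests` (tidy tibble incl. per-category tests), `positive`,
#'   `summary` (JSON-ready list). Pairs with a missing or undefined member
#'   are excluded and counted in `summary$n_excluded_pairs`.
#' @export
run_stats <- function(classified, melting = NULL, dir = NULL) {
  need <- c("sample_id", "r", "label", "pair_id", "condition")
  if (!all(need %in% names(classified))) {
    abort("`classified` needs sample_id, r, label, pair_id, condition columns.")
  }
  wide <- classified |>
    dplyr::filter(.data$condition %in% c("bare", "flanked"),
                  !is.na(.data$pair_id)) |>
    dplyr::select(dplyr::any_of(c("pair_id", "group_id", "category",
                                  "cation")),
                  "condition", "r", "label") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("r", "label"))
  n_candidate <- nrow(wide)
  ok <- !is.na(wide$r_bare) & !is.na(wide$r_flanked) &
    is.finite(wide$r_bare) & is.finite(wide$r_flanked)
  pairs <- wide[ok, ]
  if (nrow(pairs) == 0L) abort("no complete bare/flanked pairs found.")
  pairs <- pairs |>
    dplyr::rename(label_bare = "label_bare", label_flanked = "label_flanked") |>
    dplyr::mutate(delta_r = pair_delta_r(.data$r_flanked, .data$r_bare))

  long <- classified |>
    dplyr::filter(.data$pair_id %in% pairs$pair_id,
                  .data$condition %in% c("bare", "flanked"))
  groups <- if ("group_id" %in% names(long) && !all(is.na(long$group_id))) {
    long |>
      dplyr::group_by(.data$group_id, .data$condition) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$r),
                       sigma = group_sigma(.data$r), .groups = "drop")
  } else {
    tibble(group_id = character(), condition = character(), n = integer(),
           mean = numeric(), sigma = numeric())
  }

  prop_bare <- proportion_table(pairs$label_bare)
  prop_flanked <- proportion_table(pairs$label_flanked)
  proportions <- dplyr::bind_rows(
    dplyr::mutate(prop_bare, condition = "bare"),
    dplyr::mutate(prop_flanked, condition = "flanked")
  )

  pos <- positive_fraction(pairs$delta_r)
  overall <- paired_t_test(pairs$r_flanked, pairs$r_bare)
  tests <- dplyr::mutate(tidy(overall), scope = "all", .before = 1L)
  if ("category" %in% names(pairs)) {
    by_cat <- pairs |>
      dplyr::filter(!is.na(.data$category), .data$category != "none") |>
      dplyr::group_by(.data$category) |>
      dplyr::group_map(function(g, key) {
        if (nrow(g) < 2L) return(NULL)
        dplyr::mutate(tidy(paired_t_test(g$r_flanked, g$r_bare)),
                      scope = key$category, .before = 1L)
      })
    tests <- dplyr::bind_rows(tests, purrr::compact(by_cat))
  }

  if (!is.null(melting)) {
    tm_wide <- melting |>
      dplyr::filter(.data$condition %in% c("bare", "flanked"),
                    !is.na(.data$pair_id)) |>
      dplyr::select("pair_id", "condition", "tm") |>
      tidyr::pivot_wider(names_from = "condition", values_from = "tm",
                         names_prefix = "tm_")
    pairs <- dplyr::left_join(pairs, tm_wide, by = "pair_id")
    if (all(c("tm_flanked", "tm_bare") %in% names(pairs))) {
      pairs$delta_tm <- delta_tm(pairs$tm_flanked, pairs$tm_bare)
    }
  }

  summary <- list(
    n_pairs = nrow(pairs),
    n_excluded_pairs = n_candidate - nrow(pairs),
    positive_delta_r_percent = pos$percent,
    mean_delta_r = mean(pairs$delta_r),
    paired_t = list(statistic = overall$statistic, p_value = overall$p_value,
                    stars = overall$stars),
    proportions = list(
      bare = setNames(as.list(prop_bare$percent), prop_bare$label),
      flanked = setNames(as.list(prop_flanked$percent), prop_flanked$label)
    )
  )
  if ("category" %in% names(pairs)) {
    summary$mean_delta_r_by_category <- pairs |>
      dplyr::filter(!is.na(.data$category)) |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(mean_delta_r = mean(.data$delta_r), n = dplyr::n(),
                       .groups = "drop") |>
      as.list()
  }

  out <- list(pairs = pairs, groups = groups, proportions = proportions,
              tests = tests, positive = pos, summary = summary)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    readr::write_csv(pairs, file.path(dir, "pairs.csv"))
    readr::write_csv(groups, file.path(dir, "groups.csv"))
    readr::write_csv(tests, file.path(dir, "tests.csv"))
    readr::write_csv(proportions, file.path(dir, "proportions.csv"))
    jsonlite::write_json(summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
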