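#' Construct an oligonucleotide design
#'
#' A design describes one member of a three-loop G-quadruplex library built on
#' the template 5'-(flank5) GGG Ta GGG Tb GGG Tc GGG (flank3)-3': four G-tracts
#' of `g_run` guanines separated by three loops of `loops[1]`, `loops[2]` and
#' `loops[3]` copies of `loop_base`, with optional flanking nucleotides at
#' either end.
#'
#' @param loops Integer vector of length 3: lengths (nt) of the first (5'),
#'   central and third (3') loop. All must be >= 1.
#' @param flank5,flank3 Flanking nucleotide strings (possibly empty), A/C/G/T
#'   only, written 5' to 3'.
#' @param g_run Number of guanines per G-tract (>= 2, default 3).
#' @param loop_base Single nucleotide used to fill the loops (default "T").
#' @param name Optional label; if `NULL` a canonical name is generated for
#'   all-thymine flanks (see [parse_g4_name()] for the grammar).
#' @param phosphate5 Logical bookkeeping flag marking a 5'-terminal phosphate
#'   on an otherwise unflanked 5' end; it never changes the rendered sequence.
#'
#' @return An object of class `g4_design`.
#' @examples
#' d <- g4_design(c(1, 3, 6), flank5 = "TT", flank3 = "TT")
#' g4_sequence(d)
#' @export
g4_design <- function(loops, flank5 = "", flank3 = "", g_run = 3L,
                      loop_base = "T", name = NULL, phosphate5 = FALSE) {
  loops <- as.integer(loops)
  if (length(loops) != 3L || anyNA(loops) || any(loops < 1L)) {
    abort("`loops` must be three positive integers (loop lengths a, b, c).")
  }
  g_run <- as.integer(g_run)
  if (is.na(g_run) || g_run < 2L) {
    abort("`g_run` must be an integer >= 2.")
  }
  for (fl in list(flank5 = flank5, flank3 = flank3)) {
    if (!is.character(fl) || length(fl) != 1L || is.na(fl)) {
      abort("flanks must be single character strings (possibly empty).")
    }
  }
  if (grepl("[^ACGT]", flank5) || grepl("[^ACGT]", flank3)) {
    abort("flanks may contain only A, C, G or T.")
  }
  if (!is.character(loop_base) || nchar(loop_base) != 1L ||
      !loop_base %in% c("A", "C", "G", "T")) {
    abort("`loop_base` must be a single nucleotide (A/C/G/T).")
  }
  if (phosphate5 && nzchar(flank5)) {
    abort("`phosphate5` marks an unflanked 5' end; `flank5` must be empty.")
  }
  x <- structure(
    list(name = name, loops = loops, flank5 = flank5, flank3 = flank3,
         g_run = g_run, loop_base = loop_base, phosphate5 = isTRUE(phosphate5)),
    class = "g4_design"
  )
  if (is.null(x$name)) {
    # designs outside the canonical grammar (mixed flank bases, unequal
    # double flanks) get a descriptive fallback label
    x$name <- tryCatch(g4_name(x), error = function(e) {
      paste0(x$flank5, "[", paste(x$loops, collapse = ""), "]", x$flank3)
    })
  }
  x
}

#' @export
print.g4_design <- function(x, ...) {
  cat("<g4_design> ", x$name, "\n", sep = "")
  cat("  loops (a,b,c): ", paste(x$loops, collapse = ","),
      "   G-run: ", x$g_run, "\n", sep = "")
  cat("  flank5: '", x$flank5, "'  flank3: '", x$flank3, "'\n", sep = "")
  cat("  sequence: ", g4_sequence(x), "\n", sep = "")
  invisible(x)
}

#' Canonical library name of a design
#'
#' Names follow the library nomenclature: bare three-digit codes ("136") for
#' unflanked sequences; `5'Tk-abc`, `3'Tk-abc` or `DTk-abc` when k thymines
#' are appended at the 5' end, the 3' end, or both ends.
#'
#' @param design A [g4_design()].
#' @return A single string.
#' @export
g4_name <- function(design) {
  stopifnot(inherits(design, "g4_design"))
  if (any(design$loops > 9L)) {
    abort("canonical names require single-digit loop lengths (1-9).")
  }
  core <- paste(design$loops, collapse = "")
  n5 <- nchar(design$flank5)
  n3 <- nchar(design$flank3)
  if (n5 == 0L && n3 == 0L) return(core)
  if (n5 > 0L && n3 > 0L) {
    if (n5 != n3) abort("double-flank names require equal flank lengths.")
    return(paste0("DT", n5, "-", core))
  }
  if (n5 > 0L) paste0("5'T", n5, "-", core) else paste0("3'T", n3, "-", core)
}

#' Parse a library name into an oligonucleotide design
#'
#' Accepts the positional nomenclature of the loop-permutation library:
#' `abc` (three single digits, no flanks), `5'Tk-abc` (k nt at the 5' end),
#' `3'Tk-abc` (3' end) or `DTk-abc` (k nt at both ends), with k >= 1.
#' Loop digits are single-digit (1-9); natural sequences outside this grammar
#' are supplied to the pipeline as explicit sequence strings in the manifest
#' instead.
#'
#' @param name Name string, e.g. `"DT2-136"`.
#' @param flank_base Nucleotide used to build the flanks (default "T", the
#'   library standard; the name's "T" token is retained regardless, with the
#'   base recorded in the design's flank strings).
#' @inheritParams g4_design
#' @return A [g4_design()].
#' @examples
#' parse_g4_name("DT2-136")
#' parse_g4_name("5'T5-143")
#' @export
parse_g4_name <- function(name, flank_base = "T", g_run = 3L, loop_base = "T") {
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    abort("`name` must be a single string.")
  }
  m <- regmatches(name, regexec("^(?:(5'T|3'T|DT)([0-9]+)-)?([0-9]{3})$", name))[[1]]
  if (length(m) == 0L) {
    abort(paste0("malformed design name: '", name,
                 "' (expected 'abc', \"5'Tk-abc\", \"3'Tk-abc\" or 'DTk-abc')."))
  }
  prefix <- m[2]
  k <- m[3]
  digits <- m[4]
  loops <- as.integer(strsplit(digits, "")[[1]])
  if (any(loops == 0L)) {
    abort(paste0("zero loop length in name token '", digits, "'."))
  }
  flank5 <- ""
  flank3 <- ""
  if (nzchar(prefix)) {
    k <- as.integer(k)
    if (is.na(k) || k < 1L) {
      abort(paste0("invalid flank length token '", m[3], "' in '", name, "'."))
    }
    fl <- strrep(flank_base, k)
    if (prefix %in% c("5'T", "DT")) flank5 <- fl
    if (prefix %in% c("3'T", "DT")) flank3 <- fl
  }
  g4_design(loops, flank5 = flank5, flank3 = flank3, g_run = g_run,
            loop_base = loop_base, name = name)
}

#' Render the nucleotide sequence of a design
#'
#' Expands the template `flank5 + G^g + L^a + G^g + L^b + G^g + L^c + G^g +
#' flank3` (5' to 3'), where `G^g` is the G-tract and `L` the loop base.
#'
#' @param design A [g4_design()].
#' @return A single nucleotide string whose length is
#'   `4 * g_run + a + b + c + nchar(flank5) + nchar(flank3)`.
#' @examples
#' g4_sequence(g4_design(c(1, 3, 6)))
#' @export
g4_sequence <- function(design) {
  stopifnot(inherits(design, "g4_design"))
  g <- strrep("G", design$g_run)
  lp <- vapply(design$loops, function(n) strrep(design$loop_base, n), "")
  paste0(design$flank5, g, lp[1], g, lp[2], g, lp[3], g, design$flank3)
}

#' Enumerate a loop-permutation group
#'
#' A group is the set of sequences obtained by permuting a fixed multiset of
#' three loop lengths among the three loop positions; the 136 group, for
#' instance, has the six members 136, 163, 316, 361, 613, 631, while 244 has
#' three and 444 one.
#'
#' @param loop_multiset Three positive integers (order irrelevant).
#' @param flank_scheme One of `"WO"` (no flanks), `"5'Tn"`, `"3'Tn"` or
#'   `"DTn"` with `n` the flank length, e.g. `"DT2"`; case of the T is fixed.
#' @inheritParams parse_g4_name
#' @return A tibble with one row per distinct loop ordering, in lexicographic
#'   order of `(a, b, c)`: columns `name`, `a`, `b`, `c`, `flank5`, `flank3`,
#'   `sequence`, `category` (shortest-loop category, see
#'   [shortest_loop_category()]).
#' @examples
#' enumerate_group(c(1, 3, 6), "DT2")
#' @export
enumerate_group <- function(loop_multiset, flank_scheme = "WO",
                            flank_base = "T", g_run = 3L, loop_base = "T") {
  loops <- sort(as.integer(loop_multiset))
  if (length(loops) != 3L || anyNA(loops) || any(loops < 1L)) {
    abort("`loop_multiset` must be three positive integers.")
  }
  fl <- parse_flank_scheme(flank_scheme)
  perms <- expand.grid(a = unique(loops), b = unique(loops), c = unique(loops),
                       KEEP.OUT.ATTRS = FALSE)
  keep <- apply(perms, 1L, function(p) identical(sort(as.integer(p)), loops))
  perms <- perms[keep, , drop = FALSE]
  perms <- perms[order(perms$a, perms$b, perms$c), , drop = FALSE]
  designs <- purrr::pmap(perms, function(a, b, c) {
    g4_design(c(a, b, c),
              flank5 = if (fl$end5) strrep(flank_base, fl$k) else "",
              flank3 = if (fl$end3) strrep(flank_base, fl$k) else "",
              g_run = g_run, loop_base = loop_base)
  })
  tibble(
    name = vapply(designs, g4_name, ""),
    a = as.integer(perms$a), b = as.integer(perms$b), c = as.integer(perms$c),
    flank5 = vapply(designs, function(d) d$flank5, ""),
    flank3 = vapply(designs, function(d) d$flank3, ""),
    sequence = vapply(designs, g4_sequence, ""),
    category = shortest_loop_category(perms$a, perms$b, perms$c)
  )
}

parse_flank_scheme <- function(scheme) {
  if (identical(scheme, "WO")) return(list(end5 = FALSE, end3 = FALSE, k = 0L))
  m <- regmatches(scheme, regexec("^(5'T|3'T|DT)([0-9]+)$", scheme))[[1]]
  if (length(m) == 0L) {
    abort(paste0("unknown flank scheme '", scheme,
                 "' (expected WO, 5'Tn, 3'Tn or DTn)."))
  }
  k <- as.integer(m[3])
  if (k < 1L) abort("flank scheme length must be >= 1.")
  list(end5 = m[2] %in% c("5'T", "DT"), end3 = m[2] %in% c("3'T", "DT"), k = k)
}

#' Shortest-loop category of a loop triple
#'
#' Sequences whose shortest loop is a single nucleotide are categorised by the
#' position of that loop: `1bc` (first/5'-proximal loop), `a1c` (central) or
#' `ab1` (third/3'-proximal). The category is `none` when no loop has length 1
#' or when the length-1 minimum is not unique.
#'
#' @param a,b,c Loop lengths (vectorised).
#' @return A character vector in `{"1bc", "a1c", "ab1", "none"}`.
#' @examples
#' shortest_loop_category(1, 3, 4)
#' shortest_loop_category(3, 1, 6)
#' @export
shortest_loop_category <- function(a, b, c) {
  a <- as.integer(a); b <- as.integer(b); c <- as.integer(c)
  out <- rep("none", length(a))
  ones <- (a == 1L) + (b == 1L) + (c == 1L)
  out[ones == 1L & a == 1L] <- "1bc"
  out[ones == 1L & b == 1L] <- "a1c"
  out[ones == 1L & c == 1L] <- "ab1"
  out
}

#' Write a design table to FASTA
#'
#' @param designs A tibble with `name` and `sequence` columns (as returned by
#'   [enumerate_group()] or [run_design()]).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_design_fasta <- function(designs, path) {
  stopifnot(all(c("name", "sequence") %in% names(designs)))
  seqs <- Biostrings::DNAStringSet(designs$sequence)
  names(seqs) <- designs$name
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}
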