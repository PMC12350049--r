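#' Nucleotide composition and strand skews
#'
#' Counts unambiguous residues (N and other IUPAC ambiguities are excluded
#' from all counts), reports per-base percentages, A+T content and the
#' strand-asymmetry statistics
#' \deqn{AT\textrm{-}skew = (A - T)/(A + T), \quad
#'       GC\textrm{-}skew = (G - C)/(G + C).}
#' Zero denominators yield \code{NA} skews rather than an error.
#'
#' @param seq a DNA string, a named character vector of strings (counted as
#'   their concatenation), or a \code{mito_sequence}.
#' @param label text label for the summary row.
#' @return One-row tibble: \code{label}, \code{size} (counted residues),
#'   counts \code{A,C,G,T}, \code{pct_A..pct_C}, \code{at_content},
#'   \code{at_skew}, \code{gc_skew}, \code{n_excluded}. Percentages are kept
#'   at full precision; round at report time.
#' @export
composition_summary <- function(seq, label = NULL) {
  if (inherits(seq, "mito_sequence")) {
    label <- label %||% seq$id
    seq <- seq$residues
  }
  label <- label %||% (names(seq)[1] %||% "seq")
  s <- chars_seq(str_to_upper(seq))
  if (nchar(s) == 0L) abort("empty sequence")
  ch <- seq_chars(s)
  ch <- ch[ch != "-"] # gaps never counted
  cnt <- vapply(BASES, function(b) sum(ch == b), integer(1))
  total <- sum(cnt)
  if (total == 0L) abort("all residues ambiguous; nothing to count")
  pct <- 100 * cnt / total
  tibble(
    label = label,
    size = total,
    A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
    pct_A = pct[["A"]], pct_T = pct[["T"]],
    pct_G = pct[["G"]], pct_C = pct[["C"]],
    at_content = pct[["A"]] + pct[["T"]],
    at_skew = skew(cnt[["A"]], cnt[["T"]]),
    gc_skew = skew(cnt[["G"]], cnt[["C"]]),
    n_excluded = length(ch) - total
  )
}

#' Strand skew from two counts or percentages
#'
#' \code{skew(x, y) = (x - y)/(x + y)}; \code{NA} when \code{x + y == 0}.
#' Works equally on raw counts and on printed percentages, so published
#' composition rows can be checked directly.
#'
#' @param x,y counts (or percentages) of the two bases, e.g. A and T.
#' @return Dimensionless skew in \code{[-1, 1]}, or \code{NA}.
#' @export
skew <- function(x, y) {
  d <- x + y
  ifelse(d == 0, NA_real_, (x - y) / d)
}

#' Per-partition composition (Table-2 style)
#'
#' Computes \code{\link{composition_summary}} for the whole mitogenome and
#' for each requested feature class. By default partition sequences are the
#' annotated spans concatenated in genome order on heavy-strand coordinates
#' \emph{without} reverse-complementing light-strand genes, which is the
#' convention that keeps partition skews comparable with the whole-genome
#' row; \code{strand_oriented = TRUE} switches to gene-sense counting as a
#' sensitivity check. Overlapping bases belong to every feature that
#' contains them.
#'
#' @param genome a \code{mito_sequence} or DNA string.
#' @param a a \code{mito_annotation}.
#' @param classes feature classes to report, in output order.
#' @param strand_oriented reverse-complement L-strand genes before counting.
#' @return Tibble with one row per partition (first row = whole mitogenome),
#'   columns \code{partition} plus the \code{composition_summary} columns.
#' @export
summarize_partitions <- function(genome, a,
                                 classes = c("PCG", "rRNA", "tRNA", "CR"),
                                 strand_oriented = FALSE) {
  stopifnot(inherits(a, "mito_annotation"))
  res <- if (inherits(genome, "mito_sequence")) genome$residues else
    str_to_upper(genome)
  absent <- setdiff(classes, unique(a$cls))
  if (length(absent) > 0L) {
    abort(paste0("requested class absent from annotation: ",
                 paste(absent, collapse = ", ")))
  }
  rows <- map(classes, function(cl) {
    f <- filter(as_tibble(a), .data$cls == cl)
    spans <- if (strand_oriented) {
      extract_gene_seq(res, f)
    } else {
      substring(res, f$start, f$end)
    }
    composition_summary(chars_seq(spans), label = cl)
  })
  out <- bind_rows(
    composition_summary(res, label = "mitogenome"),
    bind_rows(rows)
  )
  rename(out, partition = "label") |>
    mutate(genome_id = genome_id(a), .before = 1L)
}

#' Format a composition table at report precision
#'
#' Rounds percentages to 2 decimal places and skews to 3, the precision
#' used in published composition tables; the unrounded tibble remains the
#' machine-readable output.
#'
#' @param x output of \code{\link{summarize_partitions}} or
#'   \code{\link{composition_summary}}.
#' @return Tibble with rounded report columns only.
#' @export
format_composition <- function(x) {
  x |>
    mutate(across(dplyr::starts_with("pct_"), ~ round(.x, 2)),
           at_content = round(.data$at_content, 2),
           at_skew = round(.data$at_skew, 3),
           gc_skew = round(.data$gc_skew, 3)) |>
    select(dplyr::any_of(c("genome_id", "partition", "label")), "size",
           "pct_A", "pct_T", "pct_G", "pct_C",
           "at_content", "at_skew", "gc_skew")
}
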