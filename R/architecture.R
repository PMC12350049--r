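#' Spacer/overlap ledger of consecutive features
#'
#' For each pair of consecutive annotated features computes the signed
#' intergenic-nucleotide count \code{IN = downstream.start - upstream.end - 1}:
#' positive values are spacers, negative values overlaps, zero means the
#' features abut. The ledger is linear (n-1 pairs for n features); the
#' wraparound pair across the origin of the circular genome is reported
#' separately in the attributes, not as a ledger row.
#'
#' @param a a \code{mito_annotation} (features sorted by start).
#' @return A tibble of class \code{mito_ledger} with columns
#'   \code{upstream}, \code{downstream}, \code{intergenic}. Use
#'   \code{\link[generics]{glance}} for the summary counts (spacers,
#'   overlaps, contiguous junctions, longest spacer / overlap and their
#'   flanking genes).
#' @export
build_ledger <- function(a) {
  stopifnot(inherits(a, "mito_annotation"))
  if (is.unsorted(a$start)) abort("features must be sorted by start")
  n <- nrow(a)
  if (n < 2L) abort("need at least two features for a ledger")
  led <- tibble(
    upstream = a$gene[-n],
    downstream = a$gene[-1L],
    intergenic = a$start[-1L] - a$end[-n] - 1L
  )
  glen <- genome_length(a)
  wrap <- if (a$start[1L] == 1L && a$end[n] == glen) {
    0L # last feature abuts the first across the origin
  } else {
    (glen - a$end[n]) + (a$start[1L] - 1L)
  }
  structure(
    led,
    genome_id = genome_id(a),
    wraparound = wrap,
    class = c("mito_ledger", class(tibble()))
  )
}

#' @method glance mito_ledger
#' @export
glance.mito_ledger <- function(x, ...) {
  sp <- x$intergenic > 0L
  ov <- x$intergenic < 0L
  imax <- if (any(sp)) which.max(x$intergenic) else NA_integer_
  imin <- if (any(ov)) which.min(x$intergenic) else NA_integer_
  tibble(
    n_junctions = nrow(x),
    n_spacers = sum(sp),
    n_overlaps = sum(ov),
    n_contiguous = sum(x$intergenic == 0L),
    total_spacer_bp = sum(x$intergenic[sp]),
    total_overlap_bp = -sum(x$intergenic[ov]),
    max_spacer_bp = if (is.na(imax)) NA_integer_ else x$intergenic[imax],
    max_spacer_between = if (is.na(imax)) NA_character_ else
      paste(x$upstream[imax], x$downstream[imax], sep = "/"),
    max_overlap_bp = if (is.na(imin)) NA_integer_ else -x$intergenic[imin],
    max_overlap_between = if (is.na(imin)) NA_character_ else
      paste(x$upstream[imin], x$downstream[imin], sep = "/")
  )
}

#' Partition length totals
#'
#' Total annotated length per feature class (PCG, tRNA, rRNA, CR) plus the
#' PCG fraction of the genome. Overlapping bases belong to every feature
#' containing them, so totals are sums of feature sizes (Table-style
#' convention), not union lengths.
#'
#' @param a a \code{mito_annotation}.
#' @return Tibble with columns \code{cls}, \code{n_features},
#'   \code{total_bp}, \code{fraction_of_genome}.
#' @export
partition_totals <- function(a) {
  stopifnot(inherits(a, "mito_annotation"))
  glen <- genome_length(a)
  a |>
    as_tibble() |>
    group_by(.data$cls) |>
    summarise(n_features = n(), total_bp = sum(.data$size),
              .groups = "drop") |>
    mutate(fraction_of_genome = .data$total_bp / glen) |>
    rename(cls = "cls")
}

# render trailing residues after the last complete in-frame codon the way
# gene tables print them: "TAA" (complete), "TA-" (2 nt), "T--" (1 nt)
render_stop <- function(tail_nt) {
  str_pad(tail_nt, 3L, side = "right", pad = "-")
}

#' Call start and stop codons from sequence
#'
#' For every protein-coding gene: the start codon is the first three
#' nucleotides of the strand-oriented gene sequence; the stop codon is the
#' trailing residues after the last full internal codon (a complete 3-mer
#' when size is a multiple of 3, otherwise a 1-2 nt remnant printed with
#' trailing dashes, e.g. \code{T--} or \code{TA-}). Completeness is
#' classified against the vertebrate mitochondrial stop set
#' (TAA, TAG, AGA, AGG). Annotated codons from the feature table, when
#' present, are surfaced side by side with the recomputed calls.
#'
#' @param genome a \code{mito_sequence} or DNA string.
#' @param a a \code{mito_annotation}.
#' @return Tibble with columns \code{gene}, \code{start_codon},
#'   \code{stop_codon}, \code{completeness}, \code{annotated_start},
#'   \code{annotated_stop}.
#' @export
call_codons <- function(genome, a) {
  stopifnot(inherits(a, "mito_annotation"))
  pcg <- filter(as_tibble(a), .data$cls == "PCG")
  if (nrow(pcg) == 0L) abort("no protein-coding genes in annotation")
  if (any(pcg$size < 6L)) {
    abort(paste0("PCG shorter than 6 nt: ",
                 paste(pcg$gene[pcg$size < 6L], collapse = ", ")))
  }
  seqs <- extract_gene_seq(genome, pcg)
  stops <- mito_stop_codons()
  tibble(
    gene = pcg$gene,
    start_codon = unname(str_sub(seqs, 1L, 3L)),
    stop_codon = unname(map_chr(seqs, function(s) {
      k <- nchar(s) %% 3L
      tail_nt <- if (k == 0L) str_sub(s, -3L) else str_sub(s, -k)
      render_stop(tail_nt)
    })),
    annotated_start = pcg$start_codon,
    annotated_stop = pcg$stop_codon
  ) |>
    mutate(completeness = if_else(
      !str_detect(.data$stop_codon, "-") & .data$stop_codon %in% stops,
      "complete", "incomplete"
    )) |>
    select("gene", "start_codon", "stop_codon", "completeness",
           "annotated_start", "annotated_stop")
}

#' Architecture summary of an annotated mitogenome
#'
#' Convenience wrapper combining \code{\link{partition_totals}} and the
#' \code{\link{build_ledger}} summary into one single-row tibble of the
#' headline architecture numbers.
#'
#' @param a a \code{mito_annotation}.
#' @return One-row tibble: genome length, gene count, per-class totals,
#'   spacer/overlap tallies and extremes.
#' @export
architecture_summary <- function(a) {
  pt <- partition_totals(a)
  tot <- function(cl) {
    v <- pt$total_bp[pt$cls == cl]
    if (length(v) == 0L) NA_integer_ else v
  }
  led <- glance.mito_ledger(build_ledger(a))
  bind_cols(
    tibble(
      genome_id = genome_id(a),
      genome_length = genome_length(a),
      n_genes = sum(a$cls != "CR"),
      pcg_bp = tot("PCG"),
      trna_bp = tot("tRNA"),
      rrna_bp = tot("rRNA"),
      cr_bp = tot("CR"),
      pcg_fraction = tot("PCG") / genome_length(a)
    ),
    led
  )
}
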