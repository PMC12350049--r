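# three-letter amino-acid labels used in codon reports
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Stop")

# synonymous family partition under the vertebrate mitochondrial code.
# family_mode "report" detaches ATG and TGG as singleton families (the
# convention under which Met-AUG and Trp-UGG print RSCU exactly 1 in codon
# usage figures); "code" groups strictly by encoded amino acid, so
# {ATA, ATG} = Met and {TGA, TGG} = Trp.
codon_families <- function(family_mode = c("report", "code")) {
  family_mode <- match.arg(family_mode)
  code <- mito_code()
  fam <- unname(code)
  names(fam) <- names(code)
  if (family_mode == "report") {
    fam["ATG"] <- "M1"
    fam["TGG"] <- "W1"
  }
  fam
}

#' Count codons over protein-coding genes
#'
#' Reads codons in-frame from each strand-oriented PCG sequence, drops
#' trailing incomplete codons (1-2 nt remnants of incomplete stop codons),
#' and tabulates all 64 codons under the vertebrate mitochondrial code
#' (NCBI table 2: AGA/AGG are stops, ATA is Met, TGA is Trp). Stop codons
#' are excluded from RSCU and amino-acid percentages by default.
#'
#' @param genome a \code{mito_sequence} or DNA string; ignored when
#'   \code{a} is \code{NULL} and \code{seqs} is given.
#' @param a a \code{mito_annotation}; its PCG rows are used.
#' @param seqs alternatively, a named character vector of in-frame coding
#'   sequences (strand-oriented) to count directly.
#' @param exclude_stops drop stop codons from totals, RSCU and percentages.
#' @param family_mode \code{"report"} (default; ATG and TGG singleton
#'   families) or \code{"code"} (strict table-2 amino-acid families).
#' @return A tibble of class \code{mito_codon_table}: one row per codon with
#'   \code{codon}, \code{aa}, \code{aa3}, \code{family}, \code{count},
#'   \code{rscu}. Attributes record the total counted codons and options.
#' @export
count_codons <- function(genome = NULL, a = NULL, seqs = NULL,
                         exclude_stops = TRUE,
                         family_mode = c("report", "code")) {
  family_mode <- match.arg(family_mode)
  if (is.null(seqs)) {
    stopifnot(inherits(a, "mito_annotation"))
    pcg <- filter(as_tibble(a), .data$cls == "PCG")
    if (nrow(pcg) == 0L) abort("no protein-coding genes in annotation")
    seqs <- extract_gene_seq(genome, pcg)
  }
  if (any(nchar(seqs) < 3L)) abort("gene shorter than one codon")
  cods <- unlist(map(seqs, split_codons), use.names = FALSE)
  cods <- cods[!str_detect(cods, "[^ACGT]")] # ambiguous codons excluded
  code <- mito_code()
  counts <- table(factor(cods, levels = names(code)))
  tab <- tibble(
    codon = names(code),
    aa = unname(code),
    aa3 = unname(AA3[unname(code)]),
    family = unname(codon_families(family_mode)),
    count = as.integer(counts)
  )
  if (exclude_stops) {
    tab$count[tab$aa == "*"] <- 0L
  }
  tab <- rscu(tab)
  structure(
    tab,
    total_codons = sum(tab$count),
    exclude_stops = exclude_stops,
    family_mode = family_mode,
    class = c("mito_codon_table", class(tibble()))
  )
}

#' Relative synonymous codon usage
#'
#' \deqn{RSCU(c) = |F| \; n_c / \sum_{c' \in F} n_{c'}}
#' for codon \code{c} in synonymous family \code{F}: the observed count
#' relative to the family mean, so 1 means no usage bias. Families with zero
#' total count get \code{NA}; single-codon families are 1 whenever used.
#' Stop codons never receive an RSCU.
#'
#' @param tab a codon table as built by \code{\link{count_codons}}, or any
#'   tibble with \code{codon}, \code{aa}, \code{family}, \code{count}.
#' @return The table with its \code{rscu} column (re)computed.
#' @export
rscu <- function(tab) {
  tab |>
    group_by(.data$family) |>
    mutate(rscu = if_else(
      .data$aa == "*" | sum(.data$count) == 0L,
      NA_real_,
      n() * .data$count / sum(.data$count)
    )) |>
    ungroup()
}

#' Amino-acid composition of the coding complement
#'
#' Percentage of total counted (non-stop) codons per amino acid, with the
#' two leucine families (CUN + UUR) and the two serine families merged, as
#' amino-acid abundance plots do.
#'
#' @param tab a \code{mito_codon_table}.
#' @return Tibble \code{aa3}, \code{count}, \code{pct}, sorted by
#'   decreasing abundance.
#' @export
amino_acid_profile <- function(tab) {
  aa <- tab |>
    filter(.data$aa != "*") |>
    group_by(.data$aa3) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    filter(.data$count > 0L)
  total <- sum(aa$count)
  if (total == 0L) abort("no counted codons")
  aa |>
    mutate(pct = 100 * .data$count / total) |>
    arrange(dplyr::desc(.data$pct))
}

#' @method glance mito_codon_table
#' @export
glance.mito_codon_table <- function(x, ...) {
  prof <- amino_acid_profile(x)
  used <- filter(x, .data$count > 0L, .data$aa != "*")
  tibble(
    total_codons = attr(x, "total_codons", exact = TRUE),
    n_codons_used = nrow(used),
    top_aa = prof$aa3[1L],
    top_aa_pct = prof$pct[1L],
    max_rscu_codon = used$codon[which.max(used$rscu)],
    max_rscu = max(used$rscu)
  )
}

#' Pool or average codon tables across genomes
#'
#' Either sums raw counts before computing RSCU (\code{"pooled"}) or
#' computes RSCU per genome and averages the values (\code{"mean"}), the
#' two readings of a multi-species "average RSCU".
#'
#' @param tabs list of \code{mito_codon_table}s.
#' @param how \code{"pooled"} or \code{"mean"}.
#' @return A codon tibble with \code{count} (summed) and \code{rscu}.
#' @export
combine_codon_tables <- function(tabs, how = c("pooled", "mean")) {
  how <- match.arg(how)
  stopifnot(length(tabs) >= 1L)
  base <- as_tibble(tabs[[1L]])[, c("codon", "aa", "aa3", "family")]
  counts <- rowSums(vapply(tabs, function(t) t$count, integer(nrow(base))))
  base$count <- as.integer(counts)
  if (how == "pooled") {
    rscu(base)
  } else {
    vals <- vapply(tabs, function(t) t$rscu, numeric(nrow(base)))
    base$rscu <- rowMeans(vals, na.rm = TRUE)
    base$rscu[is.nan(base$rscu)] <- NA_real_
    base
  }
}
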