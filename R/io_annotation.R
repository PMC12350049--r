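#' Construct a circular mitochondrial sequence object
#'
#' A light container for a (typically circular) mitogenome sequence: the
#' residue string over \code{A,C,G,T,N}, an identifier, and circularity.
#'
#' @param residues single DNA string (upper- or lower-case; N permitted).
#' @param id text label (e.g., an accession).
#' @param circular logical; vertebrate mitogenomes are circular.
#' @return An object of class \code{mito_sequence}: a list with elements
#'   \code{id}, \code{residues}, \code{length}, \code{circular}.
#' @export
mito_sequence <- function(residues, id = "genome", circular = TRUE) {
  if (length(residues) != 1L || !is.character(residues)) {
    abort("`residues` must be a single character string.")
  }
  residues <- str_to_upper(residues)
  if (nchar(residues) == 0L) abort("empty sequence")
  bad <- setdiff(unique(seq_chars(residues)), c(BASES, "N"))
  if (length(bad) > 0L) {
    abort(paste0("sequence contains non-DNA characters: ", chars_seq(bad)))
  }
  structure(
    list(id = id, residues = residues, length = nchar(residues),
         circular = isTRUE(circular)),
    class = "mito_sequence"
  )
}

#' @export
print.mito_sequence <- function(x, ...) {
  cat("<mito_sequence> ", x$id, ": ", x$length, " bp",
      if (x$circular) " (circular)" else "", "\n", sep = "")
  invisible(x)
}

# feature class from a gene name or GenBank feature key
infer_cls <- function(name) {
  case_when(
    str_detect(name, stringr::regex("^tRNA", ignore_case = TRUE)) ~ "tRNA",
    str_detect(name, stringr::regex("rRNA|ribosomal", ignore_case = TRUE)) ~ "rRNA",
    str_detect(name, stringr::regex("^(CR|D-?loop|control[ _-]?region)$",
                                    ignore_case = TRUE)) ~ "CR",
    TRUE ~ "PCG"
  )
}

# conventional disambiguation of the duplicated tRNA-Leu / tRNA-Ser genes;
# by anticodon when available (Leu: TAA=L2, TAG=L1; Ser: TGA=S2, GCT=S1),
# otherwise by genome order (vertebrate order puts L2 and S2 first)
disambiguate_trna <- function(gene, anticodon) {
  for (aa in c("Leu", "Ser")) {
    idx <- which(gene == paste0("tRNA-", aa))
    if (length(idx) < 2L) next
    tags <- if (aa == "Leu") {
      c(TAA = "L2", TAG = "L1")
    } else {
      c(TGA = "S2", GCT = "S1")
    }
    lab <- tags[anticodon[idx]]
    if (anyNA(lab)) {
      lab <- if (aa == "Leu") c("L2", "L1") else c("S2", "S1")
      lab <- lab[seq_along(idx)]
    }
    gene[idx] <- paste0("tRNA-", aa, "(", lab, ")")
  }
  gene
}

#' Construct a mitogenome annotation
#'
#' Builds the ordered feature table used throughout the package: one row per
#' gene or control region, with 1-based inclusive coordinates, strand
#' (\code{H} heavy / \code{L} light), size, optional tRNA anticodon and
#' annotated start/stop codons. Features are sorted by start (ties broken by
#' end, then name); "D-loop"/"control region" names are normalized to
#' \code{CR}; duplicated tRNA-Leu/tRNA-Ser names gain the conventional
#' (L1)/(L2), (S1)/(S2) suffixes.
#'
#' @param features data frame with columns \code{gene}, \code{start},
#'   \code{end}, \code{strand}; optionally \code{anticodon},
#'   \code{start_codon}, \code{stop_codon}, \code{cls}, \code{size}.
#' @param genome_id text label for the genome.
#' @param genome_length total genome length in bp; defaults to
#'   \code{max(end)}.
#' @return A tibble of class \code{mito_annotation} with attributes
#'   \code{genome_id} and \code{genome_length}.
#' @export
mito_annotation <- function(features, genome_id = "genome",
                            genome_length = NULL) {
  f <- as_tibble(features)
  need <- c("gene", "start", "end", "strand")
  miss <- setdiff(need, names(f))
  if (length(miss) > 0L) {
    abort(paste0("missing feature columns: ", paste(miss, collapse = ", ")))
  }
  if (nrow(f) == 0L) abort("no annotatable features")
  f$start <- as.integer(f$start)
  f$end <- as.integer(f$end)
  if (anyNA(f$start) || anyNA(f$end)) abort("non-numeric coordinates")
  if (!all(f$strand %in% c("H", "L"))) abort("strand must be 'H' or 'L'")
  if (any(f$start < 1L) || any(f$end < f$start)) {
    abort("coordinates must satisfy 1 <= start <= end")
  }

  for (col in c("anticodon", "start_codon", "stop_codon")) {
    if (!col %in% names(f)) f[[col]] <- NA_character_
    f[[col]][!is.na(f[[col]]) & f[[col]] == ""] <- NA_character_
  }

  # normalize CR naming before class inference
  f$gene <- if_else(
    str_detect(f$gene, stringr::regex("^(CR|D-?loop|control[ _-]?region)$",
                                      ignore_case = TRUE)),
    "CR", f$gene
  )
  if (!"cls" %in% names(f) || anyNA(f$cls)) f$cls <- infer_cls(f$gene)
  f$anticodon <- if_else(f$cls == "tRNA", f$anticodon, NA_character_)

  computed_size <- f$end - f$start + 1L
  if ("size" %in% names(f) && !all(is.na(f$size))) {
    sz <- as.integer(f$size)
    bad <- which(!is.na(sz) & sz != computed_size)
    if (length(bad) > 0L) {
      abort(paste0(
        "size column contradicts coordinates for: ",
        paste(f$gene[bad], collapse = ", ")
      ))
    }
  }
  f$size <- computed_size

  genome_length <- as.integer(genome_length %||% max(f$end))
  if (any(f$end > genome_length)) {
    abort(paste0(
      "feature beyond sequence length: ",
      paste(f$gene[f$end > genome_length], collapse = ", ")
    ))
  }

  f <- arrange(f, .data$start, .data$end, .data$gene)
  f$gene <- disambiguate_trna(f$gene, f$anticodon)
  f <- select(f, "gene", "cls", "start", "end", "strand", "size",
              "anticodon", "start_codon", "stop_codon")

  structure(
    f,
    genome_id = genome_id,
    genome_length = genome_length,
    class = c("mito_annotation", class(tibble()))
  )
}

#' @export
#' @rdname mito_annotation
#' @param x a \code{mito_annotation}.
genome_length <- function(x) attr(x, "genome_length", exact = TRUE)

#' @export
#' @rdname mito_annotation
genome_id <- function(x) attr(x, "genome_id", exact = TRUE)

normalize_header <- function(x) {
  x <- str_to_upper(x)
  x <- str_replace_all(x, "\\(.*\\)", "")
  x <- str_replace_all(x, "[^A-Z]", "")
  x
}

#' Read a Table-style feature table
#'
#' Reads a tab-delimited gene table laid out like a published
#' gene-organization table (columns Genes / Start / End / Strand / Size /
#' Intergenic nucleotide / Anti-codon / Start codon / Stop codon; header
#' matching is case- and punctuation-insensitive, extra columns such as the
#' intergenic one are ignored). A \code{Size} column, when present, is
#' validated against \code{end - start + 1}; any mismatch is an error.
#'
#' @param path path to a UTF-8 tab-separated file with a header row.
#' @param genome_id label for the genome; defaults to the file name.
#' @param genome_length optional; defaults to the last feature's end.
#' @return A \code{mito_annotation}.
#' @export
read_feature_table <- function(path, genome_id = NULL, genome_length = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  key <- normalize_header(names(raw))
  pick <- function(nm) {
    i <- match(nm, key)
    if (is.na(i)) NULL else raw[[i]]
  }
  gene <- pick("GENES") %||% pick("GENE")
  if (is.null(gene)) abort("no gene/genes column found")
  start <- pick("START")
  end <- pick("END")
  strand <- pick("STRAND")
  if (is.null(start) || is.null(end) || is.null(strand)) {
    abort("feature table needs start, end and strand columns")
  }
  strip_num <- function(x) suppressWarnings(as.integer(str_replace_all(x, "[,\\s]", "")))
  start_i <- strip_num(start)
  end_i <- strip_num(end)
  if (anyNA(start_i) || anyNA(end_i)) abort("non-numeric coordinates")
  feats <- tibble(
    gene = str_trim(gene),
    start = start_i,
    end = end_i,
    strand = str_trim(strand),
    size = strip_num(pick("SIZE") %||% pick("SIZEBP") %||%
                       rep(NA_character_, length(gene))),
    anticodon = clean_codon_col(pick("ANTICODON")),
    start_codon = clean_codon_col(pick("STARTCODON")),
    stop_codon = clean_codon_col(pick("STOPCODON"))
  )
  mito_annotation(
    feats,
    genome_id = genome_id %||% basename(path),
    genome_length = genome_length
  )
}

clean_codon_col <- function(x) {
  if (is.null(x)) return(NA_character_)
  x <- str_trim(x)
  x[x %in% c("", ".", "˙", "-", "–")] <- NA_character_
  # unify unicode dashes used for incomplete stops to ASCII "-"
  str_replace_all(x, "[‐‑‒–—―−]", "-")
}

#' Write a feature table
#'
#' Writes the annotation back out in the Table-style layout, including the
#' signed intergenic-nucleotide column recomputed from coordinates. The
#' writer/reader pair round-trips all coordinate, strand, size and codon
#' fields.
#'
#' @param a a \code{mito_annotation}.
#' @param path output path (tab-separated, UTF-8).
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(a, path) {
  stopifnot(inherits(a, "mito_annotation"))
  out <- as_tibble(a)
  out$intergenic <- c(out$start[-1L] - out$end[-nrow(out)] - 1L, NA_integer_)
  out <- select(out, "gene", "start", "end", "strand", "size",
                "intergenic", "anticodon", "start_codon", "stop_codon")
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a GenBank flat file
#'
#' A minimal reader for annotated mitogenome records: parses LOCUS,
#' the FEATURES table (gene/CDS/tRNA/rRNA/D-loop keys, \code{a..b} and
#' \code{complement(a..b)} locations, \code{/gene}, \code{/product} and
#' \code{/note} qualifiers) and the ORIGIN sequence. Complement-strand
#' features are assigned strand \code{L}. Features that span the origin
#' (join locations) are not supported.
#'
#' @param path path to a GenBank flat file.
#' @return A list with elements \code{sequence} (a \code{mito_sequence}) and
#'   \code{annotation} (a \code{mito_annotation}).
#' @export
read_genbank <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  locus <- str_trim(lines[str_starts(lines, "LOCUS")][1] %||% "")
  acc_line <- lines[str_starts(lines, "ACCESSION")]
  id <- if (length(acc_line) > 0L) {
    str_trim(str_replace(acc_line[1], "ACCESSION", ""))
  } else if (nchar(locus) > 0L) {
    strsplit(locus, "\\s+")[[1]][2]
  } else {
    basename(path)
  }

  fstart <- which(str_starts(lines, "FEATURES"))
  ostart <- which(str_starts(lines, "ORIGIN"))
  if (length(ostart) == 0L) abort("missing ORIGIN sequence")
  if (length(fstart) == 0L) abort("no annotatable features")

  # sequence
  seq_lines <- lines[(ostart[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!str_starts(seq_lines, "//")]
  residues <- str_to_upper(str_replace_all(chars_seq(seq_lines), "[^A-Za-z]", ""))
  if (nchar(residues) == 0L) abort("missing ORIGIN sequence")
  genome <- mito_sequence(residues, id = id)

  # features block: key lines start at column 6, qualifiers at column 22
  fl <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
  key_idx <- which(str_detect(fl, "^ {5}\\S"))
  if (length(key_idx) == 0L) abort("no annotatable features")
  feats <- list()
  for (k in seq_along(key_idx)) {
    i <- key_idx[k]
    j <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(fl)
    block <- fl[i:j]
    head_parts <- strsplit(str_trim(block[1]), "\\s+")[[1]]
    key <- head_parts[1]
    if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")) next
    loc <- paste(head_parts[-1], collapse = "")
    quals <- paste(str_trim(block[-1]), collapse = " ")
    if (str_detect(loc, "join")) {
      abort(paste0("join/origin-spanning locations not supported: ", loc))
    }
    strand <- if (str_detect(loc, "complement")) "L" else "H"
    nums <- as.integer(strsplit(str_replace_all(loc, "[^0-9.]", ""), "\\.\\.")[[1]])
    if (length(nums) != 2L || anyNA(nums)) next
    getq <- function(q) {
      m <- stringr::str_match(quals, paste0("/", q, "=\"([^\"]*)\""))[, 2]
      if (is.na(m)) NULL else m
    }
    name <- if (key == "D-loop") {
      "CR"
    } else {
      getq("gene") %||% getq("product") %||% getq("note") %||% key
    }
    feats[[length(feats) + 1L]] <- tibble(
      gene = name,
      cls = switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                   `D-loop` = "CR", infer_cls(name)),
      start = nums[1], end = nums[2], strand = strand,
      anticodon = getq("anticodon_seq") %||% NA_character_
    )
  }
  if (length(feats) == 0L) abort("no annotatable features")
  feats <- bind_rows(feats)
  bad <- feats$end > genome$length
  if (any(bad)) {
    abort(paste0("feature beyond sequence length: ",
                 paste(feats$gene[bad], collapse = ", ")))
  }
  ann <- mito_annotation(feats, genome_id = id, genome_length = genome$length)
  list(sequence = genome, annotation = ann)
}

#' Extract strand-oriented gene sequences
#'
#' Returns the residues \code{start..end} for heavy-strand features and the
#' reverse complement of that span for light-strand features, so every
#' returned sequence reads 5'→3' in the gene's sense orientation.
#'
#' @param genome a \code{mito_sequence} (or a plain DNA string).
#' @param a a \code{mito_annotation} or any data frame with \code{gene},
#'   \code{start}, \code{end}, \code{strand} columns (may be a single row).
#' @return Named character vector of gene sequences (names = gene).
#' @export
extract_gene_seq <- function(genome, a) {
  res <- if (inherits(genome, "mito_sequence")) genome$residues else
    str_to_upper(genome)
  glen <- nchar(res)
  if (any(a$end > glen) || any(a$start < 1L)) {
    abort(paste0("feature beyond sequence length: ",
                 paste(a$gene[a$end > glen | a$start < 1L], collapse = ", ")))
  }
  out <- substring(res, a$start, a$end)
  isL <- a$strand == "L"
  out[isL] <- revcomp(out[isL])
  setNames(out, a$gene)
}

#' Read and write FASTA
#'
#' Thin wrappers over \pkg{Biostrings} returning/consuming named character
#' vectors, the package's working representation for (aligned) sequences.
#'
#' @param path file path.
#' @return \code{read_fasta}: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param x named character vector of DNA strings (gaps allowed).
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(x), path
  )
  invisible(path)
}

#' Bundled example feature table
#'
#' Path to the feature table of the Cyclocheilichthys repasson mitogenome
#' (GenBank PP937077) shipped with the package: 37 genes plus the control
#' region over a 16,571 bp circular genome.
#'
#' @return File path.
#' @export
crepasson_feature_table <- function() {
  system.file("extdata", "crepasson_features.tsv", package = "mitochar",
              mustWork = TRUE)
}
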