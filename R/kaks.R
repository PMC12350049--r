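# --- Nei-Gojobori (1986) site counting and path averaging -------------------

# per-codon synonymous site count: at each position the fraction of one-step
# changes that are synonymous, mutations to stop codons disregarded (removed
# from numerator and denominator)
ng_syn_sites <- function() {
  code <- mito_code()
  stops <- mito_stop_codons()
  sense <- setdiff(names(code), stops)
  out <- setNames(numeric(length(sense)), sense)
  for (cod in sense) {
    ch <- seq_chars(cod)
    s <- 0
    for (pos in 1:3) {
      alts <- setdiff(BASES, ch[pos])
      syn <- 0L
      valid <- 0L
      for (b in alts) {
        mut <- ch
        mut[pos] <- b
        mutc <- chars_seq(mut)
        if (mutc %in% stops) next
        valid <- valid + 1L
        if (code[[mutc]] == code[[cod]]) syn <- syn + 1L
      }
      if (valid > 0L) s <- s + syn / valid
    }
    out[cod] <- s
  }
  out
}

# cache: computed once per session
ng_sites_env <- new.env(parent = emptyenv())
get_ng_syn_sites <- function() {
  if (is.null(ng_sites_env$tab)) ng_sites_env$tab <- ng_syn_sites()
  ng_sites_env$tab
}

# synonymous/nonsynonymous differences between two codons, averaged with
# equal weight over shortest mutational paths; paths through stop codons are
# excluded (all paths used if none survive)
ng_codon_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  code <- mito_code()
  stops <- mito_stop_codons()
  ch1 <- seq_chars(c1)
  ch2 <- seq_chars(c2)
  pos <- which(ch1 != ch2)
  perms <- switch(length(pos),
    list(pos),
    list(pos, rev(pos)),
    {
      p <- pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    }
  )
  walk_path <- function(order) {
    cur <- ch1
    sd <- 0L
    nd <- 0L
    for (p in order) {
      nxt <- cur
      nxt[p] <- ch2[p]
      from <- chars_seq(cur)
      to <- chars_seq(nxt)
      if (to %in% stops && !identical(nxt, ch2)) return(NULL) # via a stop
      if (to %in% stops) return(NULL) # ends in stop: caller filtered these
      if (code[[from]] == code[[to]]) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- compact(map(perms, walk_path))
  if (length(res) == 0L) {
    # no stop-free path: fall back to counting through stops
    walk_all <- function(order) {
      cur <- ch1
      sd <- 0L
      nd <- 0L
      for (p in order) {
        nxt <- cur
        nxt[p] <- ch2[p]
        from <- chars_seq(cur)
        to <- chars_seq(nxt)
        syn <- !(from %in% stops) && !(to %in% stops) &&
          code[[from]] == code[[to]]
        if (syn) sd <- sd + 1L else nd <- nd + 1L
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }
    res <- map(perms, walk_all)
  }
  colMeans(do.call(rbind, res))
}

jukes_cantor <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori Ka/Ks for a codon-aligned gene pair
#'
#' Synonymous (Ks) and nonsynonymous (Ka) substitution rates per site by the
#' Nei-Gojobori (1986) method under the vertebrate mitochondrial code:
#' synonymous site fractions per codon position (mutations to stop codons
#' disregarded), observed differences averaged with equal weight over
#' shortest mutational paths (paths through stop codons excluded), and the
#' Jukes-Cantor correction applied to the proportions. \code{ka_ks} is
#' \code{NA} when Ks is 0 or undefined.
#'
#' @param x,y in-frame codon-aligned DNA strings of equal length. Codon
#'   pairs containing gaps or ambiguities are excluded; a trailing stop
#'   codon is dropped; an internal stop is an error.
#' @return One-row tibble: \code{codons}, \code{S}, \code{N}, \code{Sd},
#'   \code{Nd}, \code{pS}, \code{pN}, \code{Ks}, \code{Ka}, \code{ka_ks}.
#' @export
nei_gojobori <- function(x, y) {
  if (nchar(x) != nchar(y)) abort("sequences differ in length")
  cx <- split_codons(str_to_upper(x))
  cy <- split_codons(str_to_upper(y))
  if (length(cx) == 0L) abort("no complete codons")
  stops <- mito_stop_codons()
  # drop a trailing stop in either sequence
  nlast <- length(cx)
  if (cx[nlast] %in% stops || cy[nlast] %in% stops) {
    cx <- cx[-nlast]
    cy <- cy[-nlast]
  }
  ok <- !str_detect(cx, "[^ACGT]") & !str_detect(cy, "[^ACGT]")
  cx <- cx[ok]
  cy <- cy[ok]
  if (length(cx) == 0L) abort("no comparable codons")
  if (any(cx %in% stops) || any(cy %in% stops)) {
    abort("internal stop codon in coding sequence")
  }
  syn <- get_ng_syn_sites()
  S <- (sum(syn[cx]) + sum(syn[cy])) / 2
  N <- 3 * length(cx) - S
  dif <- which(cx != cy)
  sd <- 0
  nd <- 0
  for (k in dif) {
    d <- ng_codon_diffs(cx[k], cy[k])
    sd <- sd + d[["sd"]]
    nd <- nd + d[["nd"]]
  }
  pS <- if (S > 0) sd / S else NA_real_
  pN <- if (N > 0) nd / N else NA_real_
  Ks <- jukes_cantor(pS)
  Ka <- jukes_cantor(pN)
  if ((!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)) {
    warn("proportion >= 3/4: Jukes-Cantor correction undefined, NA returned")
  }
  tibble(
    codons = length(cx), S = S, N = N, Sd = sd, Nd = nd,
    pS = pS, pN = pN, Ks = Ks, Ka = Ka,
    ka_ks = if_else(is.na(Ka) | is.na(Ks) | Ks == 0, NA_real_, Ka / Ks)
  )
}

#' Per-gene pairwise Ka/Ks across a set of annotated genomes
#'
#' Runs \code{\link{nei_gojobori}} for every gene shared by every pair of
#' genomes. Sequences are extracted strand-oriented; genes whose lengths
#' differ between two genomes are skipped for that pair (no aligner is
#' bundled; supply pre-aligned sets for diverged inputs with indels).
#'
#' @param genomes named list of \code{mito_sequence} objects (or strings).
#' @param annotations named list of matching \code{mito_annotation}s.
#' @param genes genes to test; default all PCGs of the first annotation.
#' @return Tibble: \code{gene}, \code{genome_i}, \code{genome_j} plus the
#'   \code{nei_gojobori} columns.
#' @export
pairwise_kaks <- function(genomes, annotations, genes = NULL) {
  stopifnot(length(genomes) == length(annotations), length(genomes) >= 2L)
  ids <- names(genomes) %||% paste0("g", seq_along(genomes))
  cds <- map(seq_along(genomes), function(i) {
    pcg <- filter(as_tibble(annotations[[i]]), .data$cls == "PCG")
    extract_gene_seq(genomes[[i]], pcg)
  })
  genes <- genes %||% names(cds[[1L]])
  pairs <- utils::combn(length(genomes), 2L)
  rows <- list()
  for (g in genes) {
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]
      j <- pairs[2L, k]
      if (!g %in% names(cds[[i]]) || !g %in% names(cds[[j]])) next
      si <- cds[[i]][[g]]
      sj <- cds[[j]][[g]]
      if (nchar(si) != nchar(sj)) next
      # trim to complete codons (incomplete terminal stops are sub-codon)
      ncod <- nchar(si) %/% 3L
      si <- str_sub(si, 1L, 3L * ncod)
      sj <- str_sub(sj, 1L, 3L * ncod)
      rows[[length(rows) + 1L]] <- bind_cols(
        tibble(gene = g, genome_i = ids[i], genome_j = ids[j]),
        nei_gojobori(si, sj)
      )
    }
  }
  if (length(rows) == 0L) abort("no comparable gene pairs")
  bind_rows(rows)
}
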