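# --- synthetic annotated mitogenomes with known truth -----------------------

# per-partition base-frequency targets (A, C, G, T) for the default
# configuration: the composition of a typical AT-rich, negatively GC-skewed
# cyprinid mitogenome (~57.7% A+T overall)
default_partition_freqs <- function() {
  list(
    PCG  = c(A = 0.3115, C = 0.2762, G = 0.1460, T = 0.2664),
    rRNA = c(A = 0.3521, C = 0.2466, G = 0.2049, T = 0.1964),
    tRNA = c(A = 0.3114, C = 0.2502, G = 0.1940, T = 0.2444),
    CR   = c(A = 0.3617, C = 0.1917, G = 0.1209, T = 0.3257),
    background = c(A = 0.3304, C = 0.2710, G = 0.1520, T = 0.2466)
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-mitogenome generator. Defaults
#' emulate the structure of a cyprinid mitogenome: the standard vertebrate
#' gene order and strand layout (13 PCGs, 22 tRNAs, 2 rRNAs, 1 control
#' region over ~16.5 kb, including the conserved ATP8/ATP6 and ND4L/ND4
#' 7 bp overlaps), AT-rich composition with negative GC-skew, a
#' transition/transversion rate ratio \code{kappa}, and per-gene
#' \code{omega} (the acceptance probability of nonsynonymous changes,
#' < 1 = purifying selection).
#'
#' @param seed integer seed; the same config yields byte-identical output.
#' @param template a \code{mito_annotation} giving gene order, coordinates,
#'   strands and anticodons; default is the bundled vertebrate layout.
#' @param partition_freqs named list of A/C/G/T frequency vectors per
#'   feature class (plus \code{background} for spacers).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega scalar or named per-gene vector of nonsynonymous acceptance
#'   probabilities.
#' @param branch_lengths named numeric vector: proposed substitutions per
#'   site from the ancestor to each descendant genome.
#' @param csb_motifs named character vector of control-region blocks to
#'   implant in order (NULL = none).
#' @param cr_repeat optional list \code{list(motif =, copies =)}: a tandem
#'   repeat implanted in the control region.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       template = NULL,
                       partition_freqs = default_partition_freqs(),
                       kappa = 4,
                       omega = 0.05,
                       branch_lengths = c(sp1 = 0.02, sp2 = 0.05,
                                          sp3 = 0.08, sp4 = 0.10),
                       csb_motifs = csb_seed_motifs(),
                       cr_repeat = NULL) {
  stopifnot(kappa > 0, all(omega >= 0))
  freqs <- map(partition_freqs, function(f) f / sum(f))
  structure(
    list(seed = as.integer(seed), template = template,
         partition_freqs = freqs, kappa = kappa, omega = omega,
         branch_lengths = branch_lengths, csb_motifs = csb_motifs,
         cr_repeat = cr_repeat),
    class = "sim_config"
  )
}

default_template <- function() {
  read_feature_table(crepasson_feature_table(), genome_id = "synthetic")
}

# codon sampling distribution whose induced base composition approximates a
# target frequency vector despite the exclusion of stop codons; a few
# fixed-point reweighting passes suffice
codon_probs_for_freq <- function(freq, iters = 8L) {
  stops <- mito_stop_codons()
  codons <- setdiff(names(mito_code()), stops)
  mat <- do.call(rbind, strsplit(codons, "", fixed = TRUE))
  f <- freq
  for (it in seq_len(iters)) {
    w <- f[mat[, 1]] * f[mat[, 2]] * f[mat[, 3]]
    w <- w / sum(w)
    induced <- vapply(BASES, function(b) sum(w * rowSums(mat == b)) / 3,
                      numeric(1))
    f <- f * (freq / induced)
    f <- f / sum(f)
  }
  w <- f[mat[, 1]] * f[mat[, 2]] * f[mat[, 3]]
  setNames(w / sum(w), codons)
}

# sample one codon compatible with a fixed-base pattern (NA = free);
# pool = "sense" (non-stop) or "stop"
sample_codon <- function(pattern, probs, pool = c("sense", "stop")) {
  pool <- match.arg(pool)
  cand <- if (pool == "sense") names(probs) else mito_stop_codons()
  if (!all(is.na(pattern))) {
    keep <- rep(TRUE, length(cand))
    for (p in 1:3) {
      if (!is.na(pattern[p])) {
        keep <- keep & substring(cand, p, p) == pattern[p]
      }
    }
    cand <- cand[keep]
  }
  if (length(cand) == 0L) {
    abort("no codon compatible with junction constraints")
  }
  w <- if (pool == "sense") probs[cand] else rep(1, length(cand))
  sample(cand, 1L, prob = w)
}

# generate one protein-coding sequence of length `size` (sense orientation):
# forced start codon, internal non-stop codons, a complete stop or a 1-2 nt
# remnant, honouring fixed bases (named by sense position)
generate_pcg <- function(size, start_codon, probs, fixed = NULL) {
  ncod <- size %/% 3L
  k <- size %% 3L
  out <- rep(NA_character_, size)
  if (!is.null(fixed)) out[as.integer(names(fixed))] <- fixed
  pat <- function(i) out[(3L * i - 2L):(3L * i)]
  set <- function(i, codon) {
    out[(3L * i - 2L):(3L * i)] <<- seq_chars(codon)
  }
  # start codon
  sc <- seq_chars(start_codon)
  cur <- pat(1L)
  if (any(!is.na(cur) & cur != sc)) abort("start codon conflicts with fixed bases")
  set(1L, start_codon)
  nfull <- if (k == 0L) ncod - 1L else ncod # internal (non-stop) codons
  for (i in seq(2L, length.out = max(0L, nfull - 1L))) {
    set(i, sample_codon(pat(i), probs, "sense"))
  }
  if (k == 0L) {
    set(ncod, sample_codon(pat(ncod), probs, "stop"))
  } else {
    tail_pos <- (3L * ncod + 1L):size
    remnant <- seq_chars(str_sub("TAA", 1L, k))
    cur <- out[tail_pos]
    out[tail_pos] <- ifelse(is.na(cur), remnant, cur)
  }
  chars_seq(out)
}

#' Generate an annotated ancestor mitogenome
#'
#' Builds a circular genome realizing the template's gene order: every PCG
#' has a valid start codon (GTG for COI, ATG otherwise), no internal stops
#' under the vertebrate mitochondrial code, and a complete or incomplete
#' terminal stop as dictated by its length; tRNA/rRNA/spacer residues are
#' drawn iid from the per-partition composition targets; the control region
#' carries the configured conserved blocks in order and, optionally, a
#' tandem repeat. PCG/PCG overlaps in the template (ATP8/ATP6, ND4L/ND4,
#' ND5/ND6) are resolved by fixing the shared junction bases before
#' generation, so both reading frames stay stop-free.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return List: \code{sequence} (a \code{mito_sequence}),
#'   \code{annotation} (with recomputed start/stop codons), and
#'   \code{truth} (implanted CSB and repeat coordinates in CR and genome
#'   coordinates, plus the config).
#' @export
make_ancestor <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  tmpl <- cfg$template %||% default_template()
  glen <- genome_length(tmpl)
  res <- rep(NA_character_, glen)
  pf <- cfg$partition_freqs
  probs <- codon_probs_for_freq(pf$PCG)

  feats <- as_tibble(tmpl)
  truth <- list(csb = NULL, cr_repeat = NULL)

  # junction constraints for PCG/PCG overlaps
  pcg_idx <- which(feats$cls == "PCG")
  for (k in seq_len(nrow(feats) - 1L)) {
    u <- feats[k, ]
    d <- feats[k + 1L, ]
    if (u$cls != "PCG" || d$cls != "PCG" || d$start > u$end) next
    if (u$strand == "H" && d$strand == "H" &&
        u$end - d$start + 1L == 7L && u$size %% 3L == 0L &&
        (d$start - u$start) %% 3L == 2L) {
      # 7 bp in-frame overlap: the downstream ATG sits inside the upstream
      # gene and the upstream stop (pinned to TAG) inside the downstream
      # one; with this geometry neither frame can acquire a stop
      res[d$start:(d$start + 2L)] <- seq_chars("ATG")
      res[(u$end - 2L):u$end] <- seq_chars("TAG")
    } else if (u$strand == "H" && d$strand == "L" &&
               u$end - d$start + 1L == 4L && u$size %% 3L == 0L) {
      # H-strand stop TAA and L-strand stop TAG share the 4 bp junction
      res[d$start] <- "C"
      res[(u$end - 2L):u$end] <- seq_chars("TAA")
    } else {
      abort("unsupported PCG overlap geometry in template")
    }
  }

  for (k in seq_len(nrow(feats))) {
    f <- feats[k, ]
    span <- f$start:f$end
    if (f$cls == "PCG") {
      start_codon <- if (f$gene == "COI") "GTG" else "ATG"
      if (f$strand == "H") {
        fixed_pos <- which(!is.na(res[span]))
        fixed <- setNames(res[span][fixed_pos], fixed_pos)
        gene_seq <- generate_pcg(f$size, start_codon, probs,
                                 fixed = if (length(fixed)) fixed else NULL)
        res[span] <- seq_chars(gene_seq)
      } else {
        # map genome-fixed bases into sense coordinates
        fixed_pos <- which(!is.na(res[span]))
        fixed <- NULL
        if (length(fixed_pos) > 0L) {
          sense_pos <- f$size - fixed_pos + 1L
          fixed <- setNames(
            chartr("ACGT", "TGCA", res[span][fixed_pos]), sense_pos
          )
        }
        gene_seq <- generate_pcg(f$size, start_codon, probs, fixed = fixed)
        res[span] <- seq_chars(revcomp(gene_seq))
      }
    } else if (f$cls == "CR") {
      cr <- generate_cr(f$size, pf$CR, cfg$csb_motifs, cfg$cr_repeat)
      open <- is.na(res[span])
      res[span][open] <- seq_chars(cr$seq)[open]
      truth$csb <- cr$csb |>
        mutate(genome_start = .data$start + f$start - 1L,
               genome_end = .data$end + f$start - 1L)
      if (!is.null(cr$rep)) {
        truth$cr_repeat <- cr$rep |>
          mutate(genome_start = .data$start + f$start - 1L,
                 genome_end = .data$end + f$start - 1L)
      }
    } else {
      freq <- pf[[f$cls]]
      open <- is.na(res[span])
      res[span][open] <- sample(BASES, sum(open), replace = TRUE, prob = freq)
    }
  }
  open <- is.na(res)
  if (any(open)) {
    res[open] <- sample(BASES, sum(open), replace = TRUE,
                        prob = pf$background)
  }

  genome <- mito_sequence(chars_seq(res), id = genome_id(tmpl))
  calls <- call_codons(genome, tmpl)
  feats$start_codon[match(calls$gene, feats$gene)] <- calls$start_codon
  feats$stop_codon[match(calls$gene, feats$gene)] <- calls$stop_codon
  ann <- mito_annotation(feats, genome_id = genome_id(tmpl),
                         genome_length = glen)
  truth$config <- cfg
  list(sequence = genome, annotation = ann, truth = truth)
}

# control region: iid background with CSB motifs implanted in order and an
# optional tandem repeat between the last CSB-free stretch
generate_cr <- function(size, freq, csb_motifs, cr_repeat) {
  s <- sample(BASES, size, replace = TRUE, prob = freq)
  csb <- NULL
  cursor <- max(1L, size %/% 5L)
  if (!is.null(csb_motifs) && length(csb_motifs) > 0L) {
    total <- sum(nchar(csb_motifs))
    gap <- max(5L, (size - cursor - total - 20L) %/% length(csb_motifs))
    rows <- list()
    for (nm in names(csb_motifs)) {
      motif <- csb_motifs[[nm]]
      k <- nchar(motif)
      if (cursor + k - 1L > size) abort("control region too short for CSBs")
      s[cursor:(cursor + k - 1L)] <- seq_chars(motif)
      rows[[nm]] <- tibble(block = nm, start = cursor, end = cursor + k - 1L)
      cursor <- cursor + k + gap
    }
    csb <- bind_rows(rows)
  }
  rep_row <- NULL
  if (!is.null(cr_repeat)) {
    motif <- str_to_upper(cr_repeat$motif)
    p <- nchar(motif)
    span <- as.integer(round(p * cr_repeat$copies))
    unit <- seq_chars(chars_seq(rep(motif, ceiling(span / p))))
    start <- 5L # ahead of the first CSB
    if (start + span - 1L >= (csb$start[1L] %||% size)) {
      abort("control region too short for the configured repeat")
    }
    s[start:(start + span - 1L)] <- unit[seq_len(span)]
    rep_row <- tibble(period = p, copies = round(span / p, 1L),
                      start = start, end = start + span - 1L,
                      motif = motif)
  }
  list(seq = chars_seq(s), csb = csb, rep = rep_row)
}

# --- evolution along branches ------------------------------------------------

# site -> containing PCG rows (precomputed lookup)
pcg_lookup <- function(a) {
  filter(as_tibble(a), .data$cls == "PCG")
}

propose_base <- function(cur, kappa) {
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  if (runif(1L) < kappa / (kappa + 2)) {
    ts[[cur]]
  } else {
    sample(setdiff(BASES, c(cur, ts[[cur]])), 1L)
  }
}

# classify a candidate substitution at genome position `pos` within PCG `f`
# given current residues: returns list(stop = , syn = )
classify_change <- function(res, f, pos, new_base) {
  code <- mito_code()
  if (f$strand == "H") {
    off <- pos - f$start # 0-based sense offset
    base_new <- new_base
  } else {
    off <- f$end - pos
    base_new <- chartr("ACGT", "TGCA", new_base)
  }
  cidx <- off %/% 3L
  ph <- off %% 3L
  sense_start <- cidx * 3L
  idx <- sense_start + 0:2
  gpos <- if (f$strand == "H") f$start + idx else f$end - idx
  cod <- res[gpos]
  if (f$strand == "L") cod <- chartr("ACGT", "TGCA", cod)
  old <- chars_seq(cod)
  cod[ph + 1L] <- base_new
  new <- chars_seq(cod)
  ncod <- f$size %/% 3L
  is_terminal_stop <- (f$size %% 3L == 0L) && (cidx == ncod - 1L)
  if (str_detect(old, "[^ACGT]") || str_detect(new, "[^ACGT]")) {
    return(list(stop = FALSE, syn = TRUE, partial = TRUE))
  }
  if (cidx >= ncod) { # incomplete terminal remnant: sub-codon, neutral
    return(list(stop = FALSE, syn = TRUE, partial = TRUE))
  }
  stops <- mito_stop_codons()
  if (is_terminal_stop) {
    # terminal stop codon must stay a stop
    return(list(stop = !(new %in% stops), syn = TRUE, partial = FALSE))
  }
  if (new %in% stops) return(list(stop = TRUE, syn = NA, partial = FALSE))
  list(stop = FALSE, syn = code[[old]] == code[[new]], partial = FALSE)
}

#' Evolve descendant genomes from an ancestor
#'
#' Per branch, substitution proposals are drawn site-uniformly at rate
#' \code{branch_length} proposals/site under a two-rate process
#' (transitions \code{kappa} times likelier than each transversion).
#' Within protein-coding genes a proposal creating an internal stop is
#' rejected, a nonsynonymous proposal is accepted with probability
#' \code{omega} (per gene), and terminal stop codons must remain stops;
#' all other sites evolve neutrally. Realized per-gene synonymous and
#' nonsynonymous counts are recorded as truth.
#'
#' @param ancestor output of \code{\link{make_ancestor}}.
#' @param cfg the same \code{\link{sim_config}} (its \code{branch_lengths},
#'   \code{kappa}, \code{omega} and \code{seed} are used).
#' @return List with \code{genomes} (named list of \code{mito_sequence}),
#'   \code{annotation} (shared coordinates), and \code{truth}: per-branch
#'   tibble of proposed/accepted/syn/nonsyn counts.
#' @export
evolve_genomes <- function(ancestor, cfg = ancestor$truth$config) {
  set.seed(cfg$seed + 1L)
  a <- ancestor$annotation
  pcg <- pcg_lookup(a)
  anc <- seq_chars(ancestor$sequence$residues)
  glen <- length(anc)
  omega_of <- function(gene) {
    if (length(cfg$omega) == 1L && is.null(names(cfg$omega))) {
      cfg$omega
    } else {
      cfg$omega[[gene]] %||% 0.05
    }
  }
  genomes <- list()
  truth <- list()
  for (b in names(cfg$branch_lengths)) {
    res <- anc
    n_prop <- rpois(1L, cfg$branch_lengths[[b]] * glen)
    acc <- 0L
    syn <- 0L
    nonsyn <- 0L
    for (e in seq_len(n_prop)) {
      pos <- sample.int(glen, 1L)
      cur <- res[pos]
      if (!cur %in% BASES) next
      nb <- propose_base(cur, cfg$kappa)
      hits <- pcg[pcg$start <= pos & pcg$end >= pos, ]
      if (nrow(hits) == 0L) {
        res[pos] <- nb
        acc <- acc + 1L
        next
      }
      cls <- map(seq_len(nrow(hits)),
                 function(i) classify_change(res, hits[i, ], pos, nb))
      if (any(map_lgl(cls, "stop"))) next
      nonsyn_any <- any(!map_lgl(cls, "syn"))
      if (nonsyn_any) {
        p_acc <- prod(vapply(which(!map_lgl(cls, "syn")),
                             function(i) omega_of(hits$gene[i]), numeric(1)))
        if (runif(1L) >= p_acc) next
        nonsyn <- nonsyn + 1L
      } else if (!any(map_lgl(cls, "partial"))) {
        syn <- syn + 1L
      }
      res[pos] <- nb
      acc <- acc + 1L
    }
    genomes[[b]] <- mito_sequence(chars_seq(res), id = b)
    truth[[b]] <- tibble(branch = b, proposed = n_prop, accepted = acc,
                         syn = syn, nonsyn = nonsyn)
  }
  list(genomes = genomes, annotation = a, truth = bind_rows(truth))
}

#' Simulate a K80 sequence pair at an exact expected distance
#'
#' Draws an iid uniform ancestor and a partner whose per-site difference
#' categories follow the closed-form K80 transition/transversion
#' probabilities at distance \code{d} and ratio \code{kappa}, so the
#' estimated K2P distance is a direct parameter-recovery check.
#'
#' @param L sites.
#' @param d expected substitutions/site.
#' @param kappa transition/transversion rate ratio.
#' @param seed integer seed.
#' @return Named character vector of two sequences \code{x}, \code{y}.
#' @export
simulate_k80_pair <- function(L, d, kappa = 4, seed = 1L) {
  set.seed(seed)
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * d)
  e2 <- exp(-2 * (alpha + beta) * d)
  P <- 0.25 + 0.25 * e1 - 0.5 * e2
  Q <- 0.5 - 0.5 * e1
  x <- sample(BASES, L, replace = TRUE)
  cat3 <- sample(c("same", "ts", "tv"), L, replace = TRUE,
                 prob = c(1 - P - Q, P, Q))
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  y <- x
  i <- cat3 == "ts"
  y[i] <- ts[x[i]]
  i <- which(cat3 == "tv")
  for (k in i) y[k] <- sample(setdiff(BASES, c(x[k], ts[[x[k]]])), 1L)
  c(x = chars_seq(x), y = chars_seq(y))
}

#' Simulate a diverged codon-sequence pair with known omega
#'
#' An ancestor of uniform random sense codons is evolved into two
#' descendants under the proposal/acceptance process of
#' \code{\link{evolve_genomes}} restricted to a single reading frame:
#' transitions \code{kappa}-fold favoured, stop-creating changes rejected,
#' nonsynonymous changes accepted with probability \code{omega}.
#'
#' @param n_codons codons per sequence.
#' @param omega nonsynonymous acceptance probability.
#' @param kappa transition/transversion ratio.
#' @param proposals_per_site proposal rate per nucleotide site per lineage.
#' @param seed integer seed.
#' @return Named character vector \code{x}, \code{y} of in-frame sequences.
#' @export
simulate_codon_pair <- function(n_codons, omega = 0.05, kappa = 4,
                                proposals_per_site = 0.3, seed = 1L) {
  set.seed(seed)
  code <- mito_code()
  stops <- mito_stop_codons()
  sense <- setdiff(names(code), stops)
  anc <- sample(sense, n_codons, replace = TRUE)
  evolve_cds <- function(cods) {
    s <- seq_chars(chars_seq(cods))
    L <- length(s)
    n_prop <- rpois(1L, proposals_per_site * L)
    for (e in seq_len(n_prop)) {
      pos <- sample.int(L, 1L)
      nb <- propose_base(s[pos], kappa)
      ci <- (pos - 1L) %/% 3L
      idx <- ci * 3L + 1:3
      old <- chars_seq(s[idx])
      cod <- s[idx]
      cod[(pos - 1L) %% 3L + 1L] <- nb
      new <- chars_seq(cod)
      if (new %in% stops) next
      if (code[[old]] != code[[new]] && runif(1L) >= omega) next
      s[pos] <- nb
    }
    chars_seq(s)
  }
  c(x = evolve_cds(anc), y = evolve_cds(anc))
}
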