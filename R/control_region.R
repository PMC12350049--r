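#' Majority-rule consensus for conserved sequence blocks
#'
#' Builds a per-block consensus over aligned control regions: for each seed
#' window (alignment coordinates) the column-wise majority base (ties broken
#' alphabetically; gaps/ambiguities ignored unless a column is all-gap) and
#' per-row mismatch counts against that consensus.
#'
#' @param aln named character vector: aligned control regions (>= 3 rows).
#' @param seed_windows named list of \code{c(start, end)} alignment windows,
#'   one per block, e.g. \code{list("CSB-D" = c(101, 118), ...)}.
#' @return Tibble: \code{block}, \code{start}, \code{end}, \code{consensus},
#'   and a \code{mismatches} list-column of named per-row mismatch counts.
#' @export
build_csb_consensus <- function(aln, seed_windows) {
  m <- aln_matrix(aln)
  if (nrow(m) < 3L) abort("need at least three aligned control regions")
  L <- ncol(m)
  rows <- imap(seed_windows, function(w, block) {
    if (w[1] < 1L || w[2] > L || w[1] > w[2]) {
      abort(paste0("seed window outside alignment: ", block))
    }
    sub <- m[, w[1]:w[2], drop = FALSE]
    cons <- apply(sub, 2L, function(col) {
      col <- col[col %in% BASES]
      if (length(col) == 0L) return("-")
      tt <- table(col)
      names(tt)[which.max(tt)] # which.max takes the first = alphabetical tie
    })
    consensus <- chars_seq(cons)
    mism <- apply(sub, 1L, function(row) {
      sum(row != cons & row %in% BASES & cons %in% BASES)
    })
    tibble(block = block, start = w[1], end = w[2],
           consensus = consensus, mismatches = list(mism))
  })
  bind_rows(rows)
}

#' Scan a control region for conserved sequence blocks
#'
#' Finds the best ungapped match of each block consensus in a single control
#' region under Hamming distance. Blocks whose best match exceeds
#' \code{max_mismatch} are reported as absent (\code{found = FALSE}). Hits
#' are returned in control-region order.
#'
#' @param cr_seq control-region DNA string (CR coordinates start at 1).
#' @param consensus named character vector of block consensus motifs, e.g.
#'   \code{c("CSB-D" = "...", "CSB-1" = "...")}, or the output tibble of
#'   \code{\link{build_csb_consensus}}.
#' @param max_mismatch maximum Hamming mismatches for a reported hit.
#' @return Tibble: \code{block}, \code{found}, \code{start}, \code{end},
#'   \code{match}, \code{mismatches}.
#' @export
scan_csb <- function(cr_seq, consensus, max_mismatch = 4L) {
  if (is.data.frame(consensus)) {
    consensus <- setNames(consensus$consensus, consensus$block)
  }
  s <- seq_chars(str_to_upper(cr_seq))
  n <- length(s)
  rows <- imap(consensus, function(motif, block) {
    mch <- seq_chars(str_to_upper(motif))
    k <- length(mch)
    if (k > n) {
      return(tibble(block = block, found = FALSE, start = NA_integer_,
                    end = NA_integer_, match = NA_character_,
                    mismatches = NA_integer_))
    }
    # Hamming profile of the motif against every window
    mm <- integer(n - k + 1L)
    for (p in seq_len(k)) {
      mm <- mm + (s[p:(n - k + p)] != mch[p])
    }
    best <- which.min(mm)
    if (mm[best] > max_mismatch) {
      tibble(block = block, found = FALSE, start = NA_integer_,
             end = NA_integer_, match = NA_character_,
             mismatches = as.integer(mm[best]))
    } else {
      tibble(block = block, found = TRUE, start = best,
             end = best + k - 1L,
             match = chars_seq(s[best:(best + k - 1L)]),
             mismatches = as.integer(mm[best]))
    }
  })
  bind_rows(rows) |> arrange(is.na(.data$start), .data$start)
}

#' Default synthetic CSB seed motifs
#'
#' Synthetic consensus motifs for the four conserved sequence blocks at the
#' block lengths seen in cyprinid control regions (CSB-D 18 bp, CSB-1 21 bp,
#' CSB-2 18 bp, CSB-3 20 bp). These are configuration data for simulations
#' and examples, \emph{not} claims about the true consensus of any species
#' (which the package derives from alignments via
#' \code{\link{build_csb_consensus}}).
#'
#' @return Named character vector of four motifs in CR order.
#' @export
csb_seed_motifs <- function() {
  c(
    "CSB-D" = "TATCTGGTTCCTACTTCA",      # 18 bp
    "CSB-1" = "TTGGTAGGACATATTATGCAT",   # 21 bp
    "CSB-2" = "CAAACCCCCCTACCCCCT",      # 18 bp
    "CSB-3" = "TGCAAACCCCGAAACCAGGA"     # 20 bp
  )
}

# maximal-scoring segments of a logical match profile under match/mismatch
# scoring (Kadane-style sweep, resetting at negative prefixes)
scoring_segments <- function(match_vec, match_score, mismatch_score) {
  segs <- list()
  score <- 0
  start <- 1L
  best <- 0
  best_i <- 0L
  best_j <- 0L
  for (i in seq_along(match_vec)) {
    inc <- if (match_vec[i]) match_score else mismatch_score
    if (score <= 0) {
      score <- 0
      start <- i
    }
    score <- score + inc
    if (score > best) {
      best <- score
      best_i <- start
      best_j <- i
    }
    if (score <= 0 && best > 0) {
      segs[[length(segs) + 1L]] <- c(start = best_i, end = best_j,
                                     score = best)
      best <- 0
    }
  }
  if (best > 0) {
    segs[[length(segs) + 1L]] <- c(start = best_i, end = best_j, score = best)
  }
  segs
}

#' Find tandem repeats in a sequence
#'
#' A deterministic seed-and-verify tandem-repeat detector consuming the same
#' outputs a Tandem Repeats Finder run would (period, copy number, motif):
#' for each candidate period \code{p} the lag-\code{p} self-match profile is
#' scanned for maximal-scoring segments (match +2, mismatch -7 by default,
#' the TRF weights; indels are not modelled), a segment of profile span
#' \code{[i, j]} corresponding to a repeat region \code{[i, j + p]}. Copy
#' number is span/period to 1 decimal place; overlapping reports across
#' periods are merged keeping the higher score (ties to the shorter period).
#' The consensus motif is the column-majority over the repeat's periodic
#' phases.
#'
#' @param seq DNA string.
#' @param max_period maximum period to test, bp.
#' @param min_copies minimum (fractional) copy number to report.
#' @param min_score minimum segment score.
#' @param match_score,mismatch_score scoring weights.
#' @return Tibble of class \code{mito_repeats}: \code{period},
#'   \code{copies}, \code{start}, \code{end}, \code{consensus},
#'   \code{pct_match} (identity between period-separated positions),
#'   \code{score}. Empty (zero rows) when nothing qualifies.
#' @export
find_tandem_repeats <- function(seq, max_period = 50L, min_copies = 1.5,
                                min_score = 30, match_score = 2,
                                mismatch_score = -7) {
  s <- seq_chars(str_to_upper(seq))
  n <- length(s)
  if (n < 2L) abort("sequence too short")
  cand <- list()
  for (p in seq_len(min(max_period, n - 1L))) {
    mv <- s[seq_len(n - p)] == s[(p + 1L):n]
    for (seg in scoring_segments(mv, match_score, mismatch_score)) {
      start <- unname(seg["start"])
      end_prof <- unname(seg["end"])
      end <- end_prof + p
      span <- end - start + 1L
      copies <- round(span / p, 1L)
      if (copies < min_copies) next
      if (seg["score"] < min_score) next
      matches <- sum(mv[start:end_prof])
      cand[[length(cand) + 1L]] <- tibble(
        period = p, copies = copies, start = start, end = end,
        pct_match = 100 * matches / (end_prof - start + 1L),
        score = unname(seg["score"])
      )
    }
  }
  if (length(cand) == 0L) {
    return(structure(
      tibble(period = integer(), copies = numeric(), start = integer(),
             end = integer(), consensus = character(),
             pct_match = numeric(), score = numeric()),
      class = c("mito_repeats", class(tibble()))
    ))
  }
  out <- bind_rows(cand) |> arrange(dplyr::desc(.data$score), .data$period)
  # merge overlapping reports, keeping the higher score
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      for (j in (i + 1L):nrow(out)) {
        if (keep[j] &&
            out$start[j] <= out$end[i] && out$end[j] >= out$start[i]) {
          keep[j] <- FALSE
        }
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out$consensus <- map_chr(seq_len(nrow(out)), function(i) {
    repeat_consensus(s, out$start[i], out$end[i], out$period[i])
  })
  out <- select(out, "period", "copies", "start", "end", "consensus",
                "pct_match", "score") |>
    arrange(.data$start)
  structure(out, class = c("mito_repeats", class(tibble())))
}

# column-majority consensus over the periodic phases of a repeat region
repeat_consensus <- function(s, start, end, period) {
  region <- s[start:end]
  cons <- vapply(seq_len(period), function(ph) {
    col <- region[seq(ph, length(region), by = period)]
    col <- col[col %in% BASES]
    if (length(col) == 0L) return("N")
    tt <- table(col)
    names(tt)[which.max(tt)]
  }, character(1))
  chars_seq(cons)
}
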