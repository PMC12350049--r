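PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

# character matrix view of an alignment given as named character vector
aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L) abort("alignment rows differ in length")
  m <- do.call(rbind, strsplit(str_to_upper(aln), "", fixed = TRUE))
  rownames(m) <- names(aln) %||% paste0("seq", seq_along(aln))
  m
}

#' Transition/transversion tally for one sequence pair
#'
#' Compares two equal-length (gapped) sequences under complete pairwise
#' deletion: sites with a gap or ambiguity in either row are excluded.
#' Purine-purine and pyrimidine-pyrimidine mismatches are transitions
#' (count \code{s}), all other mismatches transversions (count \code{v});
#' \code{P = s/sites} and \code{Q = v/sites} are the proportions entering
#' the distance formulas.
#'
#' @param x,y equal-length DNA strings (gaps \code{-} and \code{N} allowed).
#' @return One-row tibble: \code{sites}, \code{s}, \code{v}, \code{P},
#'   \code{Q}, \code{p_distance}.
#' @export
pair_diffs <- function(x, y) {
  cx <- if (length(x) == 1L) seq_chars(str_to_upper(x)) else x
  cy <- if (length(y) == 1L) seq_chars(str_to_upper(y)) else y
  if (length(cx) != length(cy)) abort("sequences differ in length")
  ok <- cx %in% BASES & cy %in% BASES
  cx <- cx[ok]
  cy <- cy[ok]
  sites <- length(cx)
  if (sites == 0L) abort("zero comparable sites")
  diff <- cx != cy
  ts <- diff & ((cx %in% PURINES) == (cy %in% PURINES))
  s <- sum(ts)
  v <- sum(diff) - s
  tibble(
    sites = sites, s = s, v = v,
    P = s / sites, Q = v / sites,
    p_distance = (s + v) / sites
  )
}

#' Kimura two-parameter distance
#'
#' \deqn{d = -\tfrac12 \ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big)}
#' with \code{P} and \code{Q} the transition and transversion proportions.
#' Saturated pairs (non-positive log argument) yield \code{NA} with a
#' warning rather than an error.
#'
#' @param P transition proportion, or a \code{\link{pair_diffs}} row (then
#'   \code{Q} is taken from it).
#' @param Q transversion proportion.
#' @return Distance in substitutions/site (vectorized).
#' @export
k2p_distance <- function(P, Q = NULL) {
  if (is.data.frame(P)) {
    Q <- P$Q
    P <- P$P
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  bad <- w1 <= 0 | w2 <= 0
  if (any(bad)) warn("saturated pair(s): K2P distance undefined, returning NA")
  d <- rep(NA_real_, length(P))
  d[!bad] <- -0.5 * log(w1[!bad] * sqrt(w2[!bad]))
  d
}

#' F84 distance
#'
#' Felsenstein's 1984 distance allowing unequal base frequencies and a
#' transition/transversion bias, the divergence axis of saturation plots.
#' With frequencies \eqn{\pi_A..\pi_T}, \eqn{\pi_R = \pi_A+\pi_G},
#' \eqn{\pi_Y = \pi_C+\pi_T}, and
#' \eqn{A = \pi_A\pi_G/\pi_R + \pi_C\pi_T/\pi_Y},
#' \eqn{B = \pi_A\pi_G + \pi_C\pi_T}, \eqn{C = \pi_R\pi_Y}:
#' \deqn{d = -2A \ln\!\big(1 - P/(2A) - (A - B)Q/(2AC)\big)
#'        + 2(A - B - C)\ln\!\big(1 - Q/(2C)\big).}
#'
#' @param P,Q transition/transversion proportions, or a
#'   \code{\link{pair_diffs}} row as \code{P}.
#' @param base_freq numeric length-4 (A, C, G, T order), need not be
#'   normalized. Defaults are estimated from the pooled pair by the callers.
#' @return Distance in substitutions/site; \code{NA} when a log argument is
#'   non-positive (saturation).
#' @export
f84_distance <- function(P, Q = NULL, base_freq = rep(0.25, 4)) {
  if (is.data.frame(P)) {
    Q <- P$Q
    P <- P$P
  }
  f <- base_freq / sum(base_freq)
  pA <- f[1]; pC <- f[2]; pG <- f[3]; pT <- f[4]
  pR <- pA + pG
  pY <- pC + pT
  A <- pA * pG / pR + pC * pT / pY
  B <- pA * pG + pC * pT
  C <- pR * pY
  t1 <- 1 - P / (2 * A) - (A - B) * Q / (2 * A * C)
  t2 <- 1 - Q / (2 * C)
  bad <- t1 <= 0 | t2 <= 0
  if (any(bad)) warn("saturated pair(s): F84 distance undefined, returning NA")
  d <- rep(NA_real_, length(P))
  d[!bad] <- -2 * A * log(t1[!bad]) + 2 * (A - B - C) * log(t2[!bad])
  d
}

# pooled unambiguous base frequencies of a set of rows (A, C, G, T order)
pooled_base_freq <- function(m) {
  ch <- as.vector(m)
  cnt <- vapply(BASES, function(b) sum(ch == b), numeric(1))
  cnt / sum(cnt)
}

#' Pairwise distance matrix
#'
#' Model distances between all rows of an alignment, complete pairwise
#' deletion throughout. F84 base frequencies are estimated from each pooled
#' pair. Saturated pairs give \code{NA} entries; summary means are computed
#' over defined entries with the count reported.
#'
#' @param aln named character vector of equal-length gapped sequences.
#' @param model one of \code{"K2P"}, \code{"F84"}, \code{"p"}.
#' @return A symmetric matrix of class \code{mito_dist} with a \code{model}
#'   attribute; see \code{\link{tidy.mito_dist}} and
#'   \code{\link{group_distance_means}}.
#' @export
distance_matrix <- function(aln, model = c("K2P", "F84", "p")) {
  model <- match.arg(model)
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) abort("need at least two sequences")
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pd <- pair_diffs(m[i, ], m[j, ])
      d <- switch(model,
        K2P = suppressWarnings(k2p_distance(pd)),
        F84 = suppressWarnings(f84_distance(
          pd, base_freq = pooled_base_freq(m[c(i, j), , drop = FALSE])
        )),
        p = pd$p_distance
      )
      D[i, j] <- D[j, i] <- d
    }
  }
  if (anyNA(D)) warn("saturated pair(s) produced NA distances")
  structure(D, model = model, class = c("mito_dist", "matrix", "array"))
}

#' @export
print.mito_dist <- function(x, ...) {
  cat("<mito_dist> ", attr(x, "model", exact = TRUE), " distances, ",
      nrow(x), " sequences\n", sep = "")
  print(round(unclass(x), 4), ...)
  invisible(x)
}

#' Tidy a distance matrix into pairs
#'
#' @param x a \code{mito_dist}.
#' @param ... unused.
#' @return Tibble \code{label_i}, \code{label_j}, \code{distance} over the
#'   lower triangle.
#' @method tidy mito_dist
#' @export
tidy.mito_dist <- function(x, ...) {
  idx <- which(lower.tri(x), arr.ind = TRUE)
  tibble(
    label_i = rownames(x)[idx[, "col"]],
    label_j = rownames(x)[idx[, "row"]],
    distance = x[idx]
  )
}

#' Within/between-group distance means
#'
#' @param D a \code{mito_dist}.
#' @param groups named character vector mapping sequence label to group.
#' @return Tibble \code{group_i}, \code{group_j}, \code{type}
#'   (within/between), \code{mean_distance}, \code{n_pairs},
#'   \code{n_defined}.
#' @export
group_distance_means <- function(D, groups) {
  labs <- rownames(D)
  miss <- setdiff(labs, names(groups))
  if (length(miss) > 0L) {
    abort(paste0("labels missing from groups: ", paste(miss, collapse = ", ")))
  }
  tidy.mito_dist(D) |>
    mutate(
      gi = pmin(groups[.data$label_i], groups[.data$label_j]),
      gj = pmax(groups[.data$label_i], groups[.data$label_j])
    ) |>
    group_by(group_i = .data$gi, group_j = .data$gj) |>
    summarise(
      type = if_else(first(.data$gi) == first(.data$gj),
                     "within", "between"),
      mean_distance = mean(.data$distance, na.rm = TRUE),
      n_pairs = n(),
      n_defined = sum(!is.na(.data$distance)),
      .groups = "drop"
    )
}

#' Overall mean pairwise distance
#'
#' @param D a \code{mito_dist}.
#' @return One-row tibble: \code{mean_distance}, \code{min}, \code{max},
#'   \code{n_pairs}, \code{n_defined}.
#' @export
overall_distance_mean <- function(D) {
  d <- tidy.mito_dist(D)$distance
  tibble(
    mean_distance = mean(d, na.rm = TRUE),
    min = min(d, na.rm = TRUE),
    max = max(d, na.rm = TRUE),
    n_pairs = length(d),
    n_defined = sum(!is.na(d))
  )
}

#' Sliding-window nucleotide diversity
#'
#' Profiles nucleotide diversity along an alignment: per window,
#' \eqn{\pi} is the mean over all sequence pairs of (pairwise differences /
#' pairwise compared sites), sites with gaps or ambiguities excluded
#' pairwise. Defaults follow the common DnaSP profile settings: 200 bp
#' windows stepped by 25 bp. A window longer than the alignment yields a
#' single truncated window, flagged in the output.
#'
#' @param aln named character vector of equal-length gapped sequences
#'   (at least 2).
#' @param window window length, bp (alignment columns).
#' @param step step between window starts, bp.
#' @param corrected apply the \code{n/(n-1)} sample-size correction.
#' @return A tibble of class \code{mito_pi_profile}: \code{start},
#'   \code{mid}, \code{end}, \code{pi}, \code{diffs}, \code{sites}
#'   (pooled over pairs), \code{truncated}.
#' @export
sliding_pi <- function(aln, window = 200L, step = 25L, corrected = FALSE) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) abort("need at least two sequences")
  L <- ncol(m)
  starts <- if (window >= L) 1L else seq(1L, L - window + 1L, by = step)
  pairs <- utils::combn(n, 2L)
  corr <- if (corrected) n / (n - 1) else 1
  rows <- map(starts, function(st) {
    en <- min(st + window - 1L, L)
    sub <- m[, st:en, drop = FALSE]
    ratios <- numeric(ncol(pairs))
    dtot <- 0L
    stot <- 0L
    for (k in seq_len(ncol(pairs))) {
      a <- sub[pairs[1L, k], ]
      b <- sub[pairs[2L, k], ]
      ok <- a %in% BASES & b %in% BASES
      sites <- sum(ok)
      diffs <- sum(a[ok] != b[ok])
      ratios[k] <- if (sites > 0L) diffs / sites else NA_real_
      dtot <- dtot + diffs
      stot <- stot + sites
    }
    tibble(
      start = st, mid = (st + en) / 2, end = en,
      pi = corr * mean(ratios, na.rm = TRUE),
      diffs = dtot, sites = stot,
      truncated = (en - st + 1L) < window
    )
  })
  structure(
    bind_rows(rows),
    window = window, step = step, corrected = corrected,
    class = c("mito_pi_profile", class(tibble()))
  )
}

#' Whole-alignment nucleotide diversity
#'
#' @inheritParams sliding_pi
#' @return Single numeric \eqn{\pi}.
#' @export
nucleotide_diversity <- function(aln, corrected = FALSE) {
  prof <- sliding_pi(aln, window = max(nchar(aln)), step = 1L,
                     corrected = corrected)
  prof$pi[1L]
}

#' Saturation profile (transitions/transversions vs F84 distance)
#'
#' Per sequence pair: transition and transversion proportions against the
#' F84 distance, the standard visual check that divergence has not
#' saturated.
#'
#' @param aln named character vector of equal-length gapped sequences.
#' @return A tibble of class \code{mito_saturation}: \code{label_i},
#'   \code{label_j}, \code{P}, \code{Q}, \code{f84}.
#' @export
saturation_profile <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) abort("need at least two sequences")
  pairs <- utils::combn(n, 2L)
  rows <- map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]
    j <- pairs[2L, k]
    pd <- pair_diffs(m[i, ], m[j, ])
    tibble(
      label_i = rownames(m)[i], label_j = rownames(m)[j],
      P = pd$P, Q = pd$Q,
      f84 = suppressWarnings(
        f84_distance(pd, base_freq = pooled_base_freq(m[c(i, j), ,
                                                        drop = FALSE]))
      )
    )
  })
  structure(bind_rows(rows),
            class = c("mito_saturation", class(tibble())))
}
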