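#' Neighbor joining from a distance matrix
#'
#' The standard Saitou-Nei/Studier-Keppler agglomeration: at each step the
#' pair minimizing \eqn{Q_{ij} = (r-2)d_{ij} - R_i - R_j} is joined, branch
#' lengths solved from the three-point equations, and the matrix reduced.
#' Negative branch lengths are clamped to 0 and the clamped deficit recorded
#' in the returned tree's \code{clamped} attribute. Implemented here because
#' the agglomeration is the package's tree-building primitive; \pkg{ape}'s
#' \code{nj} serves as the independent cross-check in the test suite.
#'
#' @param D a \code{mito_dist} or any symmetric numeric matrix with
#'   dimnames; at least 3 labels, no missing entries.
#' @return An unrooted \code{\link[ape]{phylo}} tree with branch lengths.
#' @export
neighbor_joining <- function(D) {
  D <- unclass(D)
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  n <- nrow(D)
  if (n < 3L) abort("need at least three labels")
  if (anyNA(D)) {
    idx <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    abort(paste0(
      "missing distances for pairs: ",
      paste(paste(rownames(D)[idx[, 1]], colnames(D)[idx[, 2]], sep = "/"),
            collapse = ", ")
    ))
  }

  labels <- rownames(D)
  n_tip <- n
  # nodes: tips 1..n_tip, internal nodes numbered upward from n_tip + 1
  active <- seq_len(n_tip)            # node ids of the active rows of D
  next_node <- 2L * n_tip - 2L        # ape convention: root gets n_tip + 1
  edges <- matrix(integer(0), 0L, 2L)
  lens <- numeric(0)
  clamped <- 0

  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    deficit <- min(len, 0)
    clamped <<- clamped + abs(deficit)
    lens <<- c(lens, max(len, 0))
  }

  while (length(active) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    k <- which.min(Q)
    i <- (k - 1L) %% r + 1L
    j <- (k - 1L) %/% r + 1L
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    node <- next_node
    next_node <- next_node - 1L
    add_edge(node, active[i], li)
    add_edge(node, active[j], lj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    active <- c(active[keep], node)
    rownames(D) <- colnames(D) <- as.character(active)
  }

  # final three-point resolution at the root (node n_tip + 1)
  root <- n_tip + 1L
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  add_edge(root, active[1], l1)
  add_edge(root, active[2], l2)
  add_edge(root, active[3], l3)

  tr <- list(
    edge = edges,
    edge.length = lens,
    tip.label = labels,
    Nnode = n_tip - 2L
  )
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "clamped") <- clamped
  tr
}

# smallest descendant tip label under each node, for deterministic output
smallest_tip <- function(tree, node, env) {
  key <- as.character(node)
  if (!is.null(env[[key]])) return(env[[key]])
  n_tip <- length(tree$tip.label)
  val <- if (node <= n_tip) {
    tree$tip.label[node]
  } else {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    min(vapply(kids, smallest_tip, character(1), tree = tree, env = env))
  }
  env[[key]] <- val
  val
}

#' Write a tree as newick text
#'
#' Deterministic newick serialization: children ordered alphabetically by
#' their smallest descendant tip label, branch lengths at 6 decimal places,
#' terminated by \code{;}.
#'
#' @param tree a \code{phylo} tree (as from \code{\link{neighbor_joining}}).
#' @param path optional file to write to.
#' @param digits decimal places for branch lengths.
#' @return The newick string (invisibly when \code{path} is given).
#' @export
write_newick <- function(tree, path = NULL, digits = 6L) {
  n_tip <- length(tree$tip.label)
  env <- new.env(parent = emptyenv())
  fmt <- function(x) formatC(x, format = "f", digits = digits)
  render <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    idx <- which(tree$edge[, 1] == node)
    kids <- tree$edge[idx, 2]
    ord <- order(vapply(kids, smallest_tip, character(1),
                        tree = tree, env = env))
    parts <- vapply(seq_along(kids)[ord], function(k) {
      paste0(render(kids[k]), ":", fmt(tree$edge.length[idx[k]]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- n_tip + 1L
  out <- paste0(render(root), ";")
  if (!is.null(path)) {
    readr::write_lines(out, path)
    return(invisible(out))
  }
  out
}

#' Patristic (path) distances of a tree
#'
#' Tip-to-tip path lengths; on an additive input matrix the neighbor-joining
#' tree reproduces the input distances exactly.
#'
#' @param tree a \code{phylo}.
#' @return Symmetric matrix of path lengths.
#' @export
tree_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}

#' Site-resampling bootstrap support for the NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the distance
#' matrix and NJ tree per replicate, and reports the frequency of each
#' bipartition of the reference tree.
#'
#' @param aln named character vector of equal-length gapped sequences.
#' @param model distance model passed to \code{\link{distance_matrix}}.
#' @param reps bootstrap replicates.
#' @param seed integer seed controlling resampling.
#' @return List with \code{tree} (reference NJ tree) and \code{support}
#'   (numeric vector, one value per internal node, proportion in [0, 1]).
#' @export
nj_bootstrap <- function(aln, model = "K2P", reps = 100L, seed = 1L) {
  m <- aln_matrix(aln)
  ref <- neighbor_joining(distance_matrix(aln, model = model))
  set.seed(seed)
  boot <- vector("list", reps)
  for (b in seq_len(reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    res <- m[, cols, drop = FALSE]
    rows <- setNames(apply(res, 1L, paste, collapse = ""), rownames(m))
    boot[[b]] <- neighbor_joining(distance_matrix(rows, model = model))
  }
  counts <- ape::prop.clades(ref, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  list(tree = ref, support = counts / reps)
}
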