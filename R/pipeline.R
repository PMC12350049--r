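#' End-to-end characterization of annotated mitogenomes
#'
#' Runs the whole single-genome report surface for one or more annotated
#' mitogenomes: architecture summary (partition totals, spacer/overlap
#' ledger), Table-style composition per partition, codon usage and RSCU,
#' recomputed start/stop codon calls, and control-region features (CSB scan
#' against the supplied consensus set and tandem-repeat search). All outputs
#' are deterministic tibbles; per-genome failures are isolated and collected
#' in \code{errors}.
#'
#' @param genomes named list of \code{mito_sequence} objects; entries may be
#'   \code{NULL} when only the annotation is available (sequence-dependent
#'   tables are skipped for those genomes).
#' @param annotations named list of \code{mito_annotation}s (same names).
#' @param csb_consensus named motif vector for \code{\link{scan_csb}}, or
#'   \code{NULL} to skip the CSB scan.
#' @param max_mismatch CSB mismatch allowance.
#' @param repeat_args list of arguments for
#'   \code{\link{find_tandem_repeats}}.
#' @param family_mode RSCU family convention, see \code{\link{count_codons}}.
#' @return List of tibbles: \code{architecture}, \code{ledger},
#'   \code{partitions}, \code{composition}, \code{codon_calls},
#'   \code{codon_usage}, \code{amino_acids}, \code{csb}, \code{repeats},
#'   \code{errors}.
#' @export
mito_characterize <- function(genomes, annotations,
                              csb_consensus = NULL,
                              max_mismatch = 4L,
                              repeat_args = list(),
                              family_mode = "report") {
  if (length(annotations) == 0L) abort("no input genomes")
  ids <- names(annotations) %||% paste0("g", seq_along(annotations))
  out <- list(architecture = list(), ledger = list(), partitions = list(),
              composition = list(), codon_calls = list(),
              codon_usage = list(), amino_acids = list(), csb = list(),
              repeats = list(), errors = list())
  for (i in seq_along(annotations)) {
    id <- ids[i]
    a <- annotations[[i]]
    g <- genomes[[id]] %||% genomes[[i]]
    step <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        out$errors[[length(out$errors) + 1L]] <<-
          tibble(genome_id = id, step = name, message = conditionMessage(e))
        NULL
      })
    }
    out$architecture[[id]] <- step("architecture", {
      mutate(architecture_summary(a), genome_id = id)
    })
    out$ledger[[id]] <- step("ledger", {
      mutate(as_tibble(build_ledger(a)), genome_id = id, .before = 1L)
    })
    out$partitions[[id]] <- step("partitions", {
      mutate(partition_totals(a), genome_id = id, .before = 1L)
    })
    if (!is.null(g)) {
      out$composition[[id]] <- step("composition", summarize_partitions(g, a))
      out$codon_calls[[id]] <- step("codon_calls", {
        mutate(call_codons(g, a), genome_id = id, .before = 1L)
      })
      tab <- step("codon_usage",
                  count_codons(g, a, family_mode = family_mode))
      if (!is.null(tab)) {
        out$codon_usage[[id]] <-
          mutate(as_tibble(tab), genome_id = id, .before = 1L)
        out$amino_acids[[id]] <-
          mutate(amino_acid_profile(tab), genome_id = id, .before = 1L)
      }
      cr_row <- filter(as_tibble(a), .data$cls == "CR")
      if (nrow(cr_row) == 1L) {
        cr_seq <- unname(extract_gene_seq(g, cr_row))
        if (!is.null(csb_consensus)) {
          out$csb[[id]] <- step("csb", {
            mutate(scan_csb(cr_seq, csb_consensus, max_mismatch),
                   genome_id = id, .before = 1L)
          })
        }
        out$repeats[[id]] <- step("repeats", {
          rep_tab <- do.call(find_tandem_repeats,
                             c(list(cr_seq), repeat_args))
          if (nrow(rep_tab) > 0L) {
            mutate(as_tibble(rep_tab), genome_id = id, .before = 1L)
          } else {
            NULL
          }
        })
      }
    }
  }
  lapply(out, bind_rows)
}

#' Compare aligned sequences: distances, tree, diversity profile
#'
#' The alignment-level report surface: model distance matrix with overall
#' and optional within/between-group means, neighbor-joining tree with
#' newick text, sliding-window nucleotide diversity, and the saturation
#' profile.
#'
#' @param aln named character vector of equal-length gapped sequences, or a
#'   path to an aligned FASTA file.
#' @param groups optional named character vector label -> group.
#' @param model distance model (\code{"K2P"}, \code{"F84"}, \code{"p"}).
#' @param window,step sliding-window settings for \code{\link{sliding_pi}}.
#' @return List: \code{distances} (\code{mito_dist}), \code{overall}
#'   (tibble), \code{group_means} (tibble or NULL), \code{tree}
#'   (\code{phylo} or NULL when < 3 sequences), \code{newick},
#'   \code{pi_profile}, \code{saturation}.
#' @export
mito_compare <- function(aln, groups = NULL, model = "K2P",
                         window = 200L, step = 25L) {
  if (is.character(aln) && length(aln) == 1L && file.exists(aln)) {
    aln <- read_fasta(aln)
  }
  if (length(aln) < 2L) abort("need at least two aligned sequences")
  if (!is.null(groups)) {
    miss <- setdiff(names(aln), names(groups))
    if (length(miss) > 0L) {
      abort(paste0("alignment labels missing from groups: ",
                   paste(miss, collapse = ", ")))
    }
  }
  D <- distance_matrix(aln, model = model)
  tree <- if (length(aln) >= 3L && !anyNA(D)) neighbor_joining(D) else NULL
  list(
    distances = D,
    overall = overall_distance_mean(D),
    group_means = if (!is.null(groups)) group_distance_means(D, groups),
    tree = tree,
    newick = if (!is.null(tree)) write_newick(tree),
    pi_profile = sliding_pi(aln, window = window, step = step),
    saturation = saturation_profile(aln)
  )
}
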