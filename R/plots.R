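#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   geom_boxplot labs theme_minimal facet_wrap scale_fill_brewer
#' @export
ggplot2::autoplot

#' Plot a nucleotide-diversity profile
#'
#' @param object a \code{mito_pi_profile} from \code{\link{sliding_pi}}.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot mito_pi_profile
#' @export
autoplot.mito_pi_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$mid, y = .data$pi)) +
    geom_line(linewidth = 0.4) +
    labs(
      x = "alignment position (window midpoint, bp)",
      y = expression(pi),
      title = sprintf("Sliding-window nucleotide diversity (%d bp / step %d)",
                      attr(object, "window", exact = TRUE),
                      attr(object, "step", exact = TRUE))
    ) +
    theme_minimal()
}

#' Plot relative synonymous codon usage
#'
#' Stacked-bar RSCU per amino acid, each bar segment one synonymous codon.
#'
#' @param object a \code{mito_codon_table} from \code{\link{count_codons}}.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot mito_codon_table
#' @export
autoplot.mito_codon_table <- function(object, ...) {
  dat <- filter(as_tibble(object), .data$aa != "*", !is.na(.data$rscu))
  ggplot(dat, aes(x = .data$aa3, y = .data$rscu, fill = .data$codon)) +
    geom_col(colour = "grey30", linewidth = 0.1, show.legend = FALSE) +
    labs(x = NULL, y = "RSCU") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a saturation profile
#'
#' Transition (\code{s}) and transversion (\code{v}) proportions against
#' F84 distance; saturation shows as a plateau.
#'
#' @param object a \code{mito_saturation} from
#'   \code{\link{saturation_profile}}.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot mito_saturation
#' @export
autoplot.mito_saturation <- function(object, ...) {
  dat <- pivot_longer(as_tibble(object), c("P", "Q"),
                      names_to = "type", values_to = "proportion") |>
    mutate(type = if_else(.data$type == "P", "transitions (s)",
                          "transversions (v)"))
  ggplot(dat, aes(x = .data$f84, y = .data$proportion,
                  colour = .data$type)) +
    geom_point(size = 1.5) +
    labs(x = "F84 distance", y = "proportion of sites", colour = NULL) +
    theme_minimal()
}

#' Plot per-gene Ka/Ks ratios
#'
#' @param object output of \code{\link{pairwise_kaks}}.
#' @param ... unused.
#' @return A ggplot (boxplot per gene across pairs).
#' @export
plot_kaks <- function(object, ...) {
  ggplot(object, aes(x = .data$gene, y = .data$ka_ks)) +
    geom_boxplot(outlier.size = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    labs(x = NULL, y = "Ka/Ks") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
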