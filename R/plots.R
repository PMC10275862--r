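#' Plot a mutation spectrum
#'
#' Bar plot of a categories-by-clones count matrix (6, 96 or 83
#' categories), one facet per clone, colored by substitution type where
#' applicable.
#'
#' @param counts Count-matrix tibble from [build_count_matrix()].
#' @param relative Show per-clone relative contributions instead of counts.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(counts, relative = FALSE) {
  counts <- as_tibble(counts)
  long <- tidyr::pivot_longer(counts, -"category", names_to = "clone_id",
                              values_to = "n")
  if (relative) {
    long <- long |>
      group_by(.data$clone_id) |>
      mutate(n = .data$n / sum(.data$n)) |>
      ungroup()
  }
  long$category <- factor(long$category, levels = counts$category)
  sub <- if (all(grepl("\\[", counts$category))) {
    sub("^.\\[(.>.)\\].$", "\\1", long$category)
  } else if (all(counts$category %in% sbs6_types())) {
    as.character(long$category)
  } else {
    sub("^([0-9]+:[A-Za-z]+).*", "\\1", long$category)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$n,
                                     fill = sub)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$clone_id)) +
    ggplot2::labs(x = NULL, y = if (relative) "fraction" else "count",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, size = 4, vjust = 0.5))
}

#' @export
autoplot.radmut_signatures <- function(object, ...) {
  long <- tidy.radmut_signatures(object)
  long$category <- factor(long$category,
                          levels = rownames(object$signatures))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category,
                                     y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$signature), ncol = 1) +
    ggplot2::labs(x = NULL, y = "weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, size = 4, vjust = 0.5))
}

#' @export
autoplot.radmut_clusters <- function(object, ...) {
  counts <- count_cluster_classes(object, by = "clone_id")
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$clone_id,
                                       y = .data$n_mutations,
                                       fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "clustered mutations", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-clone VAF distributions
#'
#' Histograms of variant allele fractions, whose peaks reflect the ploidy
#' state of the sequenced clone (~0.25 tetraploid-het, ~0.5 diploid-het,
#' ~1 haploid/homozygous).
#'
#' @param variants Tibble with `clone_id` and `vaf` columns, e.g. from
#'   [attributed_variants()].
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_vaf_distribution <- function(variants, bins = 40) {
  ggplot2::ggplot(as_tibble(variants), ggplot2::aes(x = .data$vaf)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::facet_wrap(ggplot2::vars(.data$clone_id)) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "variant allele fraction", y = "variants") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
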