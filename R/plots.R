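#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_col labs theme_minimal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Bar plot of subgroup counts in a classified family
#'
#' @param summary A `ppr_family_summary` from [family_summary()].
#' @return A ggplot object.
#' @export
plot_family_summary <- function(summary) {
  stopifnot(inherits(summary, "ppr_family_summary"))
  df <- summary$label_counts |>
    mutate(label = factor(.data$label, levels = c("P", "PLS", "E1", "E2", "E+", "DYW")))
  ggplot(df, aes(x = .data$label, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(
      x = "Subfamily / subgroup", y = "Proteins",
      title = "PPR family composition"
    ) +
    theme_minimal()
}

#' @export
autoplot.ppr_family_summary <- function(object, ...) {
  plot_family_summary(object)
}

#' Bar plot of intron-count bin proportions
#'
#' @param bins Tibble from [bin_intron_counts()].
#' @return A ggplot object.
#' @export
plot_intron_bins <- function(bins) {
  ggplot(bins, aes(x = .data$bin, y = .data$proportion)) +
    geom_col(fill = "darkseagreen4") +
    labs(
      x = "Introns per gene", y = "Proportion of genes",
      title = "Intron-count distribution"
    ) +
    theme_minimal()
}

#' Histogram of motif counts per subfamily
#'
#' @param summary A `ppr_family_summary`.
#' @return A ggplot object.
#' @export
plot_motif_histogram <- function(summary) {
  stopifnot(inherits(summary, "ppr_family_summary"))
  ggplot(
    summary$motif_histogram,
    aes(x = .data$total_motifs, y = .data$n, fill = .data$subfamily)
  ) +
    geom_col(position = "dodge") +
    labs(
      x = "Motifs per protein", y = "Proteins", fill = "Subfamily",
      title = "Motif-count distribution by subfamily"
    ) +
    theme_minimal()
}
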