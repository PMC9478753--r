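#' Plot an RT profile along a chromosome
#'
#' Early (positive) bins are drawn upward, late (negative) downward,
#' the standard presentation of a replication-timing track.
#'
#' @param p An RT-profile tibble.
#' @param chrom Chromosome to plot (default: first).
#' @return A ggplot object.
#' @export
plot_rt_profile <- function(p, chrom = NULL) {
  if (is.null(chrom)) chrom <- p$chrom[1]
  d <- dplyr::filter(p, .data$chrom == !!chrom, !is.na(.data$rt))
  ggplot2::ggplot(d, ggplot2::aes(x = (start + end) / 2e6, y = rt)) +
    ggplot2::geom_area(ggplot2::aes(fill = rt > 0), alpha = 0.8,
                       show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#D55E00",
                                          `FALSE` = "#0072B2")) +
    ggplot2::labs(x = sprintf("%s position (Mb)", chrom),
                  y = "RT (log2 early/late)") +
    ggplot2::theme_minimal()
}

#' Plot a feature's distribution across RT categories
#'
#' Boxplots of a feature-table column per RT category — the panel layout
#' used for gene density, GC content and mark-signal comparisons.
#'
#' @param ft A feature table from [build_feature_table()].
#' @param feature Column name to plot.
#' @return A ggplot object.
#' @export
plot_category_feature <- function(ft, feature) {
  d <- dplyr::filter(ft, .data$category %in% c("CE", "CL", "EtoL", "LtoE"),
                     !is.na(.data[[feature]]))
  ggplot2::ggplot(d, ggplot2::aes(x = category, y = .data[[feature]],
                                  fill = category)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = feature) +
    ggplot2::theme_minimal()
}

#' Plot compartment composition per RT category
#'
#' Stacked A/B fractions per category, the presentation of the
#' compartment-discordance result.
#'
#' @param comp A table from [compartment_composition()].
#' @return A ggplot object.
#' @export
plot_compartment_composition <- function(comp) {
  d <- tidyr::pivot_longer(comp, c("A", "B"), names_to = "compartment",
                           values_to = "fraction")
  ggplot2::ggplot(d, ggplot2::aes(x = category, y = fraction,
                                  fill = compartment)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(A = "#D55E00", B = "#0072B2")) +
    ggplot2::labs(x = NULL, y = "fraction of bins") +
    ggplot2::theme_minimal()
}

#' Plot a contact matrix heatmap
#'
#' @param m A [contact_matrix()].
#' @param log_scale Log10-transform counts (default TRUE).
#' @return A ggplot object.
#' @export
plot_contact_matrix <- function(m, log_scale = TRUE) {
  d <- tidy.contact_matrix(m)
  d2 <- d
  names(d2)[names(d2) == "bin_i"] <- "tmp"
  names(d2)[names(d2) == "bin_j"] <- "bin_i"
  names(d2)[names(d2) == "tmp"] <- "bin_j"
  d <- dplyr::bind_rows(d, d2[d2$bin_i != d2$bin_j, ])
  if (log_scale) d$count <- log10(d$count + 1)
  ggplot2::ggplot(d, ggplot2::aes(x = bin_i, y = bin_j, fill = count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "#B2182B",
                                 name = if (log_scale) "log10(1+n)" else "n") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin", y = "bin") +
    ggplot2::theme_minimal()
}
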