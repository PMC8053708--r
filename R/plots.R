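#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a class composition
#'
#' @param object a `cpa_composition` tibble ([class_composition()] or
#'   [responsive_composition()]).
#' @param ... unused.
#' @return A ggplot bar chart of class fractions.
#' @export
autoplot.cpa_composition <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$srna_class,
                                                  -.data$fraction),
                               y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a coverage and terminus-end profile
#'
#' @param object a `cpa_coverage` tibble ([coverage_profile()]).
#' @param ... unused.
#' @return A ggplot with the coverage ribbon and 5'/3' end histograms.
#' @export
autoplot.cpa_coverage <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("coverage", "end5", "end3"),
                              names_to = "layer")
  long$layer <- factor(long$layer, levels = c("coverage", "end5", "end3"),
                       labels = c("coverage", "5' ends", "3' ends"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_area(fill = "grey40") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$layer), scales = "free_y") +
    ggplot2::labs(x = "position on reference (nt)", y = "abundance") +
    ggplot2::theme_minimal()
}

#' Plot methylation calls
#'
#' Mismatch frequency without AlkB against frequency with AlkB, one point
#' per called site, colored by kind; the diagonal marks no demethylation
#' response.
#'
#' @param object a `cpa_methyl_calls` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cpa_methyl_calls <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$f_withAlkB,
                                       y = .data$f_noAlkB,
                                       colour = .data$kind)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "mismatch frequency, AlkB-treated",
                  y = "mismatch frequency, untreated") +
    ggplot2::theme_minimal()
}

#' Plot the TSI distribution
#'
#' @param object a `cpa_tsi` tibble ([tissue_specificity()]).
#' @param ... unused.
#' @return A ggplot histogram of TSI, faceted by class when available.
#' @export
autoplot.cpa_tsi <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$tsi)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue") +
    ggplot2::labs(x = "tissue specificity index", y = "sequences") +
    ggplot2::theme_minimal()
  if ("srna_class" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$srna_class),
                                 scales = "free_y")
  }
  p
}

#' Dot plot of tissue-enriched small RNAs
#'
#' @param enriched a [filter_and_enrich()] result.
#' @return A ggplot dot plot of enriched sequences by home tissue.
#' @export
plot_enrichment <- function(enriched) {
  ggplot2::ggplot(enriched, ggplot2::aes(x = .data$max_tissue,
                                         y = .data$max_value,
                                         colour = .data$srna_class)) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "tissue of maximal expression",
                  y = "max expression (RPM)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Fold-change scatter of a treatment comparison
#'
#' @param full_tbl,reduced_tbl per-library expression tibbles (as passed to
#'   [call_responsive()]).
#' @param calls the matching [call_responsive()] result.
#' @param value value layer name.
#' @return A ggplot of reduced vs full abundance with responsive calls
#'   highlighted.
#' @export
plot_responsive <- function(full_tbl, reduced_tbl, calls,
                            value = "mirna_norm") {
  take <- function(tbl, nm) {
    out <- tbl[, c("sequence", value)]
    names(out)[2] <- nm
    out
  }
  joined <- dplyr::full_join(take(full_tbl, "full"),
                             take(reduced_tbl, "reduced"),
                             by = "sequence")
  joined$full[is.na(joined$full)] <- 0
  joined$reduced[is.na(joined$reduced)] <- 0
  joined$responsive <- joined$sequence %in% calls$sequence
  ggplot2::ggplot(joined, ggplot2::aes(x = .data$reduced + 0.5,
                                       y = .data$full + 0.5,
                                       colour = .data$responsive)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "enzyme-omitted library", y = "full treatment") +
    ggplot2::theme_minimal()
}
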