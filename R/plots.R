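# ggplot2 views of the result tables.

#' Volcano plot of a differential result
#'
#' Works for [test_de()] (effect = log2 fold change) and [test_dmp()]
#' (effect = delta beta) tables.
#'
#' @param x A `methlink_de` or `methlink_dmp` tibble.
#' @return A ggplot object.
#' @export
plot_volcano <- function(x) {
  eff <- if ("log2fc" %in% names(x)) "log2fc" else "delta_beta"
  sig <- if ("is_deg" %in% names(x)) "is_deg" else "is_dmp"
  ggplot2::ggplot(x, ggplot2::aes(.data[[eff]], -log10(.data$p),
                                  colour = .data[[sig]])) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = eff, y = "-log10 p", colour = "significant",
                  subtitle = x$contrast[1]) +
    ggplot2::theme_minimal()
}

#' @method autoplot methlink_de
#' @export
autoplot.methlink_de <- function(object, ...) plot_volcano(object)

#' @method autoplot methlink_dmp
#' @export
autoplot.methlink_dmp <- function(object, ...) plot_volcano(object)

#' Bar plot of rescue status counts
#' @param x A [classify_rescue()] result.
#' @return A ggplot object.
#' @export
plot_rescue_summary <- function(x) {
  x %>%
    filter(.data$status != "not_applicable") %>%
    count(.data$status) %>%
    ggplot2::ggplot(ggplot2::aes(.data$status, .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "rescue status", y = "features") +
    ggplot2::theme_minimal()
}

#' @method autoplot methlink_rescue
#' @export
autoplot.methlink_rescue <- function(object, ...) plot_rescue_summary(object)

#' Correlation-vs-distance view of classified cis pairs
#' @param x A [classify_pairs()] result.
#' @return A ggplot object.
#' @export
plot_pairs <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(.data$distance, .data$rho,
                                  colour = .data$pair_class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(canonical = "royalblue",
                                            non_canonical = "darkorange",
                                            ns = "grey70")) +
    ggplot2::labs(x = "distance to TSS (bp, downstream positive)",
                  y = "Spearman rho", colour = "pair class") +
    ggplot2::theme_minimal()
}

#' @method autoplot methlink_pairs
#' @export
autoplot.methlink_pairs <- function(object, ...) plot_pairs(object)

#' Cross-dataset correlation-direction plot
#' @param x An [intersect_linked_genes()] result.
#' @return A ggplot object.
#' @export
plot_concordance <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(.data$rho_a, .data$rho_b,
                                  colour = .data$concordant)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "representative rho, dataset A",
                  y = "representative rho, dataset B") +
    ggplot2::theme_minimal()
}

#' @method autoplot methlink_concordance
#' @export
autoplot.methlink_concordance <- function(object, ...) plot_concordance(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
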