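#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_histogram geom_point
#'   geom_vline labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a relative-location profile
#'
#' Proportion of anchored promoters with at least one query site per offset
#' bin, relative to the anchor midpoint (negative = upstream of the anchor,
#' positive = toward the gene).
#'
#' @param object A `rel_loc_profile` from [relative_locations()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rel_loc_profile
#' @export
autoplot.rel_loc_profile <- function(object, ...) {
  ggplot(object$bins, aes(x = .data$bin_start, y = .data$proportion)) +
    geom_col(width = object$bin_size * 0.9, fill = "#5b3794") +
    labs(x = sprintf("offset of %s midpoint from %s anchor (bp)",
                     object$query, object$anchor),
         y = "proportion of promoters",
         title = sprintf("%s sites relative to the %s anchor",
                         object$query, object$anchor)) +
    theme_minimal()
}

#' Plot sampled gain/loss distributions
#'
#' Histograms of per-map gain and loss counts over the sampled character
#' maps.
#'
#' @param object A `char_maps` from [sample_maps()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot char_maps
#' @export
autoplot.char_maps <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("gains", "losses"),
                        names_to = "event", values_to = "count")
  ggplot(df, aes(x = .data$count)) +
    geom_histogram(binwidth = 1, fill = "#2a7e43") +
    facet_wrap(~event, scales = "free_x") +
    labs(x = "events per map", y = "maps",
         title = sprintf("%d stochastic character maps", object$nmaps)) +
    theme_minimal()
}

#' Volcano-style plot of per-gene allelic expression results
#'
#' @param results Tibble from [ase_test()].
#' @param fdr FDR level used for colouring.
#' @return A ggplot.
#' @export
plot_ase <- function(results, fdr = 0.05) {
  df <- results[results$status == "tested", ]
  ggplot(df, aes(x = .data$mean_log2, y = -log10(.data$p),
                 colour = .data$significant)) +
    geom_point(size = 0.6, alpha = 0.6) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    labs(x = "mean log2 allelic ratio (A / B)", y = "-log10 p",
         colour = sprintf("q <= %.2g", fdr)) +
    theme_minimal()
}
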