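# ggplot2 views of the main result types.

#' Volcano plot of region activities
#'
#' @param object A `starr_activity` tibble from [call_activity()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot starr_activity
#' @export
autoplot.starr_activity <- function(object, ...) {
  d <- as_tibble(object)
  d <- d[!is.na(d$pvalue), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2FC,
                                  y = -log10(pmax(.data$padj, 1e-300)),
                                  colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      PRE = "#c0392b", NRE = "#2980b9", inactive = "grey60", filtered = "grey85"
    )) +
    ggplot2::labs(x = "log2 fold change (output / input)",
                  y = "-log10 adjusted p", colour = "class") +
    ggplot2::theme_minimal()
}

#' Allelic effect-size plot
#'
#' Effect size (fold change of allele ratios, output over input) against
#' adjusted p, regulatory calls highlighted.
#'
#' @param object A `starr_allelic` tibble from [allelic_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot starr_allelic
#' @export
autoplot.starr_allelic <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = log2(.data$effect_size),
                                  y = -log10(pmax(.data$padj, 1e-300)),
                                  colour = .data$regulatory)) +
    ggplot2::geom_point(alpha = 0.7, size = 0.9) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "log2 allelic effect size", y = "-log10 adjusted p",
                  colour = "regulatory") +
    ggplot2::theme_minimal()
}

#' Coverage-curve plot
#'
#' Mean covered fraction (both alleles represented) against the number of
#' pooled individuals, with +/- 1 sd error bars over repeats.
#'
#' @param object A `starr_coverage` tibble from [coverage_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot starr_coverage
#' @export
autoplot.starr_coverage <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$i, y = .data$mean_p)) +
    ggplot2::geom_line(colour = "#2980b9") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_p - .data$sd_p,
                                          ymax = .data$mean_p + .data$sd_p),
                             size = 0.3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "individuals sampled",
                  y = "fraction of SNPs with both alleles covered") +
    ggplot2::theme_minimal()
}

#' Forest plot of enrichment odds ratios
#'
#' @param enrichment An enrichment tibble (rows from [overlap_enrichment()]
#'   or [delta_enrichment()]).
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment) {
  check_columns(enrichment, c("test_class", "odds_ratio", "ci_lower",
                              "ci_upper"), "enrichment")
  d <- dplyr::mutate(as_tibble(enrichment),
                     label = paste(.data$test_class, "vs", .data$reference_class))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lower,
                                          xmax = .data$ci_upper)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (conditional MLE, 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
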