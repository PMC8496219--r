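#' Plot a LOD curve
#'
#' LOD against genetic position, faceted by chromosome, with the genome-wide
#' permutation threshold as a dashed line when available.
#'
#' @param object A `scan_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scan_result
#' @export
autoplot.scan_result <- function(object, ...) {
  df <- tidy(object)
  df$chrom <- factor(df$chrom, levels = unique(df$chrom))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_cM, y = .data$lod)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x", switch = "x") +
    ggplot2::labs(x = "position (cM)", y = "LOD") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing.x = ggplot2::unit(0.15, "lines"),
                   axis.text.x = ggplot2::element_blank(),
                   strip.placement = "outside")
  if (!is.null(attr(object, "threshold"))) {
    p <- p + ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot the tetrad spectrum
#'
#' Histogram of the number of phenotype-positive (diploidized) spores per
#' tetrad; a single 2:2-segregating causal locus concentrates mass at 2.
#'
#' @param cross A `sim_cross` object.
#' @return A ggplot.
#' @export
plot_tetrad_spectrum <- function(cross) {
  spec <- tetrad_spectrum(cross) |>
    dplyr::count(.data$n_diploid, name = "n_tetrads")
  ggplot2::ggplot(spec, ggplot2::aes(x = factor(.data$n_diploid, levels = 0:4),
                                     y = .data$n_tetrads)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = "diploidized spores per tetrad", y = "tetrads") +
    ggplot2::theme_minimal()
}

#' Plot pool B-allele fractions
#'
#' Per-pool proportion of reads matching the B allele at a marker, with exact
#' binomial confidence intervals -- the bulk-segregant enrichment picture.
#'
#' @param pools Pool counts tibble.
#' @param marker `marker_id` to display.
#' @param conf_level Confidence level for the intervals. Default 0.95.
#' @return A ggplot.
#' @export
plot_pool_fractions <- function(pools, marker, conf_level = 0.95) {
  df <- pool_allele_fraction(pools, marker = marker, conf_level = conf_level)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pool_id, y = .data$fraction_B,
                                   fill = .data$phenotype)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf_low,
                                        ymax = .data$conf_high), width = 0.2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "fraction of reads matching B allele",
                  title = paste("B-allele enrichment at", marker)) +
    ggplot2::theme_minimal()
}

#' Plot allele effects at a locus
#'
#' Phenotype mean (estimated penetrance) of each parental allele with its
#' binomial standard error.
#'
#' @param effects Tibble from [estimate_effects()] (or the `effects` element
#'   of a fitted `qtl_model`).
#' @return A ggplot.
#' @export
plot_allele_effects <- function(effects) {
  ggplot2::ggplot(effects, ggplot2::aes(x = .data$allele, y = .data$mean)) +
    ggplot2::geom_col(width = 0.5) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.15) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "allele at locus", y = "phenotype mean (penetrance)") +
    ggplot2::theme_minimal()
}
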