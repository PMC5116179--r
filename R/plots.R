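#' Plot a probe series with its segmentation
#'
#' Probe log2 ratios as points, segment means as horizontal bars colored by
#' call class.
#'
#' @param probes Probe tibble `(chrom, pos, log2)`.
#' @param segments Segment tibble from [segment_probes()].
#' @return A ggplot.
#' @export
plot_cna_profile <- function(probes, segments) {
  ggplot2::ggplot(probes, ggplot2::aes(x = .data$pos, y = .data$log2)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4, colour = "grey40") +
    ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$mean_log2, yend = .data$mean_log2,
                   colour = .data$call),
      linewidth = 1.2
    ) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(
      gain = "#2166ac", high_gain = "#053061", loss = "#b2182b",
      homozygous_loss = "#67001f", neutral = "grey55"
    )) +
    ggplot2::labs(x = "position (bp)", y = "log2 ratio", colour = "call") +
    ggplot2::theme_minimal()
}

#' Tumor-vs-leukocyte allele-fraction plot of classified variants
#'
#' @param classification A `trio_classification`.
#' @return A ggplot.
#' @export
plot_vaf_scatter <- function(classification) {
  v <- tidy(classification) |>
    mutate(class = dplyr::case_when(
      .data$somatic %in% TRUE ~ "somatic",
      .data$rare_homozygous %in% TRUE ~ "rare homozygous",
      .data$compound_het_member %in% TRUE ~ "compound het",
      .data$de_novo %in% TRUE ~ "de novo",
      TRUE ~ "unclassified"
    ))
  ggplot2::ggplot(v, ggplot2::aes(x = .data$patient_vaf, y = .data$tumor_vaf,
                                  colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::labs(x = "leukocyte VAF", y = "tumor VAF", colour = NULL) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Detection-probability heat map of a limit-of-detection grid
#'
#' @param lod Tibble from [lod_simulation()].
#' @return A ggplot.
#' @export
plot_lod_grid <- function(lod) {
  ggplot2::ggplot(lod, ggplot2::aes(x = factor(.data$mass_ng),
                                    y = factor(.data$fraction),
                                    fill = .data$detect_prob)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$detect_prob)),
                       colour = "white", size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "input mass (ng)", y = "tumor fraction",
                  fill = "P(detect)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot.trio_classification()` draws the VAF scatter;
#' `autoplot.ddpcr_quant()` the per-channel concentrations with CIs.
#'
#' @param object The fitted object.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-rarecase
NULL

#' @rdname autoplot-rarecase
#' @exportS3Method ggplot2::autoplot
autoplot.trio_classification <- function(object, ...) plot_vaf_scatter(object)

#' @rdname autoplot-rarecase
#' @exportS3Method ggplot2::autoplot
autoplot.ddpcr_quant <- function(object, ...) {
  d <- as_tibble(object) |> filter(is.finite(.data$copies_per_ul))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$channel, y = .data$copies_per_ul)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conc_low,
                                          ymax = .data$conc_high)) +
    ggplot2::labs(x = NULL, y = "copies / µL partitioned volume") +
    ggplot2::theme_minimal()
}
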