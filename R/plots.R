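#' Plot per-sample splice-form proportions
#'
#' Stacked proportions of assigned reads per sample — the first look at a
#' sequencing run: dominance of individual splice forms and the size of
#' the unassigned fraction.
#'
#' @param counts A count table from [count_splice_forms()].
#' @param include_unassigned Include the `UNASSIGNED` bucket (default
#'   FALSE).
#' @return A ggplot object.
#' @export
plot_splice_form_proportions <- function(counts, include_unassigned = FALSE) {
  d <- counts
  if (!include_unassigned) d <- dplyr::filter(d, .data$species != "UNASSIGNED")
  d <- d |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(proportion = .data$raw_count / sum(.data$raw_count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(species = factor(.data$species, levels = species_levels()))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$proportion,
                                  fill = .data$species)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of reads", fill = "species") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname estimate_bias
#' @param object A `bias_model`.
#' @export
autoplot.bias_model <- function(object, ...) {
  per_mix <- object$per_mixture_factors |>
    tidyr::pivot_longer(-"sample_id", names_to = "species",
                        values_to = "factor")
  p <- ggplot2::ggplot(per_mix,
                       ggplot2::aes(x = .data$species, y = .data$factor)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$sample_id), alpha = 0.7) +
    ggplot2::geom_point(data = object$factors, shape = 4, size = 3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(y = "amplification bias factor (log2 scale)",
                  colour = "mixture") +
    ggplot2::theme_minimal()
  p
}

#' Forest-style plot of harmonized GWAS odds ratios
#'
#' Loci on the y axis sorted by median OR across studies, one point per
#' study, on a log2 OR axis anchored at 1.
#'
#' @param harmonized Output of [harmonize_odds_ratios()].
#' @return A ggplot object.
#' @export
plot_odds_ratios <- function(harmonized) {
  d <- dplyr::mutate(harmonized,
                     locus = factor(.data$locus,
                                    levels = rev(unique(.data$locus))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio, y = .data$locus)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$study)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$median_or), shape = 124,
                        size = 4, colour = "black") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "odds ratio (log2 axis)", y = NULL) +
    ggplot2::theme_minimal()
}
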