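#' Heatmap of a stage-similarity matrix
#'
#' @param object A `stage_cor` from [pairwise_similarity()].
#' @param ... Ignored.
#' @return A ggplot: samples on both axes, fill = Spearman rho, brighter
#'   cells = higher similarity.
#' @method autoplot stage_cor
#' @export
autoplot.stage_cor <- function(object, ...) {
  df <- tidy.stage_cor(object)
  lv <- rownames(unclass(object))
  df$sample_1 <- factor(df$sample_1, levels = lv)
  df$sample_2 <- factor(df$sample_2, levels = rev(lv))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_1, .data$sample_2,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(min(df$rho, na.rm = TRUE), 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman\nrho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Null distribution of a resampling test
#'
#' @param object A `resampling_result`.
#' @param ... Ignored.
#' @return A ggplot: histogram of the null metric values with the observed
#'   value marked.
#' @method autoplot resampling_result
#' @export
autoplot.resampling_result <- function(object, ...) {
  df <- tibble::tibble(null_value = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(.data$null_value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(x = "metric on random gene sets", y = "count",
                  subtitle = sprintf("observed = %.3f, quantile = %.3f, p = %.3g",
                                     object$observed, object$quantile,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}

#' Genes per trajectory template
#'
#' @param object A `trajectory_assignment`.
#' @param ... Ignored.
#' @return A ggplot bar chart of assignment counts over the 27 templates,
#'   zigzag templates highlighted.
#' @method autoplot trajectory_assignment
#' @export
autoplot.trajectory_assignment <- function(object, ...) {
  counts <- dplyr::count(tibble::as_tibble(unclass(object)), .data$template)
  counts$template <- factor(counts$template,
                            levels = trajectory_templates()$id)
  counts$zigzag <- counts$template %in% zigzag_template_ids()
  ggplot2::ggplot(counts, ggplot2::aes(.data$template, .data$n,
                                       fill = .data$zigzag)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick"),
                               guide = "none") +
    ggplot2::labs(x = "trajectory template", y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Embryo-similarity profile across development
#'
#' @param profile Tibble from [embryo_similarity_profile()].
#' @return A ggplot: samples in time order against Spearman similarity with
#'   the embryonic reference; a pupal rise above the larval trough is the
#'   reversion signature.
#' @export
plot_embryo_similarity <- function(profile) {
  profile$sample_id <- factor(profile$sample_id, levels = profile$sample_id)
  ggplot2::ggplot(profile, ggplot2::aes(.data$sample_id, .data$rho,
                                        colour = .data$major_stage,
                                        group = 1)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "Spearman rho vs embryonic reference",
                  colour = "stage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Cross-transition fold-change scatter
#'
#' One dot per gene: pupa-to-adult log fold change on the x-axis against
#' embryo-to-larva on the y-axis. Genes significant in both transitions
#' (|lfc| above the threshold) are drawn in red. A rising cloud means the
#' adult-eclosion program recapitulates the larval-hatching program.
#'
#' @param lfc_el,lfc_pa Tibbles from [transition_lfc()] (embryo-to-larva and
#'   pupa-to-adult).
#' @return A ggplot.
#' @export
plot_recapitulation <- function(lfc_el, lfc_pa) {
  stopifnot(identical(lfc_el$gene_id, lfc_pa$gene_id))
  df <- tibble::tibble(
    el = lfc_el$lfc, pa = lfc_pa$lfc,
    significant = lfc_el$significant & lfc_pa$significant
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$pa, .data$el,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 FC pupa to adult", y = "log2 FC embryo to larva") +
    ggplot2::theme_minimal()
}
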