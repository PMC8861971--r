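#' Plot a ctDNA detection report
#'
#' Per-site VAF on a log scale, coloured by detection status against the
#' negative controls.
#'
#' @param object A `ctdna_detection` tibble from [detect_ctdna()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ctdna_detection
#' @export
autoplot.ctdna_detection <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$site_id, y = pmax(.data$vaf, 1e-6),
    colour = .data$detected
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = NULL, y = "VAF (log scale)",
      colour = sprintf("detected (p <= %.3g)", attr(object, "alpha") %||% 0.05)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot regulator activity scores
#'
#' Ranked lollipop plot of integrated regulon activity, highlighting the top
#' regulators.
#'
#' @param object A `regulon_scores` tibble.
#' @param top Number of regulators to display (by |integrated|).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot regulon_scores
#' @export
autoplot.regulon_scores <- function(object, top = 20, ...) {
  df <- as_tibble(object) |>
    arrange(desc(abs(.data$integrated))) |>
    head(top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$regulator, .data$integrated),
    y = .data$integrated
  )) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$regulator, yend = 0)) +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "integrated activity score") +
    ggplot2::theme_minimal()
}

#' Plot intensity distributions by distance bin
#'
#' Boxplots of marker intensity per distance bin, faceted by marker and
#' stratum, annotated with the adjusted ANOVA p-value.
#'
#' @param object A `distance_bin_result` from [bin_and_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot distance_bin_result
#' @export
autoplot.distance_bin_result <- function(object, ...) {
  markers <- unique(object$tests$marker)
  long <- tidyr::pivot_longer(
    object$cells,
    cols = dplyr::all_of(markers),
    names_to = "marker", values_to = "intensity"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$.bin, y = .data$intensity)) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.size = 0.5) +
    ggplot2::facet_wrap(~marker, scales = "free_y") +
    ggplot2::labs(x = "distance to ECM mask (µm)", y = "intensity") +
    ggplot2::theme_minimal()
}
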