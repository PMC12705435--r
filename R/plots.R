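#' Bubble plot of age-related programs
#'
#' Cell types against gene sets; color carries the normalized enrichment
#' score (sign = direction of the age association), point size the magnitude
#' of the signature-score–age correlation, and hollow points mark pairs that
#' fail the dual significance gate.
#'
#' @param object An `aspen_result`.
#' @param significant_only Drop non-significant pairs (default FALSE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aspen_result <- function(object, significant_only = FALSE, ...) {
  df <- dplyr::filter(object$table, !is.na(.data$nes))
  if (significant_only) df <- dplyr::filter(df, .data$significant)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$celltype, y = .data$gene_set)) +
    ggplot2::geom_point(ggplot2::aes(size = abs(.data$score_age_r),
                                     fill = .data$nes,
                                     alpha = .data$significant),
                        shape = 21) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "NES") +
    ggplot2::scale_size_area(name = "|score-age r|", max_size = 6) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25),
                                name = "dual gate") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Scatter plot of composition trends against age
#'
#' @param composition Output of [minor_within_major_proportions()].
#' @param donors Donor tibble with `donor_id`, `age`.
#' @return A ggplot object faceted by major type.
#' @export
plot_composition_trends <- function(composition, donors) {
  df <- dplyr::left_join(composition,
                         dplyr::select(donors, "donor_id", "age"),
                         by = "donor_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$proportion,
                                   color = .data$celltype_minor)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$celltype_major)) +
    ggplot2::labs(x = "donor age (years)",
                  y = "proportion within major type", color = "minor type") +
    ggplot2::theme_minimal()
}

#' Patient-level proximity by age group
#'
#' @param object A `proximity_result`.
#' @param ... Unused.
#' @return A ggplot object: patient medians by age group, one facet per
#'   query/reference comparison.
#' @export
autoplot.proximity_result <- function(object, ...) {
  df <- object$summaries |>
    dplyr::mutate(comparison = paste(.data$query, .data$reference,
                                     sep = " vs "))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_group,
                                   y = .data$median_fraction)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$comparison)) +
    ggplot2::labs(x = NULL, y = "patient median adjacency fraction") +
    ggplot2::theme_minimal()
}
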