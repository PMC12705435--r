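#' Minor-within-major cell type proportions per donor
#'
#' For each donor and major cell type with at least one cell, computes the
#' proportion of each minor type among that donor's cells of the major type.
#' Donors with zero cells of a major type contribute no rows for its minors
#' (a proportion over an empty denominator is undefined, not zero).
#'
#' @param cells Per-cell annotation tibble with `donor_id`, `celltype_major`,
#'   `celltype_minor`.
#' @return A tibble: `donor_id`, `celltype_major`, `celltype_minor`,
#'   `n_cells`, `proportion`; within each (donor, major) the proportions sum
#'   to 1.
#' @export
minor_within_major_proportions <- function(cells) {
  map <- dplyr::distinct(cells, .data$celltype_minor, .data$celltype_major)
  dup <- map$celltype_minor[duplicated(map$celltype_minor)]
  if (length(dup)) {
    stop(sprintf("minor type(s) mapped to more than one major type: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  cells |>
    dplyr::count(.data$donor_id, .data$celltype_major, .data$celltype_minor,
                 name = "n_cells") |>
    dplyr::group_by(.data$donor_id, .data$celltype_major) |>
    dplyr::mutate(proportion = .data$n_cells / sum(.data$n_cells)) |>
    dplyr::ungroup()
}

#' Age trend in minor cell type proportions
#'
#' Correlates each minor type's per-donor proportion with donor age and
#' applies Benjamini–Hochberg adjustment across the minor types that share a
#' major type (never across majors). Minor types observed in fewer than 3
#' donors are flagged `not_testable`; constant proportions are flagged
#' `undefined`.
#'
#' @param composition Output of [minor_within_major_proportions()].
#' @param donors Donor tibble with `donor_id`, `age`.
#' @param method Correlation method, `"pearson"` (default) or `"spearman"`.
#' @return A tibble: `celltype_major`, `celltype_minor`, `n_donors`, `r`,
#'   `p`, `padj`, `status`.
#' @export
composition_age_trend <- function(composition, donors,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ages <- stats::setNames(donors$age, donors$donor_id)
  per_minor <- composition |>
    dplyr::group_by(.data$celltype_major, .data$celltype_minor) |>
    dplyr::summarise(
      n_donors = dplyr::n(),
      res = list(cor_or_flag(.data$proportion, ages[.data$donor_id], method)),
      .groups = "drop") |>
    tidyr::unnest_wider("res")
  per_minor |>
    dplyr::group_by(.data$celltype_major) |>
    dplyr::mutate(padj = bh_adjust(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::select("celltype_major", "celltype_minor", "n_donors", "r", "p",
                  "padj", "status")
}

cor_or_flag <- function(x, y, method = "pearson") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    return(list(r = NA_real_, p = NA_real_, status = "not_testable"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, status = "undefined"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, status = "ok")
}
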