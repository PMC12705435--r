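#' Tidy an ASPEN result
#'
#' Returns the age-related-program table, one row per (cell type, gene set),
#' dropping the list columns by default.
#'
#' @param x An `aspen_result`.
#' @param leading_edge Keep the leading-edge list column (default FALSE).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.aspen_result <- function(x, leading_edge = FALSE, ...) {
  out <- x$table
  if (!leading_edge) out <- dplyr::select(out, -"leading_edge")
  out
}

#' One-row summary of an ASPEN run
#'
#' @param x An `aspen_result`.
#' @param ... Unused.
#' @return A tibble with counts of cell types, sets, significant pairs, the
#'   alpha and permutation settings used.
#' @export
glance.aspen_result <- function(x, ...) {
  tibble::tibble(
    n_celltypes = dplyr::n_distinct(x$table$celltype),
    n_gene_sets = dplyr::n_distinct(x$table$gene_set),
    n_excluded_celltypes = nrow(x$excluded),
    n_significant = sum(x$table$significant, na.rm = TRUE),
    alpha = x$config$alpha,
    n_permutations = x$config$n_permutations,
    seed = x$config$seed)
}

#' Tidy a proximity comparison
#' @param x A `proximity_result`.
#' @param ... Unused.
#' @return The comparison tibble.
#' @export
tidy.proximity_result <- function(x, ...) x$comparisons

#' One-row summary of a proximity comparison
#' @param x A `proximity_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.proximity_result <- function(x, ...) {
  tibble::tibble(
    n_comparisons = nrow(x$comparisons),
    n_tested = sum(x$comparisons$status == "ok"),
    n_significant = sum(x$comparisons$padj < 0.05, na.rm = TRUE))
}
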