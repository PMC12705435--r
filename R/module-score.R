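#' Binned-control signature scores per cell
#'
#' Assigns each cell a score per gene set: the mean log-normalized expression
#' of the matched signature genes minus the mean over a pool of control genes
#' drawn from expression-matched bins. Genes are ranked by their dataset-wide
#' average log-normalized expression and split into `n_bins` equal-occupancy
#' quantile bins; ties are resolved deterministically by gene id, never by
#' jitter. For every signature gene, `n_ctrl` controls are sampled without
#' replacement from its bin (the whole bin when it is smaller), the draws
#' pooled (unique genes) per set.
#'
#' @param dataset An `expression_dataset` with a lognorm layer.
#' @param gene_sets A `gene_set_collection` or named list.
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Controls sampled per signature gene (default 100).
#' @param seed Integer seed for the control draws; one stream is used for the
#'   whole call so identical inputs give bitwise-identical scores.
#' @param exclude_signature Exclude a set's own genes from its control pool
#'   (default TRUE).
#' @return An object of class `module_scores`: list with `scores` (cells x
#'   sets dense matrix), `bins` (named integer vector of bin assignments),
#'   `unmatched` (named list of set members absent from the matrix), `seed`.
#' @export
module_scores <- function(dataset, gene_sets, n_bins = 24, n_ctrl = 100,
                          seed = 1L, exclude_signature = TRUE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$lognorm)) {
    stop("dataset has no lognorm layer; run lognormalize() first",
         call. = FALSE)
  }
  expr <- dataset$lognorm
  genes <- rownames(expr)
  if (n_bins > length(genes)) {
    stop("n_bins exceeds the gene universe", call. = FALSE)
  }
  avg <- Matrix::rowMeans(expr)
  # deterministic quantile bins: order by (average, gene id), cut into
  # n_bins nearly equal slices
  ord <- order(avg, genes, method = "radix")
  bin_of_rank <- if (n_bins == 1L) rep(1L, length(genes)) else
    as.integer(cut(seq_along(genes), breaks = n_bins, labels = FALSE))
  bins <- integer(length(genes))
  bins[ord] <- bin_of_rank
  names(bins) <- genes
  by_bin <- split(genes, bins)

  sets <- unclass(gene_sets)
  set.seed(seed)
  scores <- matrix(NA_real_, nrow = ncol(expr), ncol = length(sets),
                   dimnames = list(colnames(expr), names(sets)))
  unmatched <- purrr::map(sets, ~ setdiff(.x, genes))
  for (si in seq_along(sets)) {
    sig <- intersect(sets[[si]], genes)
    if (!length(sig)) next
    ctrl <- unique(unlist(purrr::map(sig, function(g) {
      pool <- by_bin[[as.character(bins[[g]])]]
      if (exclude_signature) pool <- setdiff(pool, sig)
      if (!length(pool)) return(character())
      if (length(pool) <= n_ctrl) pool
      else pool[sort.int(sample.int(length(pool), n_ctrl))]
    }), use.names = FALSE))
    sig_mean <- Matrix::colMeans(expr[sig, , drop = FALSE])
    ctrl_mean <- if (length(ctrl)) {
      Matrix::colMeans(expr[ctrl, , drop = FALSE])
    } else 0
    scores[, si] <- sig_mean - ctrl_mean
  }
  structure(list(scores = scores, bins = bins, unmatched = unmatched,
                 seed = seed),
            class = "module_scores")
}

#' @export
print.module_scores <- function(x, ...) {
  cat(sprintf("<module_scores> %d cells x %d gene sets (seed %d)\n",
              nrow(x$scores), ncol(x$scores), x$seed))
  invisible(x)
}

#' Correlate per-donor mean signature scores with age
#'
#' For each eligible cell type and gene set, averages the per-cell signature
#' score over each retained donor's cells of that type and correlates the
#' donor means with donor age (Pearson; two-sided p from the t transform with
#' n - 2 degrees of freedom).
#'
#' @param ms A `module_scores` object.
#' @param dataset The `expression_dataset` the scores came from.
#' @param eligibility Result of [eligible_celltypes()] (retained donors per
#'   kept cell type).
#' @param celltype_col Annotation column holding the cell type labels.
#' @return A tibble: `celltype`, `gene_set`, `n_donors`, `score_age_r`,
#'   `score_age_p`, `status` (`"ok"`, `"not_testable"`, `"undefined"`).
#' @export
score_age_correlation <- function(ms, dataset, eligibility,
                                  celltype_col = "celltype_minor") {
  stopifnot(inherits(ms, "module_scores"))
  ages <- stats::setNames(dataset$donors$age, dataset$donors$donor_id)
  cells <- dataset$cells
  cells$.ct <- cells[[celltype_col]]
  kept <- eligibility$kept
  rows <- purrr::map(seq_len(nrow(kept)), function(i) {
    ct <- kept$celltype[i]
    dns <- kept$retained_donors[[i]]
    sub <- cells[cells$.ct == ct & cells$donor_id %in% dns, ]
    per_set <- purrr::map(colnames(ms$scores), function(set) {
      sc <- ms$scores[sub$barcode, set]
      dm <- tapply(sc, sub$donor_id, mean)
      dm <- dm[dns[dns %in% names(dm)]]
      a <- ages[names(dm)]
      if (length(dm) < 3L || all(is.na(sc))) {
        return(tibble::tibble(celltype = ct, gene_set = set,
                              n_donors = length(dm), score_age_r = NA_real_,
                              score_age_p = NA_real_, status = "not_testable"))
      }
      if (stats::sd(dm) == 0 || stats::sd(a) == 0) {
        return(tibble::tibble(celltype = ct, gene_set = set,
                              n_donors = length(dm), score_age_r = NA_real_,
                              score_age_p = NA_real_, status = "undefined"))
      }
      ct_test <- stats::cor.test(as.numeric(dm), as.numeric(a))
      tibble::tibble(celltype = ct, gene_set = set, n_donors = length(dm),
                     score_age_r = unname(ct_test$estimate),
                     score_age_p = ct_test$p.value, status = "ok")
    })
    dplyr::bind_rows(per_set)
  })
  dplyr::bind_rows(rows)
}
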