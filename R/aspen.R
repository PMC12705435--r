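#' Configuration for an ASPEN run
#'
#' @param min_donor_fraction Minimum fraction of donors in which a cell type
#'   must be present to be analyzed (default 0.5; a type present in exactly
#'   half the donors is retained).
#' @param n_permutations Gene-sampling null draws per set size (default
#'   10000; the attainable permutation p floor is `1/(n_permutations + 1)`).
#' @param seed Integer seed governing the permutation null and control-gene
#'   draws.
#' @param weight_exponent Running-sum weight exponent (default 1).
#' @param alpha Significance threshold applied to both adjusted p-values
#'   (default 0.05).
#' @param n_bins Expression bins for control-gene matching (default 24).
#' @param n_ctrl Control genes per signature gene (default 100).
#' @param scale_factor Library-size target for log-normalization (default
#'   10000).
#' @return A list of class `aspen_config`.
#' @export
aspen_config <- function(min_donor_fraction = 0.5, n_permutations = 10000,
                         seed = 1L, weight_exponent = 1, alpha = 0.05,
                         n_bins = 24, n_ctrl = 100, scale_factor = 10000) {
  stopifnot(min_donor_fraction > 0, min_donor_fraction <= 1,
            alpha > 0, alpha < 1, n_bins >= 1, n_ctrl >= 1,
            n_permutations >= 1)
  structure(list(min_donor_fraction = min_donor_fraction,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 weight_exponent = weight_exponent, alpha = alpha,
                 n_bins = as.integer(n_bins), n_ctrl = as.integer(n_ctrl),
                 scale_factor = scale_factor),
            class = "aspen_config")
}

#' Cell-type eligibility and per-type donor retention
#'
#' A donor is retained for a cell type iff it contributes at least one cell
#' of that type; a cell type is analyzed iff the retained donors make up at
#' least `min_donor_fraction` of all donors (a type present in exactly half
#' the donors passes the default 0.5).
#'
#' @param cells Per-cell annotation tibble (`barcode`, `donor_id`, and the
#'   cell type column).
#' @param donors Donor tibble (`donor_id`, `age`).
#' @param min_donor_fraction Retention threshold (default 0.5).
#' @param celltype_col Which annotation column defines the cell types.
#' @return A list with `kept` (tibble: `celltype`, `n_donors`,
#'   `retained_donors` list-column) and `excluded` (tibble: `celltype`,
#'   `n_donors`, `reason`).
#' @export
eligible_celltypes <- function(cells, donors, min_donor_fraction = 0.5,
                               celltype_col = "celltype_minor") {
  stopifnot(nrow(donors) >= 2)
  n_total <- dplyr::n_distinct(donors$donor_id)
  presence <- cells |>
    dplyr::rename(celltype = dplyr::all_of(celltype_col)) |>
    dplyr::distinct(.data$celltype, .data$donor_id) |>
    dplyr::group_by(.data$celltype) |>
    dplyr::summarise(n_donors = dplyr::n(),
                     retained_donors = list(sort(.data$donor_id)),
                     .groups = "drop")
  keep <- presence$n_donors / n_total >= min_donor_fraction
  list(
    kept = presence[keep, ],
    excluded = presence[!keep, c("celltype", "n_donors")] |>
      dplyr::mutate(reason = sprintf(
        "present in %d/%d donors (< %.0f%%)", .data$n_donors, n_total,
        100 * min_donor_fraction))
  )
}

#' Per-donor pseudobulk mean expression for one cell type
#'
#' Averages the log-normalized expression of every gene over each retained
#' donor's cells of the given type.
#'
#' @param dataset An `expression_dataset` with a lognorm layer.
#' @param celltype Cell type label.
#' @param retained_donors Donor ids to include (each must contribute at least
#'   one cell of the type).
#' @param celltype_col Annotation column holding the labels.
#' @return A list: `means` (genes x donors dense matrix), `donors` (tibble
#'   `donor_id`, `age`, `n_cells`).
#' @export
pseudobulk_means <- function(dataset, celltype, retained_donors,
                             celltype_col = "celltype_minor") {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$lognorm)) {
    stop("dataset has no lognorm layer; run lognormalize() first",
         call. = FALSE)
  }
  if (!length(retained_donors)) {
    stop("empty retained-donor list", call. = FALSE)
  }
  cells <- dataset$cells
  sel <- cells[[celltype_col]] == celltype & cells$donor_id %in% retained_donors
  sub <- cells[sel, ]
  missing <- setdiff(retained_donors, sub$donor_id)
  if (length(missing)) {
    stop(sprintf("donor(s) with no '%s' cells: %s", celltype,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  donor_ids <- sort(unique(sub$donor_id))
  mm <- vapply(donor_ids, function(d) {
    bc <- sub$barcode[sub$donor_id == d]
    Matrix::rowMeans(dataset$lognorm[, bc, drop = FALSE])
  }, numeric(nrow(dataset$lognorm)))
  dimnames(mm) <- list(rownames(dataset$lognorm), donor_ids)
  ages <- dataset$donors$age[match(donor_ids, dataset$donors$donor_id)]
  n_cells <- as.integer(table(sub$donor_id)[donor_ids])
  list(means = mm,
       donors = tibble::tibble(donor_id = donor_ids, age = ages,
                               n_cells = n_cells))
}

#' Rank genes by the correlation of pseudobulk mean expression with age
#'
#' Computes the Pearson correlation of each gene's per-donor mean expression
#' with donor age and returns genes sorted from most positively to most
#' negatively correlated (ties broken lexicographically by gene id). Genes
#' whose correlation is undefined (zero variance across donors) or exactly
#' zero (|r| below 1e-15) are dropped into a ledger.
#'
#' @param pb Result of [pseudobulk_means()].
#' @return A list: `ranking` (named numeric vector of r, non-increasing),
#'   `dropped` (tibble `gene`, `reason`).
#' @export
gene_age_correlation <- function(pb) {
  ages <- pb$donors$age
  if (length(ages) < 3L || dplyr::n_distinct(ages) < 3L) {
    stop("need at least 3 retained donors with distinct ages", call. = FALSE)
  }
  m <- pb$means
  a <- as.numeric(ages)
  ac <- a - mean(a)
  mc <- m - rowMeans(m)
  num <- as.numeric(mc %*% ac)
  den <- sqrt(rowSums(mc^2) * sum(ac^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  names(r) <- rownames(m)
  zero_var <- is.na(r)
  zero_r <- !zero_var & abs(r) < 1e-15
  dropped <- dplyr::bind_rows(
    tibble::tibble(gene = names(r)[zero_var], reason = "zero_variance"),
    tibble::tibble(gene = names(r)[zero_r], reason = "zero_coefficient")
  )
  r <- r[!zero_var & !zero_r]
  if (!length(r)) stop("all genes dropped from the ranking", call. = FALSE)
  r <- pmin(pmax(r, -1), 1)
  ord <- order(-r, names(r), method = "radix")
  list(ranking = r[ord], dropped = dropped)
}

#' Run the dual-arm age-program enrichment analysis
#'
#' Arm 1: per eligible cell type, pseudobulk donor means are correlated with
#' age, genes are ranked by the correlation coefficient, and every gene set
#' is scored with the weighted running-sum enrichment statistic, a
#' gene-sampling permutation test (with NES) and a Welch parametric set test;
#' the two p-value families are BH-adjusted within the cell type separately
#' and a pair is significant only when both adjusted p-values fall below
#' `alpha`. Arm 2: per-cell binned-control signature scores are averaged per
#' donor and cell type and correlated with age; the magnitude of that
#' correlation accompanies each row (no significance gate on arm 2).
#'
#' @param dataset An `expression_dataset` (raw counts suffice; the lognorm
#'   layer is computed when absent).
#' @param gene_sets A `gene_set_collection` or named list.
#' @param config An [aspen_config()].
#' @param celltype_col Annotation column defining the cell types analyzed
#'   (default `"celltype_minor"`).
#' @return An object of class `aspen_result`: list with `table` (the ARP
#'   tibble: one row per eligible cell type x gene set), `excluded` (cell
#'   type exclusion ledger), `dropped_genes` (per-cell-type ranking ledger),
#'   `config`.
#' @export
run_aspen <- function(dataset, gene_sets, config = aspen_config(),
                      celltype_col = "celltype_minor") {
  stopifnot(inherits(dataset, "expression_dataset"))
  report <- validate_dataset(dataset)
  if (nrow(report)) {
    stop(paste0("dataset failed validation:\n",
                paste(utils::capture.output(print(report)), collapse = "\n")),
         call. = FALSE)
  }
  if (nrow(dataset$donors) < 3L) stop("need at least 3 donors", call. = FALSE)
  if (is.null(dataset$lognorm)) {
    dataset <- lognormalize(dataset, scale_factor = config$scale_factor)
  }
  set.seed(config$seed)

  elig <- eligible_celltypes(dataset$cells, dataset$donors,
                             config$min_donor_fraction, celltype_col)
  dropped_genes <- list()
  arm1 <- purrr::map(seq_len(nrow(elig$kept)), function(i) {
    ct <- elig$kept$celltype[i]
    dns <- elig$kept$retained_donors[[i]]
    pb <- pseudobulk_means(dataset, ct, dns, celltype_col)
    rk <- gene_age_correlation(pb)
    dropped_genes[[ct]] <<- rk$dropped
    tab <- enrich_ranking(rk$ranking, gene_sets, config$n_permutations,
                          config$weight_exponent)
    dplyr::mutate(tab, celltype = ct, n_donors_used = length(dns),
                  .before = 1)
  })
  arm1 <- dplyr::bind_rows(arm1)

  ms <- module_scores(dataset, gene_sets, n_bins = config$n_bins,
                      n_ctrl = config$n_ctrl, seed = config$seed)
  arm2 <- score_age_correlation(ms, dataset, elig, celltype_col)

  table <- arm1 |>
    dplyr::left_join(
      dplyr::select(arm2, "celltype", "gene_set", "score_age_r",
                    "score_age_p", arm2_status = "status"),
      by = c("celltype", "gene_set")) |>
    dplyr::mutate(
      significant = !is.na(.data$padj_perm) & !is.na(.data$padj_param) &
        .data$padj_perm < config$alpha & .data$padj_param < config$alpha,
      direction = dplyr::case_when(
        is.na(.data$nes) ~ NA_character_,
        .data$nes > 0 ~ "older",
        TRUE ~ "younger")) |>
    dplyr::select("celltype", "gene_set", "n_donors_used", "n_hits", "es",
                  "nes", "p_perm", "padj_perm", "t_param", "p_param",
                  "padj_param", "significant", "direction", "score_age_r",
                  "score_age_p", "leading_edge", "status", "arm2_status")

  structure(list(table = table, excluded = elig$excluded,
                 dropped_genes = dropped_genes, config = config),
            class = "aspen_result")
}

#' @export
print.aspen_result <- function(x, ...) {
  cat(sprintf(
    "<aspen_result> %d cell types x %d gene sets; %d significant pairs (alpha = %g); %d cell types excluded\n",
    dplyr::n_distinct(x$table$celltype),
    dplyr::n_distinct(x$table$gene_set),
    sum(x$table$significant, na.rm = TRUE), x$config$alpha,
    nrow(x$excluded)))
  invisible(x)
}
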