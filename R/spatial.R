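#' Remove region-inconsistent cells
#'
#' Drops likely misclassified cells: stromal-class cells (by default myCAFs,
#' iCAFs and endothelial cells) found inside tumor regions, and tumor-class
#' cells found inside stromal regions. Cells in `unknown` regions pass
#' through untouched.
#'
#' @param cells Tibble with at least `cell_type` and `region`
#'   (`"tumor"`/`"stroma"`/`"unknown"`).
#' @param stromal_classes Cell types expected only in stroma.
#' @param tumor_classes Cell types expected only in tumor regions.
#' @return The retained cells; the removed rows (with a `reason` column) are
#'   attached as attribute `"removed"`.
#' @export
region_consistency_filter <- function(cells,
                                      stromal_classes = c("myCAF", "iCAF",
                                                          "EC"),
                                      tumor_classes = "tumor") {
  require_columns(cells, c("cell_type", "region"), "cells")
  bad_stromal <- cells$cell_type %in% stromal_classes &
    cells$region == "tumor"
  bad_tumor <- cells$cell_type %in% tumor_classes & cells$region == "stroma"
  removed <- dplyr::bind_rows(
    dplyr::mutate(cells[bad_stromal, ], reason = "stromal class in tumor region"),
    dplyr::mutate(cells[bad_tumor, ], reason = "tumor class in stromal region"))
  kept <- cells[!(bad_stromal | bad_tumor), ]
  attr(kept, "removed") <- removed
  kept
}

#' Drop cores with extreme stromal content
#'
#' Excludes tissue cores whose stromal fraction is below 0.10 or above 0.90
#' (strict inequalities: the boundary values are retained).
#'
#' @param cells Cell tibble with a `core_id` column.
#' @param qc Tibble with `core_id`, `stromal_fraction`; one row per core in
#'   `cells` (a core without a QC row is an error).
#' @return The cells of passing cores; attribute `"qc"` holds the QC table
#'   with a `pass` flag.
#' @export
qc_filter_cores <- function(cells, qc) {
  require_columns(cells, "core_id", "cells")
  require_columns(qc, c("core_id", "stromal_fraction"), "qc")
  missing <- setdiff(unique(cells$core_id), qc$core_id)
  if (length(missing)) {
    stop(sprintf("core(s) without a QC row: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  qc <- dplyr::mutate(qc, pass = .data$stromal_fraction >= 0.10 &
                        .data$stromal_fraction <= 0.90)
  kept <- cells[cells$core_id %in% qc$core_id[qc$pass], ]
  attr(kept, "qc") <- qc
  kept
}

#' Fraction of query cells with a reference neighbor within a radius
#'
#' Euclidean distance, inclusive boundary (a reference at exactly `radius`
#' counts). A cell never counts as its own neighbor: identity is tracked via
#' `q_id`/`r_id`, so coincident distinct cells still count. The grid method
#' buckets reference cells into radius-sized tiles and inspects the 3x3
#' neighborhood of each query's tile; it is exact, not approximate.
#'
#' @param qx,qy Query coordinates (micrometres).
#' @param rx,ry Reference coordinates.
#' @param radius Neighborhood radius (default 30); must be non-negative.
#' @param q_id,r_id Optional cell identities for self-exclusion when query
#'   and reference sets overlap.
#' @param method `"auto"` (grid for large inputs), `"grid"` or `"brute"`.
#' @return The fraction in `[0, 1]`, or `NA` when there are no query cells
#'   (empty reference set gives 0).
#' @export
fraction_within_radius <- function(qx, qy, rx, ry, radius = 30,
                                   q_id = NULL, r_id = NULL,
                                   method = c("auto", "grid", "brute")) {
  method <- match.arg(method)
  if (radius < 0) stop("radius must be non-negative", call. = FALSE)
  nq <- length(qx); nr <- length(rx)
  if (nq == 0L) return(NA_real_)
  if (nr == 0L) return(0)
  if (method == "auto") {
    method <- if (as.double(nq) * nr <= 250000) "brute" else "grid"
  }
  has_neigh <- if (method == "brute") {
    d2 <- outer(qx, rx, "-")^2 + outer(qy, ry, "-")^2
    if (!is.null(q_id) && !is.null(r_id)) {
      same <- outer(q_id, r_id, "==")
      d2[same] <- Inf
    }
    matrixStats_rowMin(d2) <= radius^2 + 1e-9
  } else {
    grid_has_neighbor(qx, qy, rx, ry, radius, q_id, r_id)
  }
  mean(has_neigh)
}

matrixStats_rowMin <- function(m) {
  apply(m, 1, min)
}

grid_has_neighbor <- function(qx, qy, rx, ry, radius, q_id, r_id) {
  h <- max(radius, 1e-9)
  key <- function(ix, iy) paste(ix, iy, sep = ",")
  rix <- floor(rx / h); riy <- floor(ry / h)
  buckets <- split(seq_along(rx), key(rix, riy))
  qix <- floor(qx / h); qiy <- floor(qy / h)
  r2 <- radius^2 + 1e-9
  vapply(seq_along(qx), function(i) {
    for (dx in -1:1) for (dy in -1:1) {
      idx <- buckets[[key(qix[i] + dx, qiy[i] + dy)]]
      if (is.null(idx)) next
      if (!is.null(q_id) && !is.null(r_id)) {
        idx <- idx[r_id[idx] != q_id[i]]
        if (!length(idx)) next
      }
      if (any((rx[idx] - qx[i])^2 + (ry[idx] - qy[i])^2 <= r2)) return(TRUE)
    }
    FALSE
  }, logical(1))
}

#' Per-core adjacency fractions for query/reference cell type pairs
#'
#' For each core and each (query type, reference type) pair, computes the
#' fraction of query cells with at least one reference cell within `radius`
#' ([fraction_within_radius()]); cores lacking query cells of the type are
#' flagged rather than scored.
#'
#' @param cells Cell tibble with `x`, `y`, `cell_type`, `core_id`,
#'   `patient_id`, `age_group`.
#' @param pairs Tibble with columns `query`, `reference`, or a character
#'   vector like `c("CD8:tumor", "EC:myCAF")`.
#' @param radius Adjacency radius in micrometres (default 30).
#' @return A tibble: `core_id`, `patient_id`, `age_group`, `query`,
#'   `reference`, `n_query`, `n_reference`, `fraction`.
#' @export
proximity_fractions <- function(cells, pairs, radius = 30) {
  require_columns(cells, c("x", "y", "cell_type", "core_id", "patient_id",
                           "age_group"), "cells")
  pairs <- normalize_pairs(pairs)
  core_info <- dplyr::distinct(cells, .data$core_id, .data$patient_id,
                               .data$age_group)
  if (anyDuplicated(core_info$core_id)) {
    stop("a core maps to more than one patient or age group", call. = FALSE)
  }
  cells$.row <- seq_len(nrow(cells))
  grid <- tidyr::crossing(core_info, pairs)
  res <- purrr::pmap(grid, function(core_id, patient_id, age_group, query,
                                    reference) {
    core <- cells[cells$core_id == core_id, ]
    q <- core[core$cell_type == query, ]
    r <- core[core$cell_type == reference, ]
    tibble::tibble(
      core_id = core_id, patient_id = patient_id, age_group = age_group,
      query = query, reference = reference,
      n_query = nrow(q), n_reference = nrow(r),
      fraction = fraction_within_radius(q$x, q$y, r$x, r$y, radius,
                                        q_id = q$.row, r_id = r$.row))
  })
  dplyr::bind_rows(res)
}

normalize_pairs <- function(pairs) {
  if (is.character(pairs)) {
    parts <- stringr::str_split_fixed(pairs, ":", 2)
    if (any(parts[, 2] == "")) {
      stop("pairs must be 'query:reference'", call. = FALSE)
    }
    pairs <- tibble::tibble(query = parts[, 1], reference = parts[, 2])
  }
  require_columns(tibble::as_tibble(pairs), c("query", "reference"), "pairs")
}

#' Summarize core fractions at patient level
#'
#' Median over each patient's computable core fractions (average of the two
#' middle values for even core counts). Cores with no computable fraction
#' are dropped before the median.
#'
#' @param fractions Output of [proximity_fractions()].
#' @return A tibble: `patient_id`, `age_group`, `query`, `reference`,
#'   `n_cores`, `median_fraction`.
#' @export
patient_summary <- function(fractions) {
  fractions |>
    dplyr::filter(!is.na(.data$fraction)) |>
    dplyr::group_by(.data$patient_id, .data$age_group, .data$query,
                    .data$reference) |>
    dplyr::summarise(n_cores = dplyr::n(),
                     median_fraction = stats::median(.data$fraction),
                     .groups = "drop")
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison. With 12 or fewer observations in total and
#' no ties the exact null distribution is used; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param a,b Numeric samples (both non-empty).
#' @return A list: `W` (rank-sum U statistic of `a`), `p`, `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= 12 && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Compare patient-level proximity between age groups
#'
#' One Wilcoxon rank-sum test per (query, reference) comparison between the
#' old and young patients' median fractions, Benjamini–Hochberg adjusted
#' across the comparisons tested in the call. Comparisons with fewer than 2
#' patients in either group are flagged `underpowered` and not tested.
#'
#' @param summaries Output of [patient_summary()] (column `age_group` with
#'   values `"young"`/`"old"`).
#' @return An object of class `proximity_result`: list with `comparisons`
#'   (tibble: `query`, `reference`, `n_young`, `n_old`, `median_young`,
#'   `median_old`, `W`, `p`, `padj`, `direction`, `status`) and `summaries`.
#' @export
compare_groups <- function(summaries) {
  comp <- summaries |>
    dplyr::group_by(.data$query, .data$reference) |>
    dplyr::summarise(res = list({
      y <- .data$median_fraction[.data$age_group == "young"]
      o <- .data$median_fraction[.data$age_group == "old"]
      if (length(y) < 2L || length(o) < 2L) {
        list(n_young = length(y), n_old = length(o),
             median_young = stats::median(y), median_old = stats::median(o),
             W = NA_real_, p = NA_real_, status = "underpowered")
      } else {
        wt <- wilcoxon_rank_sum(o, y)
        list(n_young = length(y), n_old = length(o),
             median_young = stats::median(y), median_old = stats::median(o),
             W = wt$W, p = wt$p, status = "ok")
      }
    }), .groups = "drop") |>
    tidyr::unnest_wider("res") |>
    dplyr::mutate(
      padj = bh_adjust(.data$p),
      direction = dplyr::case_when(
        is.na(.data$median_old) | is.na(.data$median_young) ~ NA_character_,
        .data$median_old > .data$median_young ~ "older",
        .data$median_old < .data$median_young ~ "younger",
        TRUE ~ "none"))
  structure(list(comparisons = comp, summaries = summaries),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("<proximity_result> %d comparison(s); %d significant at padj < 0.05\n",
              nrow(x$comparisons),
              sum(x$comparisons$padj < 0.05, na.rm = TRUE)))
  invisible(x)
}
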