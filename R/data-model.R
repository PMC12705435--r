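#' Assemble an annotated single-cell expression dataset
#'
#' Bundles a sparse genes-by-cells count matrix with per-cell annotations and
#' a per-donor table into the container every downstream stage consumes.
#'
#' @param counts Sparse (or dense) non-negative numeric matrix, genes in rows,
#'   cells in columns. Dimnames, when present, must agree with `gene_ids` /
#'   `cell_barcodes`.
#' @param cells Data frame with one row per cell barcode; required columns
#'   `barcode`, `donor_id`, `celltype_major`, `celltype_minor`.
#' @param donors Data frame with one row per donor; required columns
#'   `donor_id`, `age` (years, positive), `subtype`.
#' @param gene_ids,cell_barcodes Character vectors naming matrix rows/columns;
#'   taken from `dimnames(counts)` when omitted.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `counts` (dgCMatrix, the raw layer), `lognorm` (NULL until
#'   [lognormalize()] is applied), `cells` (tibble) and `donors` (tibble).
#' @export
expression_dataset <- function(counts, cells, donors,
                               gene_ids = rownames(counts),
                               cell_barcodes = colnames(counts)) {
  counts <- as_dgc(counts)
  if (is.null(gene_ids) || is.null(cell_barcodes)) {
    stop("`counts` needs gene ids (rows) and cell barcodes (columns)",
         call. = FALSE)
  }
  gene_ids <- disambiguate_ids(as.character(gene_ids))
  cell_barcodes <- as.character(cell_barcodes)
  if (anyDuplicated(cell_barcodes)) {
    stop("cell barcodes must be unique", call. = FALSE)
  }
  dimnames(counts) <- list(gene_ids, cell_barcodes)
  if (any(counts@x < 0)) {
    stop("raw counts must be non-negative", call. = FALSE)
  }
  cells <- require_columns(tibble::as_tibble(cells),
                           c("barcode", "donor_id", "celltype_major",
                             "celltype_minor"), "cells")
  donors <- require_columns(tibble::as_tibble(donors),
                            c("donor_id", "age", "subtype"), "donors")
  structure(
    list(counts = counts, lognorm = NULL, cells = cells, donors = donors),
    class = "expression_dataset"
  )
}

# canonical sparse form: numeric dgCMatrix, works for base and Matrix inputs
as_dgc <- function(m) {
  m <- Matrix::Matrix(m, sparse = TRUE)
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> %d genes x %d cells, %d donors, %d minor cell types%s\n",
    nrow(x$counts), ncol(x$counts), nrow(x$donors),
    dplyr::n_distinct(x$cells$celltype_minor),
    if (is.null(x$lognorm)) " (raw only)" else " (raw + lognorm)"
  ))
  invisible(x)
}

disambiguate_ids <- function(ids) {
  if (!anyDuplicated(ids)) return(ids)
  # second occurrence of "ACTB" becomes "ACTB.1", third "ACTB.2", ...
  occ <- stats::ave(seq_along(ids), ids, FUN = seq_along) - 1L
  ifelse(occ > 0L, paste0(ids, ".", occ), ids)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("`%s` is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a MatrixMarket triplet (matrix + features + barcodes)
#'
#' Reads the three-file sparse layout common to deposited single-cell count
#' matrices: a MatrixMarket coordinate file plus per-row feature identifiers
#' and per-column cell barcodes, one per line. Feature/barcode files are
#' accepted with or without a header line; the dialect is detected by
#' comparing line counts against the matrix dimensions. Duplicate gene
#' identifiers are disambiguated by suffixing an occurrence index
#' (`ACTB`, `ACTB.1`, ...).
#'
#' @param matrix_path Path to the `.mtx` coordinate file.
#' @param features_path Path to the feature (gene) id file; first whitespace- or
#'   tab-separated token of each line is used.
#' @param barcodes_path Path to the barcode file, one barcode per line.
#'
#' @return A list with `counts` (dgCMatrix), `gene_ids`, `barcodes`.
#' @export
read_matrix_triplet <- function(matrix_path, features_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  if (any(m@x < 0)) {
    stop(sprintf("matrix file '%s' contains negative entries", matrix_path),
         call. = FALSE)
  }
  feats <- read_id_column(features_path, nrow(m))
  if (length(feats) != nrow(m)) {
    stop(sprintf(
      "dimension mismatch: features file '%s' has %d ids but matrix '%s' has %d rows",
      features_path, length(feats), matrix_path, nrow(m)), call. = FALSE)
  }
  bcs <- read_id_column(barcodes_path, ncol(m))
  if (length(bcs) != ncol(m)) {
    stop(sprintf(
      "dimension mismatch: barcodes file '%s' has %d ids but matrix '%s' has %d columns",
      barcodes_path, length(bcs), matrix_path, ncol(m)), call. = FALSE)
  }
  gene_ids <- disambiguate_ids(feats)
  m <- as_dgc(m)
  dimnames(m) <- list(gene_ids, bcs)
  list(counts = m, gene_ids = gene_ids, barcodes = bcs)
}

# First token per line; drops one header line iff that reconciles the length
# with the expected dimension AND the first token reads like a column header
# (so an over-long id file still surfaces as a dimension mismatch).
read_id_column <- function(path, expected) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  ids <- stringr::str_split_i(lines, "[\t ]", 1)
  looks_header <- length(ids) > 1L &&
    grepl("^(gene|feature|symbol|ensembl|id|barcode|cell)",
          ids[1], ignore.case = TRUE) &&
    !ids[1] %in% ids[-1]
  if (length(ids) == expected + 1L && looks_header) ids <- ids[-1L]
  ids
}

#' Write a MatrixMarket triplet
#'
#' Inverse of [read_matrix_triplet()]: writes `matrix.mtx`, `features.tsv`
#' and `barcodes.tsv` (no header lines) into `dir`.
#'
#' @param counts Sparse matrix with gene ids as rownames and barcodes as
#'   colnames.
#' @param dir Output directory, created if absent.
#' @return Invisibly, the three file paths.
#' @export
write_matrix_triplet <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(methods::as(counts, "TsparseMatrix"), paths[1])
  readr::write_lines(rownames(counts), paths[2])
  readr::write_lines(colnames(counts), paths[3])
  invisible(paths)
}

#' Read a GMT gene set collection
#'
#' Parses the MSigDB tab-separated dialect: each line is
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members within
#' a set are dropped (first occurrence kept); duplicate set names are an
#' error.
#'
#' @param path Path to the `.gmt` file.
#' @param label Provenance label stored on the collection (e.g. `"Hallmark"`).
#' @return A named list of character vectors of class `gene_set_collection`,
#'   with attribute `label`.
#' @export
read_gmt <- function(path, label = "custom") {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- stringr::str_split(lines, "\t")
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("GMT parse error at line %d of '%s': fewer than 3 fields",
                 bad[1], path), call. = FALSE)
  }
  names_ <- purrr::map_chr(fields, 1)
  if (anyDuplicated(names_)) {
    dup <- names_[duplicated(names_)][1]
    stop(sprintf("duplicate gene set name '%s' in '%s'", dup, path),
         call. = FALSE)
  }
  sets <- purrr::map(fields, ~ unique(.x[-(1:2)]))
  sets <- purrr::map(sets, ~ .x[nzchar(.x)])
  if (any(lengths(sets) == 0L)) {
    stop("GMT contains a set with no members after de-duplication",
         call. = FALSE)
  }
  gene_set_collection(stats::setNames(sets, names_), label = label)
}

#' Construct a gene set collection from a named list
#'
#' @param sets Named list of character vectors (set name -> member gene ids).
#' @param label Provenance label.
#' @return The list, classed `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, label = "custom") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("set names must be unique", call. = FALSE)
  sets <- purrr::map(sets, unique)
  if (any(lengths(sets) == 0L)) stop("empty gene set", call. = FALSE)
  structure(sets, class = c("gene_set_collection", "list"), label = label)
}

#' Write a gene set collection as GMT
#' @param sets A `gene_set_collection` or named list.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::imap_chr(unclass(sets), function(members, nm) {
    paste(c(nm, "na", members), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Log-normalize raw counts
#'
#' Per-cell library-size normalization followed by a log transform:
#' `log1p(count / cell_total * scale_factor)` (natural log by default). The
#' raw layer is retained alongside.
#'
#' @param dataset An `expression_dataset` with a raw layer.
#' @param scale_factor Target library size (default 10000).
#' @param base Log base; `exp(1)` (natural log) by default.
#' @return The dataset with a `lognorm` layer added.
#' @export
lognormalize <- function(dataset, scale_factor = 10000, base = exp(1)) {
  stopifnot(inherits(dataset, "expression_dataset"))
  totals <- Matrix::colSums(dataset$counts)
  if (any(totals <= 0)) {
    bad <- colnames(dataset$counts)[totals <= 0]
    stop(sprintf("cells with zero total count: %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  ln <- methods::as(dataset$counts, "TsparseMatrix")
  ln@x <- log1p(ln@x / totals[ln@j + 1L] * scale_factor) / log(base)
  dataset$lognorm <- methods::as(ln, "CsparseMatrix")
  dataset
}

#' Validate dataset invariants
#'
#' Reports (never throws) on cross-table consistency: barcodes present in the
#' matrix but not the annotations and vice versa, donors referenced by cells
#' but absent from the donor table, donors with missing or non-positive ages,
#' and non-finite matrix values.
#'
#' @param dataset An `expression_dataset`.
#' @return A tibble with columns `check`, `item`; zero rows iff the dataset
#'   is internally consistent.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  mat_bc <- colnames(dataset$counts)
  ann_bc <- dataset$cells$barcode
  problems <- list(
    tibble::tibble(check = "barcode_missing_from_annotations",
                   item = setdiff(mat_bc, ann_bc)),
    tibble::tibble(check = "barcode_missing_from_matrix",
                   item = setdiff(ann_bc, mat_bc)),
    tibble::tibble(check = "donor_missing_from_donor_table",
                   item = setdiff(dataset$cells$donor_id,
                                  dataset$donors$donor_id))
  )
  bad_age <- dataset$donors$donor_id[
    is.na(dataset$donors$age) | dataset$donors$age <= 0]
  problems <- c(problems, list(
    tibble::tibble(check = "donor_age_missing_or_nonpositive",
                   item = bad_age)))
  if (length(dataset$counts@x) && any(!is.finite(dataset$counts@x))) {
    problems <- c(problems, list(
      tibble::tibble(check = "nonfinite_counts", item = "counts")))
  }
  if (!is.null(dataset$lognorm) &&
      length(dataset$lognorm@x) &&
      (any(!is.finite(dataset$lognorm@x)) || any(dataset$lognorm@x < 0))) {
    problems <- c(problems, list(
      tibble::tibble(check = "invalid_lognorm_values", item = "lognorm")))
  }
  dplyr::bind_rows(problems)
}
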