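#' Configuration for a synthetic single-cell cohort
#'
#' Defaults emulate a small annotated tumor atlas: 8 donors aged 35–85,
#' 6 minor cell types nested in 3 major types, ~30 cells per donor and type,
#' 2000 genes with lognormal baseline abundances, negative-binomial counts
#' (shared dispersion 0.5) and per-cell library-size factors. Planted
#' programs multiply the expected expression of a gene set's members, in one
#' cell type, by `exp(beta * z(age))` where `z` is the standardized donor
#' age.
#'
#' @param n_donors Number of donors.
#' @param ages Explicit donor ages, or NULL to draw uniformly on
#'   `age_range`.
#' @param age_range Age range for uniform sampling (years).
#' @param celltypes Named numeric vector: minor cell type -> expected cells
#'   per donor.
#' @param major_of Named character vector mapping minor to major types
#'   (defaults to a round-robin assignment over 3 majors).
#' @param celltype_age_slope Named numeric vector (minor type -> slope):
#'   expected cell count is multiplied by `exp(slope * z(age))`, for planting
#'   composition trends. Default: no trend.
#' @param n_genes Gene universe size.
#' @param base_mean_log_sd Spread of the lognormal baseline gene means.
#' @param libsize_factor Multiplier on per-cell expected totals.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param programs Tibble (or data frame) of planted programs with columns
#'   `celltype`, `gene_set`, `beta`; `gene_set` names entries of
#'   `gene_sets`.
#' @param gene_sets Named list of gene-id vectors over the simulated universe
#'   (`g0001`, ...). Default: 10 disjoint sets of 50 genes.
#' @param subtype Cohort subtype label stamped on every donor.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_donors = 8, ages = NULL,
                              age_range = c(35, 85),
                              celltypes = NULL, major_of = NULL,
                              celltype_age_slope = NULL,
                              n_genes = 2000, base_mean_log_sd = 1,
                              libsize_factor = 1, dispersion = 0.5,
                              programs = NULL, gene_sets = NULL,
                              subtype = "TNBC") {
  if (is.null(celltypes)) {
    celltypes <- stats::setNames(rep(30, 6), paste0("ct", 1:6))
  }
  if (is.null(major_of)) {
    major_of <- stats::setNames(
      paste0("major", ((seq_along(celltypes) - 1) %% 3) + 1),
      names(celltypes))
  }
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  if (is.null(gene_sets)) {
    n_sets <- min(10L, n_genes %/% 50L)
    gene_sets <- stats::setNames(
      purrr::map(seq_len(n_sets),
                 ~ gene_ids[((.x - 1) * 50 + 1):(.x * 50)]),
      paste0("SET_", seq_len(n_sets)))
  }
  if (is.null(programs)) {
    programs <- tibble::tibble(celltype = character(), gene_set = character(),
                               beta = numeric())
  }
  programs <- tibble::as_tibble(programs)
  if (nrow(programs)) {
    stopifnot(all(programs$gene_set %in% names(gene_sets)),
              all(programs$celltype %in% names(celltypes)),
              all(is.finite(programs$beta)))
    bad <- purrr::map_lgl(gene_sets[programs$gene_set],
                          ~ !length(intersect(.x, gene_ids)))
    if (any(bad)) {
      stop("planted gene set disjoint from the gene universe", call. = FALSE)
    }
  }
  structure(list(n_donors = n_donors, ages = ages, age_range = age_range,
                 celltypes = celltypes, major_of = major_of,
                 celltype_age_slope = celltype_age_slope,
                 n_genes = n_genes, gene_ids = gene_ids,
                 base_mean_log_sd = base_mean_log_sd,
                 libsize_factor = libsize_factor, dispersion = dispersion,
                 programs = programs, gene_sets = gene_sets,
                 subtype = subtype),
            class = "simulation_config")
}

#' Simulate an annotated single-cell cohort with planted age programs
#'
#' Draws donor ages, per-donor cell counts per type (Poisson around the
#' configured expectations, optionally age-modulated), and gene-wise
#' negative-binomial counts with cell-specific size factors. For each
#' planted program the expected expression of the set's genes in the
#' target cell type is multiplied by `exp(beta * z(age))`. Fully reproducible
#' from `seed`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list: `dataset` (an [expression_dataset()]), `gene_sets`
#'   (a `gene_set_collection`), `truth` (list of class `simulation_truth`
#'   with the planted programs and composition trends).
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  n_d <- config$n_donors
  ages <- config$ages %||% stats::runif(n_d, config$age_range[1],
                                        config$age_range[2])
  stopifnot(length(ages) == n_d)
  donor_ids <- sprintf("D%02d", seq_len(n_d))
  z_age <- if (stats::sd(ages) > 0) (ages - mean(ages)) / stats::sd(ages)
           else rep(0, n_d)

  base_mu <- exp(stats::rnorm(config$n_genes, meanlog_center(),
                              config$base_mean_log_sd))
  base_mu <- base_mu / sum(base_mu) * 2000 * config$libsize_factor

  cts <- names(config$celltypes)
  # per-donor expected counts, optionally age-modulated for composition tests
  exp_counts <- outer(rep(1, n_d), config$celltypes)
  rownames(exp_counts) <- donor_ids
  if (!is.null(config$celltype_age_slope)) {
    for (ct in names(config$celltype_age_slope)) {
      exp_counts[, ct] <- exp_counts[, ct] *
        exp(config$celltype_age_slope[[ct]] * z_age)
    }
  }
  n_cells_dt <- matrix(stats::rpois(length(exp_counts), exp_counts),
                       nrow = n_d, dimnames = dimnames(exp_counts))
  n_cells_dt[] <- pmax(n_cells_dt, 1L)  # every donor contributes >=1 cell

  cell_tabs <- list(); count_cols <- list(); bc_counter <- 0L
  size <- 1 / config$dispersion
  for (d in seq_len(n_d)) {
    for (ct in cts) {
      nc <- n_cells_dt[d, ct]
      mu_g <- base_mu
      pl <- config$programs[config$programs$celltype == ct, ]
      if (nrow(pl)) {
        for (k in seq_len(nrow(pl))) {
          gs <- config$gene_sets[[pl$gene_set[k]]]
          mu_g[match(gs, config$gene_ids)] <-
            mu_g[match(gs, config$gene_ids)] * exp(pl$beta[k] * z_age[d])
        }
      }
      sf <- exp(stats::rnorm(nc, 0, 0.2))
      mu_mat <- outer(mu_g, sf)
      cnt <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat, size = size),
                    nrow = config$n_genes)
      bcs <- sprintf("BC%06d", bc_counter + seq_len(nc))
      bc_counter <- bc_counter + nc
      colnames(cnt) <- bcs
      count_cols[[length(count_cols) + 1L]] <- cnt
      cell_tabs[[length(cell_tabs) + 1L]] <- tibble::tibble(
        barcode = bcs, donor_id = donor_ids[d],
        celltype_major = unname(config$major_of[[ct]]), celltype_minor = ct)
    }
  }
  counts <- as_dgc(do.call(cbind, count_cols))
  rownames(counts) <- config$gene_ids
  cells <- dplyr::bind_rows(cell_tabs)
  donors <- tibble::tibble(donor_id = donor_ids, age = ages,
                           subtype = config$subtype)
  ds <- expression_dataset(counts, cells, donors)
  truth <- structure(list(
    programs = config$programs,
    composition_trends = config$celltype_age_slope,
    ages = stats::setNames(ages, donor_ids), seed = seed),
    class = "simulation_truth")
  list(dataset = ds,
       gene_sets = gene_set_collection(config$gene_sets, label = "synthetic"),
       truth = truth)
}

meanlog_center <- function() 0

#' Simulate cohort-stratified ligand–receptor interaction tables
#'
#' Baseline probabilities are drawn per (pathway, source, target,
#' ligand–receptor pair) and shared between cohorts up to lognormal noise;
#' a planted bias multiplies one cohort's probabilities for one pathway by
#' `bias_factor`. Interaction p-values are drawn so that biased nodes are
#' significant (p < 0.01) in the favored cohort.
#'
#' @param n_celltypes Number of cell types (source x target combinations all
#'   present, so a pathway's frequency is `n_celltypes^2`).
#' @param n_pathways Number of pathways.
#' @param pairs_per_pathway Ligand–receptor pairs per pathway.
#' @param biased_pathway Name of the pathway to bias (`"PW1"` style), or NULL
#'   for a fully exchangeable table.
#' @param biased_cohort Cohort favored by the bias (default `"old"`).
#' @param bias_factor Multiplicative probability bias (default 2).
#' @param noise_sd Lognormal noise sd between cohorts (default 0.1).
#' @param seed Integer seed.
#' @return A list: `records` (tibble in the interaction schema), `truth`
#'   (list with the planted bias).
#' @export
simulate_interactions <- function(n_celltypes = 5, n_pathways = 8,
                                  pairs_per_pathway = 3,
                                  biased_pathway = "PW1",
                                  biased_cohort = "old", bias_factor = 2,
                                  noise_sd = 0.1, seed = 1L) {
  stopifnot(n_celltypes >= 2, n_pathways >= 1)
  set.seed(seed)
  types <- paste0("CT", seq_len(n_celltypes))
  pws <- paste0("PW", seq_len(n_pathways))
  grid <- tidyr::crossing(pathway = pws, source = types, target = types,
                          pair_i = seq_len(pairs_per_pathway))
  grid$lr_pair <- paste0(grid$pathway, "_L", grid$pair_i, "-R", grid$pair_i)
  grid$base <- stats::rlnorm(nrow(grid), log(0.02), 0.5)
  young <- grid |>
    dplyr::mutate(cohort = "young",
                  prob = .data$base * exp(stats::rnorm(dplyr::n(), 0,
                                                       noise_sd)))
  old <- grid |>
    dplyr::mutate(cohort = "old",
                  prob = .data$base * exp(stats::rnorm(dplyr::n(), 0,
                                                       noise_sd)))
  if (!is.null(biased_pathway)) {
    stopifnot(biased_pathway %in% pws, biased_cohort %in% c("young", "old"))
    if (biased_cohort == "old") {
      old$prob[old$pathway == biased_pathway] <-
        old$prob[old$pathway == biased_pathway] * bias_factor
    } else {
      young$prob[young$pathway == biased_pathway] <-
        young$prob[young$pathway == biased_pathway] * bias_factor
    }
  }
  records <- dplyr::bind_rows(young, old)
  favored <- if (is.null(biased_pathway)) rep(FALSE, nrow(records)) else
    records$pathway == biased_pathway & records$cohort == biased_cohort
  records$pval <- ifelse(favored,
                         stats::runif(nrow(records), 0, 0.009),
                         stats::runif(nrow(records), 0, 1))
  records <- dplyr::select(records, "cohort", "source", "target", "pathway",
                           "lr_pair", "prob", "pval")
  truth <- list(biased_pathway = biased_pathway,
                biased_cohort = biased_cohort,
                bias_factor = bias_factor, seed = seed)
  list(records = records, truth = truth)
}

#' Simulate imaged tissue cores with optional spatial attraction
#'
#' Reference cells follow a homogeneous Poisson process over each core's
#' window (optionally padded by `pad` on every side so the closed-form null
#' `1 - exp(-lambda * pi * r^2)` holds free of edge effects for queries in
#' the inner window). Query cells are either an independent Poisson process
#' (null) or offspring displaced from random reference parents by Gaussian
#' scatter `sigma` (attraction). Cores belong to patients; patients belong
#' to age groups; attraction can be planted in one group only.
#'
#' @param n_patients_per_group Patients per age group.
#' @param cores_per_patient Cores per patient.
#' @param window Side length of the square core window (micrometres).
#' @param lambda_ref Reference intensity (cells per square micrometre).
#' @param n_query Query cells per core.
#' @param attraction_sigma Gaussian offspring scatter in micrometres, or NULL
#'   for independent placement.
#' @param attraction_group `"old"`, `"young"` or `"both"`: which age group
#'   receives the attraction (others stay null).
#' @param query_type,reference_type Cell type labels emitted.
#' @param pad Padding margin for the reference process (default 0).
#' @param stromal_range Range the per-core stromal fraction is drawn from.
#' @param seed Integer seed.
#' @return A list: `cells` (tibble: `x`, `y`, `cell_type`, `core_id`,
#'   `patient_id`, `age_group`, `region`), `qc` (tibble: `core_id`,
#'   `stromal_fraction`), `truth`.
#' @export
simulate_cores <- function(n_patients_per_group = 5, cores_per_patient = 2,
                           window = 600, lambda_ref = 5e-4, n_query = 60,
                           attraction_sigma = NULL,
                           attraction_group = "both",
                           query_type = "CD8", reference_type = "tumor",
                           pad = 0, stromal_range = c(0.2, 0.8),
                           seed = 1L) {
  stopifnot(window > 0, lambda_ref > 0, pad >= 0)
  set.seed(seed)
  groups <- c("young", "old")
  rows <- list(); qc <- list()
  for (g in groups) {
    attract <- !is.null(attraction_sigma) &&
      (attraction_group == "both" || attraction_group == g)
    for (p in seq_len(n_patients_per_group)) {
      pid <- sprintf("%s_P%02d", g, p)
      for (cc in seq_len(cores_per_patient)) {
        cid <- sprintf("%s_C%d", pid, cc)
        side <- window + 2 * pad
        n_ref <- stats::rpois(1, lambda_ref * side^2)
        rx <- stats::runif(n_ref, -pad, window + pad)
        ry <- stats::runif(n_ref, -pad, window + pad)
        if (attract && n_ref > 0) {
          parent <- sample.int(n_ref, n_query, replace = TRUE)
          qx <- rx[parent] + stats::rnorm(n_query, 0, attraction_sigma)
          qy <- ry[parent] + stats::rnorm(n_query, 0, attraction_sigma)
        } else {
          qx <- stats::runif(n_query, 0, window)
          qy <- stats::runif(n_query, 0, window)
        }
        sf <- stats::runif(1, stromal_range[1], stromal_range[2])
        core_cells <- tibble::tibble(
          x = c(rx, qx), y = c(ry, qy),
          cell_type = c(rep(reference_type, n_ref),
                        rep(query_type, n_query)),
          core_id = cid, patient_id = pid, age_group = g,
          region = ifelse(stats::runif(n_ref + n_query) < sf,
                          "stroma", "tumor"))
        rows[[length(rows) + 1L]] <- core_cells
        qc[[length(qc) + 1L]] <- tibble::tibble(core_id = cid,
                                                stromal_fraction = sf)
      }
    }
  }
  truth <- list(attraction_sigma = attraction_sigma,
                attraction_group = attraction_group,
                lambda_ref = lambda_ref, window = window, pad = pad,
                seed = seed)
  list(cells = dplyr::bind_rows(rows), qc = dplyr::bind_rows(qc),
       truth = truth)
}

#' Write simulated outputs as plain-text fixtures
#'
#' Persists whatever the generators produced — the expression triplet
#' (matrix.mtx / features.tsv / barcodes.tsv), cells.csv, donors.csv,
#' sets.gmt, interaction records, spatial cells and QC — plus a
#' `truth.json` ledger, such that the files round-trip through the package's
#' readers.
#'
#' @param sim Output of [simulate_cohort()], [simulate_interactions()] or
#'   [simulate_cores()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) {
      stop(sprintf("cannot create directory '%s'", dir), call. = FALSE)
    }
  }
  paths <- character()
  if (!is.null(sim$dataset)) {
    paths <- c(paths, write_matrix_triplet(sim$dataset$counts, dir))
    readr::write_csv(sim$dataset$cells, file.path(dir, "cells.csv"))
    readr::write_csv(sim$dataset$donors, file.path(dir, "donors.csv"))
    write_gmt(sim$gene_sets, file.path(dir, "sets.gmt"))
    paths <- c(paths, file.path(dir, c("cells.csv", "donors.csv",
                                       "sets.gmt")))
  }
  if (!is.null(sim$records)) {
    readr::write_csv(sim$records, file.path(dir, "records.csv"))
    paths <- c(paths, file.path(dir, "records.csv"))
  }
  if (!is.null(sim$cells) && !is.null(sim$qc)) {
    readr::write_csv(sim$cells, file.path(dir, "spatial_cells.csv"))
    readr::write_csv(sim$qc, file.path(dir, "core_qc.csv"))
    paths <- c(paths, file.path(dir, c("spatial_cells.csv", "core_qc.csv")))
  }
  truth <- sim$truth
  if (inherits(truth, "simulation_truth")) truth <- unclass(truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(paths, file.path(dir, "truth.json"))
  invisible(paths)
}
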