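#' Total interaction strength per cell type, role and cohort
#'
#' Sums ligand–receptor interaction probabilities over partners for every
#' cell type acting as source and as target, per cohort. Combinations with
#' no records get strength 0; a homotypic record (A to A) counts toward both
#' A-as-source and A-as-target.
#'
#' @param records Interaction tibble with columns `cohort` (`"young"` /
#'   `"old"`), `source`, `target`, `pathway`, `lr_pair`, `prob`, `pval`.
#' @return A tibble: `celltype`, `role` (`"source"`/`"target"`), `cohort`,
#'   `strength`, complete over observed cell types x roles x cohorts.
#' @export
aggregate_strengths <- function(records) {
  check_records(records)
  long <- dplyr::bind_rows(
    dplyr::transmute(records, celltype = .data$source, role = "source",
                     cohort = .data$cohort, prob = .data$prob),
    dplyr::transmute(records, celltype = .data$target, role = "target",
                     cohort = .data$cohort, prob = .data$prob))
  all_types <- sort(unique(c(records$source, records$target)))
  long |>
    dplyr::group_by(.data$celltype, .data$role, .data$cohort) |>
    dplyr::summarise(strength = sum(.data$prob), .groups = "drop") |>
    tidyr::complete(celltype = all_types, role = c("source", "target"),
                    cohort = unique(records$cohort),
                    fill = list(strength = 0))
}

check_records <- function(records) {
  require_columns(records, c("cohort", "source", "target", "pathway",
                             "lr_pair", "prob", "pval"), "records")
  bad <- setdiff(unique(records$cohort), c("young", "old"))
  if (length(bad)) {
    stop(sprintf("invalid cohort label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.finite(records$prob)) || any(records$prob < 0)) {
    stop("interaction probabilities must be finite and non-negative",
         call. = FALSE)
  }
  invisible(records)
}

#' Select high-strength cell types from cohort interaction strengths
#'
#' Per role, the selection threshold is the sum of the two cohorts'
#' mean-over-cell-types strengths: `T_role = mean(strength young) +
#' mean(strength old)`. A cell type qualifies when its strength strictly
#' exceeds the role threshold in either cohort for either role. Manual
#' exclusions are applied afterwards, with reasons recorded.
#'
#' @param strengths Output of [aggregate_strengths()] (both cohorts present).
#' @param manual_exclusions Named character vector: cell type -> reason; or a
#'   bare character vector (reason `"manual exclusion"`).
#' @return A list: `selected` (character vector), `thresholds` (tibble
#'   `role`, `threshold`), `excluded` (tibble `celltype`, `reason`),
#'   `strengths` (the input, with a `selected` flag column).
#' @export
select_cell_types <- function(strengths, manual_exclusions = character()) {
  if (length(setdiff(c("young", "old"), unique(strengths$cohort)))) {
    stop("both cohorts must be present to form the selection threshold",
         call. = FALSE)
  }
  thresholds <- strengths |>
    dplyr::group_by(.data$role, .data$cohort) |>
    dplyr::summarise(m = mean(.data$strength), .groups = "drop") |>
    dplyr::group_by(.data$role) |>
    dplyr::summarise(threshold = sum(.data$m), .groups = "drop")
  flagged <- strengths |>
    dplyr::left_join(thresholds, by = "role") |>
    dplyr::mutate(qualifies = .data$strength > .data$threshold)
  auto <- flagged |>
    dplyr::group_by(.data$celltype) |>
    dplyr::summarise(selected = any(.data$qualifies), .groups = "drop")
  selected <- auto$celltype[auto$selected]
  if (is.null(names(manual_exclusions)) && length(manual_exclusions)) {
    manual_exclusions <- stats::setNames(
      rep("manual exclusion", length(manual_exclusions)), manual_exclusions)
  }
  excl <- tibble::tibble(celltype = names(manual_exclusions) %||% character(),
                         reason = unname(manual_exclusions))
  excl <- excl[excl$celltype %in% selected, ]
  selected <- setdiff(selected, excl$celltype)
  list(selected = selected, thresholds = thresholds, excluded = excl,
       strengths = dplyr::select(flagged, -"qualifies"))
}

#' Mean ligand–receptor probability per pathway, combo and cohort
#'
#' Restricts the records to source–target combinations among the selected
#' cell types and averages interaction probabilities over the ligand–receptor
#' pairs within each (pathway, source, target, cohort). Combinations a
#' pathway does not appear in yield no row (absence is not zero).
#'
#' @param records Interaction tibble (see [aggregate_strengths()]).
#' @param selected Character vector of selected cell types.
#' @return A tibble: `pathway`, `source`, `target`, `cohort`, `mean_prob`,
#'   `n_pairs`.
#' @export
pathway_mean_probabilities <- function(records, selected) {
  check_records(records)
  if (!length(selected)) stop("empty cell type selection", call. = FALSE)
  records |>
    dplyr::filter(.data$source %in% selected, .data$target %in% selected) |>
    dplyr::group_by(.data$pathway, .data$source, .data$target,
                    .data$cohort) |>
    dplyr::summarise(mean_prob = mean(.data$prob), n_pairs = dplyr::n(),
                     .groups = "drop")
}

#' Univariate logistic regression of cohort on mean pathway probability
#'
#' Fits `cohort ~ mean probability` by iteratively reweighted least squares
#' (binomial GLM; at most 25 iterations, deviance tolerance 1e-8) and reports
#' the slope with its Wald test. Perfect separation and non-convergence are
#' flagged rather than reported as spuriously extreme coefficients.
#'
#' @param x Numeric predictor (mean interaction probabilities).
#' @param y Response: 0/1, logical, or a factor/character with two levels
#'   (`"old"` coded 1 when labels are cohorts).
#' @return A list: `coefficient`, `se`, `z`, `p`, `status` (`"ok"`,
#'   `"separation"`, `"nonconvergent"`, `"not_testable"`).
#' @export
logistic_fit <- function(x, y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    stopifnot(all(y %in% c("young", "old")))
    y <- as.integer(y == "old")
  }
  y <- as.integer(y)
  if (sum(y == 0) < 2L || sum(y == 1) < 2L) {
    return(list(coefficient = NA_real_, se = NA_real_, z = NA_real_,
                p = NA_real_, status = "not_testable"))
  }
  sep <- FALSE; nonconv <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) sep <<- TRUE
      if (grepl("did not converge", msg)) nonconv <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) nonconv <- TRUE
  if (sep || nonconv) {
    return(list(coefficient = NA_real_, se = NA_real_, z = NA_real_,
                p = NA_real_,
                status = if (sep) "separation" else "nonconvergent"))
  }
  co <- summary(fit)$coefficients
  list(coefficient = co["x", "Estimate"], se = co["x", "Std. Error"],
       z = co["x", "z value"], p = co["x", "Pr(>|z|)"], status = "ok")
}

#' Fit and select pathways by regression p-value and frequency
#'
#' For each pathway, regresses cohort membership on the pathway's mean
#' probabilities over the analyzed source–target combinations
#' ([logistic_fit()]), counts how many distinct combinations the pathway
#' appears in (regardless of cohort), and selects pathways with Wald
#' `p < p_thresh` appearing in at least `min_freq` combinations.
#'
#' @param pathway_means Output of [pathway_mean_probabilities()].
#' @param p_thresh Wald p threshold (default 0.05).
#' @param min_freq Minimum combination frequency (default 15).
#' @return A tibble: `pathway`, `coefficient`, `se`, `p`, `frequency`,
#'   `selected`, `status`.
#' @export
prioritize_pathways <- function(pathway_means, p_thresh = 0.05,
                                min_freq = 15) {
  out <- pathway_means |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(
      frequency = dplyr::n_distinct(paste(.data$source, .data$target,
                                          sep = "\r")),
      fit = list(logistic_fit(.data$mean_prob, .data$cohort)),
      .groups = "drop") |>
    tidyr::unnest_wider("fit")
  out |>
    dplyr::mutate(selected = .data$status == "ok" & !is.na(.data$p) &
                    .data$p < p_thresh & .data$frequency >= min_freq) |>
    dplyr::select("pathway", "coefficient", "se", "z", "p", "frequency",
                  "selected", "status")
}

#' Classify ligand–receptor signaling nodes by cohort bias
#'
#' A node is one ligand–receptor pair between a specific source and target
#' cell type. Nodes significant (`pval < p_thresh`, default 0.01) in exactly
#' one cohort are that cohort's exclusive nodes; nodes significant in both
#' are biased toward the cohort with the larger probability when the fold
#' difference (larger/smaller; infinite when one side is absent) reaches
#' `fold`, and `shared` otherwise. Nodes significant in neither cohort are
#' labelled `not_significant`.
#'
#' @param records Interaction tibble (see [aggregate_strengths()]).
#' @param selected_pathways Optional character vector restricting the nodes
#'   to pathways of interest (default: all).
#' @param p_thresh Per-cohort significance threshold (default 0.01).
#' @param fold Minimum fold difference for a biased call (default 1.2).
#' @return A tibble: `pathway`, `lr_pair`, `source`, `target`, `prob_young`,
#'   `pval_young`, `prob_old`, `pval_old`, `fold_difference`, `class`.
#' @export
classify_nodes <- function(records, selected_pathways = NULL,
                           p_thresh = 0.01, fold = 1.2) {
  check_records(records)
  if (!is.null(selected_pathways)) {
    records <- dplyr::filter(records, .data$pathway %in% selected_pathways)
  }
  wide <- records |>
    dplyr::select("pathway", "lr_pair", "source", "target", "cohort",
                  "prob", "pval") |>
    tidyr::pivot_wider(names_from = "cohort",
                       values_from = c("prob", "pval"))
  for (col in c("prob_young", "pval_young", "prob_old", "pval_old")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide |>
    dplyr::mutate(
      sig_young = !is.na(.data$pval_young) & .data$pval_young < p_thresh,
      sig_old = !is.na(.data$pval_old) & .data$pval_old < p_thresh,
      fold_difference = dplyr::case_when(
        is.na(.data$prob_young) | is.na(.data$prob_old) ~ Inf,
        .data$prob_young == 0 & .data$prob_old == 0 ~ 1,
        pmin(.data$prob_young, .data$prob_old) == 0 ~ Inf,
        TRUE ~ pmax(.data$prob_young, .data$prob_old) /
          pmin(.data$prob_young, .data$prob_old)),
      class = dplyr::case_when(
        .data$sig_old & !.data$sig_young ~ "older-exclusive",
        .data$sig_young & !.data$sig_old ~ "younger-exclusive",
        .data$sig_old & .data$sig_young & .data$fold_difference >= fold &
          .data$prob_old > .data$prob_young ~ "older-biased",
        .data$sig_old & .data$sig_young & .data$fold_difference >= fold &
          .data$prob_young > .data$prob_old ~ "younger-biased",
        .data$sig_old & .data$sig_young ~ "shared",
        TRUE ~ "not_significant")) |>
    dplyr::select("pathway", "lr_pair", "source", "target", "prob_young",
                  "pval_young", "prob_old", "pval_old", "fold_difference",
                  "class")
}
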