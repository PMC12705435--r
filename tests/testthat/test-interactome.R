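rec <- function(cohort, source, target, prob, pval = 0.5,
                pathway = "PW", lr = "L-R") {
  tibble::tibble(cohort = cohort, source = source, target = target,
                 pathway = pathway, lr_pair = lr, prob = prob, pval = pval)
}

test_that("strength aggregation sums probabilities per role and cohort", {
  records <- dplyr::bind_rows(
    rec("young", "A", "B", 0.1), rec("young", "A", "B", 0.2),
    rec("young", "A", "A", 0.4),  # homotypic: counts for both roles
    rec("old", "B", "A", 0.3))
  st <- aggregate_strengths(records)
  g <- function(ct, role, cohort) {
    st$strength[st$celltype == ct & st$role == role & st$cohort == cohort]
  }
  expect_equal(g("A", "source", "young"), 0.1 + 0.2 + 0.4)
  expect_equal(g("A", "target", "young"), 0.4)
  expect_equal(g("B", "source", "young"), 0)   # absent combos are zero
  expect_equal(g("B", "source", "old"), 0.3)

  # brute-force check on a random table
  set.seed(61)
  rnd <- tibble::tibble(
    cohort = sample(c("young", "old"), 200, TRUE),
    source = sample(LETTERS[1:4], 200, TRUE),
    target = sample(LETTERS[1:4], 200, TRUE),
    pathway = "PW", lr_pair = "L-R",
    prob = runif(200), pval = runif(200))
  st2 <- aggregate_strengths(rnd)
  for (i in sample(nrow(st2), 12)) {
    row <- st2[i, ]
    key <- if (row$role == "source") rnd$source else rnd$target
    expect_equal(row$strength,
                 sum(rnd$prob[key == row$celltype & rnd$cohort == row$cohort]))
  }
})

test_that("cell-type selection applies the summed-cohort-means threshold", {
  strengths <- tibble::tibble(
    celltype = rep(c("A", "B"), each = 4),
    role = rep(c("source", "source", "target", "target"), 2),
    cohort = rep(c("young", "old"), 4),
    strength = c(2.0, 1.7, 0.0, 0.0,   # A
                 0.1, 0.1, 0.0, 0.0))  # B
  sel <- select_cell_types(strengths)
  # T_source = mean(young) + mean(old) = 1.05 + 0.9 = 1.95
  expect_equal(sel$thresholds$threshold[sel$thresholds$role == "source"],
               1.95)
  expect_equal(sel$selected, "A")       # 2.0 > 1.95; B nowhere near

  # all strengths equal: threshold is twice the common value, nothing passes
  flat <- dplyr::mutate(strengths, strength = 0.5)
  expect_length(select_cell_types(flat)$selected, 0L)

  # manual exclusion applies after qualification, with a reason
  sel2 <- select_cell_types(strengths, c(A = "insufficient samples"))
  expect_length(sel2$selected, 0L)
  expect_equal(sel2$excluded$reason, "insufficient samples")

  expect_error(select_cell_types(dplyr::filter(strengths,
                                               cohort == "young")),
               "both cohorts")
})

test_that("pathway means average ligand-receptor pairs and skip absent combos", {
  records <- dplyr::bind_rows(
    rec("young", "A", "B", 0.2, lr = "L1-R1"),
    rec("young", "A", "B", 0.4, lr = "L2-R2"),
    rec("old", "A", "B", 0.5, lr = "L1-R1"),
    rec("young", "A", "C", 0.9))   # C not selected -> dropped
  pm <- pathway_mean_probabilities(records, selected = c("A", "B"))
  expect_equal(nrow(pm), 2L)
  expect_equal(pm$mean_prob[pm$cohort == "young"], 0.3)
  expect_equal(pm$mean_prob[pm$cohort == "old"], 0.5)  # single pair = itself
  # no row is emitted for combos a pathway does not appear in
  expect_false(any(pm$target == "C"))
})

test_that("logistic fit matches a likelihood-grid oracle and flags separation", {
  # symmetric design: slope exactly zero
  res0 <- logistic_fit(c(1, 2, 1, 2), c(0, 1, 1, 0))
  expect_equal(res0$coefficient, 0, tolerance = 1e-8)

  # perfect separation is flagged, not reported as a huge coefficient
  res_sep <- logistic_fit(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(res_sep$status, "separation")

  # interleaved response: MLE matches the dense grid oracle
  x <- c(1, 2, 3, 4); y <- c(0, 1, 0, 1)
  res <- logistic_fit(x, y)
  oracle <- grid_logistic(x, y)
  expect_equal(res$coefficient, oracle$slope, tolerance = 1e-4)

  # a larger noisy fixture against the same oracle
  set.seed(90)
  x2 <- rnorm(40)
  y2 <- rbinom(40, 1, plogis(-0.3 + 0.8 * x2))
  res2 <- logistic_fit(x2, y2)
  oracle2 <- grid_logistic(x2, y2, b0_range = c(-5, 5), b1_range = c(-5, 5))
  expect_equal(res2$coefficient, oracle2$slope, tolerance = 1e-4)

  expect_equal(logistic_fit(c(1, 2, 3), c(0, 1, 1))$status, "not_testable")
})

test_that("pathway prioritization needs both the p and frequency gates", {
  set.seed(44)
  pm <- tidyr::crossing(source = paste0("S", 1:5), target = paste0("T", 1:5),
                        cohort = c("young", "old")) |>
    dplyr::mutate(pathway = "BIG",
                  mean_prob = ifelse(cohort == "old",
                                     runif(dplyr::n(), 0.15, 0.45),
                                     runif(dplyr::n(), 0.05, 0.30)),
                  n_pairs = 1L)
  small <- pm[1:20, ] |> dplyr::mutate(pathway = "SMALL")  # 10 combos only
  pr <- prioritize_pathways(dplyr::bind_rows(pm, small),
                            p_thresh = 0.05, min_freq = 15)
  expect_true(pr$selected[pr$pathway == "BIG"])
  expect_equal(pr$frequency[pr$pathway == "BIG"], 25)
  expect_false(pr$selected[pr$pathway == "SMALL"])   # frequency 10 < 15
})

test_that("node classification follows the exclusivity and fold rules", {
  records <- dplyr::bind_rows(
    rec("old", "A", "B", 0.05, pval = 0.005, lr = "excl"),
    rec("young", "A", "B", 0.04, pval = 0.5, lr = "excl"),
    rec("old", "A", "B", 0.06, pval = 0.005, lr = "bias"),
    rec("young", "A", "B", 0.05, pval = 0.005, lr = "bias"),
    rec("old", "A", "B", 0.055, pval = 0.005, lr = "near"),
    rec("young", "A", "B", 0.05, pval = 0.005, lr = "near"),
    rec("old", "A", "B", 0.02, pval = 0.8, lr = "none"),
    rec("young", "A", "B", 0.02, pval = 0.9, lr = "none"))
  calls <- classify_nodes(records)
  cls <- stats::setNames(calls$class, calls$lr_pair)
  expect_equal(unname(cls["excl"]), "older-exclusive")
  expect_equal(unname(cls["bias"]), "older-biased")   # fold 1.2 exactly
  expect_equal(unname(cls["near"]), "shared")         # fold 1.1 < 1.2
  expect_equal(unname(cls["none"]), "not_significant")
  expect_equal(calls$fold_difference[calls$lr_pair == "bias"], 1.2,
               tolerance = 1e-12)

  # swapping cohort labels swaps class polarity everywhere
  swapped <- dplyr::mutate(records,
                           cohort = ifelse(cohort == "old", "young", "old"))
  calls_sw <- classify_nodes(swapped)
  flip <- function(x) {
    dplyr::case_when(x == "older-exclusive" ~ "younger-exclusive",
                     x == "younger-exclusive" ~ "older-exclusive",
                     x == "older-biased" ~ "younger-biased",
                     x == "younger-biased" ~ "older-biased",
                     TRUE ~ x)
  }
  m <- match(calls$lr_pair, calls_sw$lr_pair)
  expect_equal(calls_sw$class[m], flip(calls$class))

  # classification is invariant to record order
  calls_perm <- classify_nodes(records[sample(nrow(records)), ])
  expect_equal(dplyr::arrange(calls_perm, lr_pair),
               dplyr::arrange(calls, lr_pair))
})

test_that("a planted cohort-biased pathway is recovered end to end", {
  hits <- 0L; polarity_ok <- TRUE
  for (s in 1:10) {
    sim <- simulate_interactions(biased_pathway = "PW2",
                                 biased_cohort = "old", bias_factor = 2,
                                 seed = s)
    st <- aggregate_strengths(sim$records)
    sel <- select_cell_types(st)
    types <- if (length(sel$selected) >= 2) sel$selected else
      sort(unique(sim$records$source))
    pm <- pathway_mean_probabilities(sim$records, types)
    pr <- prioritize_pathways(pm, min_freq = 15)
    if (isTRUE(pr$selected[pr$pathway == "PW2"])) {
      hits <- hits + 1L
      calls <- classify_nodes(sim$records, "PW2")
      old_like <- calls$class %in% c("older-exclusive", "older-biased")
      if (mean(old_like) <= 0.5) polarity_ok <- FALSE
    }
  }
  expect_gte(hits, 9L)
  expect_true(polarity_ok)
})
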