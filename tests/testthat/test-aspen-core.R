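test_that("donor retention and the half-of-donors rule decide eligibility", {
  donors <- tibble::tibble(donor_id = sprintf("d%02d", 1:10),
                           age = seq(35, 80, length.out = 10),
                           subtype = "TNBC")
  # typeA in 5/10 donors (exactly half: kept), typeB in 4/10 (excluded)
  cells <- dplyr::bind_rows(
    tibble::tibble(barcode = paste0("a", 1:5),
                   donor_id = sprintf("d%02d", 1:5),
                   celltype_major = "M", celltype_minor = "typeA"),
    tibble::tibble(barcode = paste0("b", 1:4),
                   donor_id = sprintf("d%02d", 1:4),
                   celltype_major = "M", celltype_minor = "typeB"))
  el <- eligible_celltypes(cells, donors)
  expect_equal(el$kept$celltype, "typeA")
  expect_equal(el$kept$retained_donors[[1]], sprintf("d%02d", 1:5))
  expect_equal(el$excluded$celltype, "typeB")
  expect_match(el$excluded$reason, "4/10")

  # a donor missing one type is excluded only from that type's retention
  cells2 <- dplyr::bind_rows(
    cells,
    tibble::tibble(barcode = paste0("c", 1:10),
                   donor_id = sprintf("d%02d", 1:10),
                   celltype_major = "M", celltype_minor = "typeC"))
  el2 <- eligible_celltypes(cells2, donors)
  expect_setequal(el2$kept$celltype, c("typeA", "typeC"))
  expect_length(
    el2$kept$retained_donors[[which(el2$kept$celltype == "typeC")]], 10)
})

test_that("pseudobulk means average lognorm values per donor and cell type", {
  ds <- lognormalize(toy_dataset())
  el <- eligible_celltypes(ds$cells, ds$donors)
  pb <- pseudobulk_means(ds, "CD4", c("d1", "d2", "d3"))
  # CD4 cells are bc1 (d1), bc3 (d2), bc5 (d3): single-cell donors, so the
  # column equals that cell's profile
  expect_equal(unname(pb$means[, "d1"]), as.numeric(ds$lognorm[, "bc1"]))
  expect_equal(pb$donors$n_cells, c(1L, 1L, 1L))

  # multi-cell donor: plain arithmetic mean
  ds2 <- ds
  ds2$cells$celltype_minor <- "CD4"
  pb2 <- pseudobulk_means(ds2, "CD4", c("d1", "d2", "d3"))
  expect_equal(unname(pb2$means[, "d1"]),
               as.numeric(Matrix::rowMeans(ds$lognorm[, c("bc1", "bc2")])))
  expect_error(pseudobulk_means(ds, "CD4", character()), "empty retained")
})

test_that("gene-age correlation ranks descending and ledgers degenerate genes", {
  pb <- list(means = matrix(c(1, 2, 3,    # r = 1
                              1, 3, 2,    # r = 0.5
                              2, 2, 2,    # zero variance
                              3, 2, 1),   # r = -1
                            nrow = 4, byrow = TRUE,
                            dimnames = list(c("gUp", "gMid", "gFlat",
                                              "gDown"), NULL)),
             donors = tibble::tibble(donor_id = c("a", "b", "c"),
                                     age = c(40, 50, 60)))
  rk <- gene_age_correlation(pb)
  expect_equal(names(rk$ranking), c("gUp", "gMid", "gDown"))
  expect_equal(unname(rk$ranking), c(1, 0.5, -1), tolerance = 1e-12)
  expect_equal(rk$dropped$gene, "gFlat")
  expect_equal(rk$dropped$reason, "zero_variance")
  expect_true(all(diff(rk$ranking) <= 0))

  pb$donors <- pb$donors[1:2, ]
  pb$means <- pb$means[, 1:2]
  expect_error(gene_age_correlation(pb), "at least 3")
})

test_that("running-sum enrichment score reproduces hand-derived cases", {
  s <- c(g1 = 3, g2 = 2, g3 = 1, g4 = -1, g5 = -2)
  top <- enrichment_score(s, c("g1", "g3"))
  expect_equal(top$es, 0.75, tolerance = 1e-12)
  expect_equal(top$leading_edge, "g1")
  bottom <- enrichment_score(s, c("g4", "g5"))
  expect_equal(bottom$es, -1.0, tolerance = 1e-12)
  expect_setequal(bottom$leading_edge, c("g4", "g5"))
  expect_error(enrichment_score(s, names(s)), "entire ranking universe")
  expect_equal(enrichment_score(s, c("zz"))$status, "empty_intersection")
})

test_that("streaming ES equals the brute-force running sum on random instances", {
  set.seed(303)
  for (i in 1:120) {
    n <- sample(20:200, 1)
    stats <- sort(rnorm(n), decreasing = TRUE)
    names(stats) <- sprintf("g%03d", 1:n)
    k <- sample(3:min(25, n - 1), 1)
    members <- sample(names(stats), k)
    es <- enrichment_score(stats, members)$es
    expect_equal(es, brute_es(stats, members), tolerance = 1e-12)
  }
})

test_that("reversing the ranking with negated statistics negates every ES", {
  set.seed(42)
  n <- 60
  stats <- sort(rnorm(n), decreasing = TRUE)
  names(stats) <- sprintf("g%02d", 1:n)
  flipped <- rev(-stats)
  for (i in 1:25) {
    members <- sample(names(stats), sample(3:15, 1))
    expect_equal(enrichment_score(flipped, members)$es,
                 -enrichment_score(stats, members)$es, tolerance = 1e-12)
  }
})

test_that("permutation p and NES follow the sign-conditional definitions", {
  # synthetic null sample with known composition
  null_es <- c(rep(0.25, 99), -0.5)
  res <- permutation_null(NULL, 2, observed_es = 0.75, null_es = null_es)
  expect_equal(res$p, 1 / 100)          # 99 same-sign nulls, none >= 0.75
  expect_equal(res$nes, 0.75 / 0.25)    # NES = ES / mean same-sign |null|
  res2 <- permutation_null(NULL, 2, observed_es = -0.4, null_es = null_es)
  expect_equal(res2$p, 2 / 2)           # single same-sign null, it is larger
  expect_equal(res2$nes, -0.4 / 0.5)
  res3 <- permutation_null(NULL, 2, observed_es = -0.4,
                           null_es = rep(0.2, 5))
  expect_equal(res3$status, "no_same_sign_null")

  # determinism under an identical seed
  s <- sort(rnorm(50), decreasing = TRUE)
  names(s) <- sprintf("g%02d", 1:50)
  set.seed(9); a <- null_es_sample(s, 5, 200)
  set.seed(9); b <- null_es_sample(s, 5, 200)
  expect_identical(a, b)
})

test_that("Welch set test matches the closed-form case and is label-symmetric", {
  s <- c(m1 = 1, m2 = 2, m3 = 3, n1 = 0, n2 = 0, n3 = 0, n4 = 0)
  res <- welch_set_test(s, c("m1", "m2", "m3"))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-6)
  expect_equal(res$df, 2, tolerance = 1e-6)
  expect_equal(res$p, 2 * stats::pt(2 * sqrt(3), 2, lower.tail = FALSE),
               tolerance = 1e-9)

  # identical multisets: t = 0, p = 1
  s2 <- c(a = 1, b = 2, c = 1, d = 2)
  res2 <- welch_set_test(s2, c("a", "b"))
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)

  # swapping group labels negates t, p unchanged
  res_swap <- welch_set_test(s, c("n1", "n2", "n3", "n4"))
  expect_equal(res_swap$t, -res$t, tolerance = 1e-12)
  expect_equal(res_swap$p, res$p, tolerance = 1e-12)

  expect_equal(welch_set_test(s, "m1")$status, "not_testable")
})

test_that("BH adjustment equals brute-force step-up on all small permutations", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.05, 0.01)), c(0.05, 0.02))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(17)
  base_ps <- list(runif(3), runif(4), runif(5), runif(6),
                  c(0.01, 0.01, 0.5, 0.5, 0.9))
  for (ps in base_ps) {
    perms <- combinat_perms(length(ps))
    for (row in seq_len(nrow(perms))) {
      p <- ps[perms[row, ]]
      expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-14)
    }
  }
})

test_that("module scores are centered, seeded, and shift with the signature", {
  set.seed(21)
  n_genes <- 60; n_cells <- 30
  counts <- matrix(rpois(n_genes * n_cells, 5) + 1, nrow = n_genes,
                   dimnames = list(sprintf("g%02d", 1:n_genes),
                                   sprintf("c%02d", 1:n_cells)))
  cells <- tibble::tibble(barcode = colnames(counts), donor_id = "d1",
                          celltype_major = "T", celltype_minor = "CD4")
  donors <- tibble::tibble(donor_id = "d1", age = 50, subtype = "TNBC")
  sets <- list(SIG = sprintf("g%02d", 1:5))

  # identical expression everywhere -> all scores zero
  ds_const <- expression_dataset(matrix(3, n_genes, n_cells,
                                        dimnames = dimnames(counts)),
                                 cells, donors)
  ds_const$lognorm <- ds_const$counts
  ms0 <- module_scores(ds_const, sets, n_bins = 4, n_ctrl = 10, seed = 3)
  expect_true(all(abs(ms0$scores) < 1e-12))

  # one bin, signature constant 2, background constant 1 -> score 1
  expr <- matrix(1, n_genes, n_cells, dimnames = dimnames(counts))
  expr[1:5, ] <- 2
  ds1 <- expression_dataset(expr, cells, donors)
  ds1$lognorm <- ds1$counts
  ms1 <- module_scores(ds1, sets, n_bins = 1, n_ctrl = 100, seed = 3)
  expect_true(all(abs(ms1$scores - 1) < 1e-12))

  # determinism under the seed
  ds <- expression_dataset(counts, cells, donors)
  ds$lognorm <- ds$counts
  msA <- module_scores(ds, sets, n_bins = 4, n_ctrl = 10, seed = 7)
  msB <- module_scores(ds, sets, n_bins = 4, n_ctrl = 10, seed = 7)
  expect_identical(msA$scores, msB$scores)

  # adding c to the signature genes shifts scores by exactly c (controls
  # exclude the signature)
  ds_shift <- ds
  shifted <- as.matrix(ds$lognorm)
  shifted[1:5, ] <- shifted[1:5, ] + 2.5
  ds_shift$lognorm <- methods::as(shifted, "CsparseMatrix")
  msS <- module_scores(ds_shift, sets, n_bins = 1, n_ctrl = 100, seed = 7)
  msR <- module_scores(ds, sets, n_bins = 1, n_ctrl = 100, seed = 7)
  expect_equal(msS$scores, msR$scores + 2.5, tolerance = 1e-9)

  expect_error(module_scores(ds, sets, n_bins = 1000, seed = 1),
               "n_bins exceeds")
})

test_that("score-age correlation recovers monotone donor trends", {
  sc <- matrix(0, nrow = 6, ncol = 1,
               dimnames = list(paste0("bc", 1:6), "S"))
  sc[, 1] <- c(0.1, 0.1, 0.2, 0.2, 0.3, 0.3)  # donor means 0.1, 0.2, 0.3
  ms <- structure(list(scores = sc, bins = integer(), unmatched = list(),
                       seed = 1L), class = "module_scores")
  ds <- toy_dataset()
  ds$cells$celltype_minor <- "CD4"
  el <- eligible_celltypes(ds$cells, ds$donors)
  res <- score_age_correlation(ms, ds, el)
  expect_equal(res$score_age_r, 1, tolerance = 1e-12)

  ms$scores[, 1] <- rev(sc[, 1])
  res2 <- score_age_correlation(ms, ds, el)
  expect_equal(res2$score_age_r, -1, tolerance = 1e-12)

  ms$scores[, 1] <- 0.5
  res3 <- score_age_correlation(ms, ds, el)
  expect_equal(res3$status, "undefined")
})

test_that("the dual gate is the AND of the two BH decisions", {
  # construct a table significant in exactly one arm and check the gate
  sim <- simulate_cohort(
    simulation_config(programs = tibble::tibble(
      celltype = "ct1", gene_set = "SET_1", beta = 0.6)), seed = 101)
  res <- run_aspen(sim$dataset, sim$gene_sets,
                   aspen_config(n_permutations = 300, seed = 5))
  tab <- tidy(res)
  expect_equal(tab$significant,
               !is.na(tab$padj_perm) & !is.na(tab$padj_param) &
                 tab$padj_perm < 0.05 & tab$padj_param < 0.05)
  one_arm <- tab$padj_perm < 0.05 & tab$padj_param >= 0.05
  expect_true(all(!tab$significant[which(one_arm)]))
  expect_true(all(tab$direction[tab$nes > 0] == "older", na.rm = TRUE))
})

test_that("a planted positive age program is detected with the right signs", {
  sim <- simulate_cohort(
    simulation_config(programs = tibble::tibble(
      celltype = "ct2", gene_set = "SET_3", beta = 0.6)), seed = 404)
  res <- run_aspen(sim$dataset, sim$gene_sets,
                   aspen_config(n_permutations = 1000, seed = 11))
  hit <- dplyr::filter(tidy(res), celltype == "ct2", gene_set == "SET_3")
  expect_true(hit$significant)
  expect_gt(hit$nes, 0)
  expect_gt(hit$score_age_r, 0)
  # the cell-type exclusion ledger stays empty when all types are ubiquitous
  expect_equal(nrow(res$excluded), 0L)
})

test_that("a cell type present in under half the donors lands in the ledger", {
  sim <- simulate_cohort(simulation_config(), seed = 77)
  ds <- sim$dataset
  # restrict ct6 to 3 of 8 donors
  drop <- ds$cells$celltype_minor == "ct6" &
    !ds$cells$donor_id %in% c("D01", "D02", "D03")
  ds$cells <- ds$cells[!drop, ]
  ds$counts <- ds$counts[, ds$cells$barcode]
  res <- run_aspen(ds, sim$gene_sets,
                   aspen_config(n_permutations = 100, seed = 2))
  expect_false("ct6" %in% res$table$celltype)
  expect_true("ct6" %in% res$excluded$celltype)
})

test_that("preranked mode shares the enrichment machinery and rejects bad input", {
  s <- c(g1 = 3, g2 = 2, g3 = 1, g4 = -1, g5 = -2)
  tab <- preranked_gsea(s, list(TOP = c("g1", "g3")),
                        n_permutations = 50, seed = 1)
  expect_equal(tab$es, 0.75, tolerance = 1e-12)

  # antisymmetry under global negation
  set.seed(8)
  stats <- rnorm(80)
  names(stats) <- sprintf("g%02d", 1:80)
  sets <- list(A = sample(names(stats), 10), B = sample(names(stats), 5))
  t1 <- preranked_gsea(stats, sets, n_permutations = 10, seed = 1)
  t2 <- preranked_gsea(-stats, sets, n_permutations = 10, seed = 1)
  expect_equal(t2$es, -t1$es, tolerance = 1e-12)

  expect_error(preranked_gsea(c(a = 1, a = 2), list(S = "a")), "unique")
  expect_error(preranked_gsea(c(a = 1, b = Inf), list(S = "a")), "finite")
})

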