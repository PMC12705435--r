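#' Weighted running-sum enrichment score
#'
#' Computes the weighted Kolmogorov–Smirnov style enrichment score of a gene
#' set against a ranked statistic vector. Walking the ranking from the top,
#' member genes ("hits") increment the running sum by
#' `|stat|^p / sum(|stat_member|^p)` and non-members decrement it by
#' `1 / (N - N_set)`; the enrichment score is the signed maximum absolute
#' deviation of the running sum from zero. Ties between an equally extreme
#' positive and negative deviation resolve to the positive one.
#'
#' @param stats Named numeric vector of ranking statistics, sorted in
#'   non-increasing order (names are gene ids).
#' @param members Character vector of gene set member ids.
#' @param weight_exponent Non-negative weight exponent `p` (default 1).
#' @return A list: `es`, `leading_edge` (member ids at or before the extremum
#'   for positive scores, at or after it for negative ones), `n_hits`, and
#'   `status` (`"ok"`, `"empty_intersection"`).
#' @export
enrichment_score <- function(stats, members, weight_exponent = 1) {
  n <- length(stats)
  hit_idx <- which(names(stats) %in% members)
  k <- length(hit_idx)
  if (k == 0L) {
    return(list(es = NA_real_, leading_edge = character(),
                n_hits = 0L, status = "empty_intersection"))
  }
  if (k == n) {
    stop("gene set covers the entire ranking universe", call. = FALSE)
  }
  es <- es_from_hits(hit_idx, abs(stats[hit_idx])^weight_exponent, n)
  hit_names <- names(stats)[hit_idx]
  leading <- if (es$es >= 0) {
    hit_names[hit_idx <= es$extremum]
  } else {
    hit_names[hit_idx >= es$extremum]
  }
  list(es = es$es, leading_edge = leading, n_hits = k, status = "ok")
}

# Running-sum extremum from hit positions only: at hit j (position q_j) the
# sum is H_j - (q_j - j) * d; the minimum of the walk occurs just before a
# hit (position q_j - 1) or at the end (value 0 by construction).
es_from_hits <- function(hit_idx, hit_wt, n) {
  d <- 1 / (n - length(hit_idx))
  total <- sum(hit_wt)
  if (total == 0) {
    # all member stats exactly zero: hits contribute nothing and the walk is
    # a pure miss descent ending at -1
    return(list(es = -1, extremum = hit_idx[1]))
  }
  H <- cumsum(hit_wt) / total
  j <- seq_along(hit_idx)
  at_hit <- H - (hit_idx - j) * d              # value at each hit position
  # just before hit j the sum is H_{j-1} - (q_j - 1 - (j-1)) * d
  before_hit <- c(0, H[-length(H)]) - (hit_idx - 1 - (j - 1)) * d
  pos <- max(at_hit)
  neg <- min(c(before_hit, 0))
  if (pos >= -neg) {
    list(es = pos, extremum = hit_idx[which.max(at_hit)])
  } else {
    list(es = neg, extremum = hit_idx[which.min(before_hit)])
  }
}

#' Gene-sampling permutation null for an enrichment score
#'
#' Draws `n_permutations` random gene sets of the observed size (without
#' replacement from the ranking universe), computes their enrichment scores,
#' and derives a sign-conditional permutation p-value and normalized
#' enrichment score (NES) for the observed score:
#' `p = (1 + #same-sign nulls at least as extreme) / (1 + #same-sign nulls)`
#' and `NES = ES / mean(|same-sign null ES|)`. The attainable p floor is
#' `1 / (n_permutations + 1)`.
#'
#' @param stats Named, non-increasing ranking statistic vector.
#' @param set_size Number of hits of the observed set within the universe.
#' @param observed_es Observed enrichment score.
#' @param n_permutations Number of null draws.
#' @param weight_exponent Weight exponent used for the observed score.
#' @param null_es Optional precomputed null ES sample for this universe and
#'   set size (from [null_es_sample()]); when supplied no drawing happens and
#'   `n_permutations` is ignored.
#' @return A list: `p`, `nes`, `n_same_sign`, `status` (`"ok"` or
#'   `"no_same_sign_null"`).
#' @export
permutation_null <- function(stats, set_size, observed_es,
                             n_permutations = 10000, weight_exponent = 1,
                             null_es = NULL) {
  if (is.null(null_es)) {
    null_es <- null_es_sample(stats, set_size, n_permutations,
                              weight_exponent)
  }
  same <- if (observed_es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  if (!length(same)) {
    return(list(p = NA_real_, nes = NA_real_, n_same_sign = 0L,
                status = "no_same_sign_null"))
  }
  p <- (1 + sum(abs(same) >= abs(observed_es))) / (1 + length(same))
  nes <- observed_es / mean(abs(same))
  list(p = p, nes = nes, n_same_sign = length(same), status = "ok")
}

#' Draw a null enrichment-score sample for one set size
#'
#' @inheritParams permutation_null
#' @param n Number of draws.
#' @return Numeric vector of null enrichment scores, length `n`.
#' @export
null_es_sample <- function(stats, set_size, n, weight_exponent = 1) {
  N <- length(stats)
  stopifnot(set_size > 0, set_size < N)
  aw <- abs(stats)^weight_exponent
  vapply(seq_len(n), function(i) {
    idx <- sort.int(sample.int(N, set_size))
    es_from_hits(idx, aw[idx], N)$es
  }, numeric(1))
}

#' Parametric gene set test (Welch two-sample t on the ranking statistic)
#'
#' Compares the ranking statistic of set members against non-members with a
#' two-sided Welch t-test (Welch–Satterthwaite degrees of freedom).
#'
#' @param stats Named numeric vector of ranking statistics.
#' @param members Member gene ids.
#' @return A list: `t`, `df`, `p`, `n_members`, `status` (`"ok"` or
#'   `"not_testable"` when either group has fewer than 2 values or both are
#'   constant).
#' @export
welch_set_test <- function(stats, members) {
  in_set <- names(stats) %in% members
  x <- stats[in_set]
  y <- stats[!in_set]
  if (length(x) < 2L || length(y) < 2L) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                n_members = length(x), status = "not_testable"))
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    # identical-variance degenerate case: equal means => no evidence
    p <- if (mean(x) == mean(y)) 1 else 0
    return(list(t = if (p == 1) 0 else Inf * sign(mean(x) - mean(y)),
                df = NA_real_, p = p, n_members = length(x), status = "ok"))
  }
  tt <- stats::t.test(x, y)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_members = length(x), status = "ok")
}

#' Benjamini–Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement;
#' input order is preserved. `NA` entries stay `NA` and do not count toward
#' the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Preranked gene set enrichment
#'
#' Applies the running-sum enrichment score, gene-sampling permutation null
#' and Welch parametric set test to an externally supplied ranking (e.g. bulk
#' log2 fold changes), with BH adjustment across the sets tested.
#'
#' @param stats Named numeric vector of finite statistics with unique names;
#'   sorted internally in non-increasing order (ties broken by name).
#' @param gene_sets A `gene_set_collection` or named list of member vectors.
#' @param n_permutations Null draws per set size (default 1000).
#' @param weight_exponent Weight exponent (default 1).
#' @param seed Optional integer seed for the permutation null.
#' @return A tibble with one row per gene set: `gene_set`, `n_hits`, `es`,
#'   `nes`, `p_perm`, `padj_perm`, `t_param`, `p_param`, `padj_param`,
#'   `leading_edge` (list column), `status`.
#' @export
preranked_gsea <- function(stats, gene_sets, n_permutations = 1000,
                           weight_exponent = 1, seed = NULL) {
  if (is.null(names(stats)) || anyDuplicated(names(stats))) {
    stop("`stats` must have unique names", call. = FALSE)
  }
  if (any(!is.finite(stats))) stop("`stats` must be finite", call. = FALSE)
  ord <- order(-stats, names(stats), method = "radix")
  stats <- stats[ord]
  if (!is.null(seed)) set.seed(seed)
  enrich_ranking(stats, gene_sets, n_permutations, weight_exponent)
}

# Shared engine: ES + permutation + Welch for every set against one ranking,
# reusing one null ES sample per distinct hit count.
enrich_ranking <- function(stats, gene_sets, n_permutations,
                           weight_exponent = 1) {
  sets <- unclass(gene_sets)
  rows <- purrr::imap(sets, function(members, nm) {
    esr <- enrichment_score(stats, members, weight_exponent)
    tibble::tibble(gene_set = nm, n_hits = esr$n_hits, es = esr$es,
                   leading_edge = list(esr$leading_edge),
                   status = esr$status)
  })
  tab <- dplyr::bind_rows(rows)

  null_cache <- new.env(parent = emptyenv())
  perm <- purrr::pmap(list(tab$es, tab$n_hits, tab$status),
                      function(es, k, status) {
    if (status != "ok" || k >= length(stats)) {
      return(list(p = NA_real_, nes = NA_real_, status = status))
    }
    key <- as.character(k)
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- null_es_sample(stats, k, n_permutations,
                                          weight_exponent)
    }
    permutation_null(stats, k, es, null_es = null_cache[[key]],
                     weight_exponent = weight_exponent)
  })
  welch <- purrr::map(sets, ~ welch_set_test(stats, .x))

  tab$nes <- purrr::map_dbl(perm, "nes")
  tab$p_perm <- purrr::map_dbl(perm, "p")
  tab$t_param <- purrr::map_dbl(welch, "t")
  tab$p_param <- purrr::map_dbl(welch, "p")
  tab$status <- dplyr::case_when(
    tab$status != "ok" ~ tab$status,
    purrr::map_chr(perm, "status") != "ok" ~ purrr::map_chr(perm, "status"),
    purrr::map_chr(welch, "status") != "ok" ~ "param_not_testable",
    TRUE ~ "ok"
  )
  tab$padj_perm <- bh_adjust(tab$p_perm)
  tab$padj_param <- bh_adjust(tab$p_param)
  dplyr::select(tab, "gene_set", "n_hits", "es", "nes", "p_perm",
                "padj_perm", "t_param", "p_param", "padj_param",
                "leading_edge", "status")
}
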