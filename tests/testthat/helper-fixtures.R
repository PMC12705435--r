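# Small hand-built fixtures shared across test files.

toy_dataset <- function() {
  counts <- Matrix::sparseMatrix(
    i = c(1, 1, 2, 3, 3, 1, 2, 3, 1, 3, 2, 3),
    j = c(1, 2, 2, 1, 3, 4, 4, 4, 5, 5, 6, 6),
    x = c(2, 1, 3, 5, 4, 1, 2, 3, 4, 2, 6, 1),
    dims = c(3, 6),
    dimnames = list(c("GA", "GB", "GC"), paste0("bc", 1:6)))
  cells <- tibble::tibble(
    barcode = paste0("bc", 1:6),
    donor_id = rep(c("d1", "d2", "d3"), each = 2),
    celltype_major = "T",
    celltype_minor = rep(c("CD4", "CD8"), 3))
  donors <- tibble::tibble(donor_id = c("d1", "d2", "d3"),
                           age = c(40, 50, 60), subtype = "TNBC")
  expression_dataset(counts, cells, donors)
}

# brute-force running-sum enrichment score: the independent oracle
brute_es <- function(stats, members, p = 1) {
  hit <- names(stats) %in% members
  n <- length(stats)
  k <- sum(hit)
  w <- abs(stats)^p
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (n - k))
  rs <- cumsum(inc)
  # signed maximum absolute deviation; an exact positive/negative tie
  # resolves to the positive deviation (the implementation's convention)
  if (max(rs) >= -min(rs)) max(rs) else min(rs)
}

# brute-force BH step-up: independent of stats::p.adjust
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# exact two-sided Wilcoxon p by full enumeration of rank assignments
enum_wilcoxon_p <- function(a, b) {
  n <- length(a) + length(b)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_along(a)])
  all_w <- apply(utils::combn(n, length(a)), 2, function(ix) sum(ix))
  mu <- length(a) * (n + 1) / 2
  min(1, mean(abs(all_w - mu) >= abs(w_obs - mu) - 1e-9))
}

# dense log-likelihood grid oracle for univariate logistic regression
grid_logistic <- function(x, y, b0_range = c(-20, 20),
                          b1_range = c(-20, 20), steps = 201) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  b0s <- seq(b0_range[1], b0_range[2], length.out = steps)
  b1s <- seq(b1_range[1], b1_range[2], length.out = steps)
  best <- c(NA, NA, -Inf)
  for (b0 in b0s) for (b1 in b1s) {
    v <- ll(b0, b1)
    if (v > best[3]) best <- c(b0, b1, v)
  }
  # refine around the coarse optimum
  for (iter in 1:3) {
    span0 <- diff(b0_range) / steps * 2
    span1 <- diff(b1_range) / steps * 2
    b0s <- seq(best[1] - span0, best[1] + span0, length.out = 41)
    b1s <- seq(best[2] - span1, best[2] + span1, length.out = 41)
    for (b0 in b0s) for (b1 in b1s) {
      v <- ll(b0, b1)
      if (v > best[3]) best <- c(b0, b1, v)
    }
    b0_range <- c(best[1] - span0, best[1] + span0)
    b1_range <- c(best[2] - span1, best[2] + span1)
    steps <- 41
  }
  list(intercept = best[1], slope = best[2], loglik = best[3])
}

# all permutations of 1..n (row per permutation)
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- combinat_perms(n - 1)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 1
  for (k in 1:n) {
    for (i in seq_len(nrow(sub))) {
      rest <- (1:n)[-k]
      out[r, ] <- c(k, rest[sub[i, ]])
      r <- r + 1
    }
  }
  out
}
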