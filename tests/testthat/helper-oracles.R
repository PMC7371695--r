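# Independent brute-force oracles. These re-derive each statistic from its
# definition with naive code, deliberately sharing nothing with the package
# implementations they check.

# Weighted trimmed mean of M-values, written out literally: sort by M and
# by A, drop the trimmed tails, average what is left with inverse-variance
# weights.
oracle_tmm_pair <- function(x, y, nx, ny, trim_m = 0.3, trim_a = 0.05) {
  keep <- x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  m <- log2((x / nx) / (y / ny))
  a <- 0.5 * log2((x / nx) * (y / ny))
  w <- 1 / ((nx - x) / (nx * x) + (ny - y) / (ny * y))
  n <- length(m)
  keep_m <- keep_a <- rep(FALSE, n)
  lo <- floor(n * trim_m) + 1; hi <- n + 1 - lo
  keep_m[order(m)[seq(lo, hi)]] <- TRUE
  lo <- floor(n * trim_a) + 1; hi <- n + 1 - lo
  keep_a[order(a)[seq(lo, hi)]] <- TRUE
  k <- keep_m & keep_a
  2^(sum(w[k] * m[k]) / sum(w[k]))
}

oracle_tmm_factors <- function(counts, ref) {
  lib <- colSums(counts)
  f <- sapply(seq_len(ncol(counts)), function(j) {
    oracle_tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref])
  })
  f / exp(mean(log(f)))
}

# Direct evaluation of the moderated-t formula, one feature at a time.
oracle_moderated_t <- function(x1, x2, s0_sq, d0) {
  n1 <- length(x1); n2 <- length(x2)
  d <- n1 + n2 - 2
  s2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / d
  s_post2 <- (d0 * s0_sq + d * s2) / (d0 + d)
  tstat <- (mean(x2) - mean(x1)) / sqrt(s_post2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(abs(tstat), df = d0 + d, lower.tail = FALSE)
  c(t = tstat, p = p)
}

# Step-up BH by the definition: adj(i) = min over j with p_j >= p_i of
# min(1, p_j * m / rank_j).
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "min")
  sapply(seq_len(m), function(i) {
    cand <- which(p >= p[i])
    min(1, min(p[cand] * m / rank(p, ties.method = "max")[cand]))
  })
}

# Sup of |ECDF difference| by looping over every pooled point.
oracle_ks_d <- function(x, y) {
  best <- 0
  for (v in c(x, y)) {
    d <- abs(mean(x <= v) - mean(y <= v))
    if (d > best) best <- d
  }
  best
}

# Hypergeometric enrichment tail by exhaustive enumeration of all
# subsets of size n1 from a universe of size N.
oracle_hyper_enrichment <- function(n1, n2, N, k) {
  universe <- seq_len(N)
  set_b <- seq_len(n2)
  subsets <- combn(N, n1)
  hits <- apply(subsets, 2, function(a) length(intersect(a, set_b)) >= k)
  mean(hits)
}

# GSEA running sum written out step by step.
oracle_gsea_es <- function(ranked_stats, hit, w) {
  N <- length(ranked_stats)
  nh <- sum(hit)
  denom_hit <- sum(abs(ranked_stats[hit])^w)
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      run <- run + if (denom_hit > 0) abs(ranked_stats[i])^w / denom_hit
                   else 1 / nh
    } else {
      run <- run - 1 / (N - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Count-and-phyper RRHO cell.
oracle_rrho_cell <- function(names_a_ranked, names_b_ranked, i, j) {
  k <- length(intersect(names_a_ranked[seq_len(i)],
                        names_b_ranked[seq_len(j)]))
  N <- length(names_a_ranked)
  -log10(max(phyper(k - 1, i, N - i, j, lower.tail = FALSE),
             .Machine$double.xmin))
}

# Tiny deterministic ChIP fixture used by several files.
make_chip_fixture <- function(seed = 1, n_loci = 60) {
  simulate_chip(n_loci = n_loci, n_reps = 2, depth = 2e5, seed = seed)
}
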