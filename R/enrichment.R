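# Gene-set and cross-study comparison statistics: GSEA running enrichment
# score, threshold-free rank-rank hypergeometric overlap (RRHO), and
# fixed-threshold set overlap against random expectation.

# Order a named statistic vector into a ranking (decreasing), breaking
# ties deterministically by gene id.
rank_genes <- function(stats) {
  if (is.null(names(stats))) stop2("statistics must be named by gene id")
  if (anyDuplicated(names(stats))) stop2("duplicate gene ids in ranked list")
  ord <- order(-stats, names(stats))
  stats[ord]
}

#' GSEA running enrichment score
#'
#' Walks the ranked list from top to bottom keeping a running sum that
#' increases by `|stat|^w / sum(|stat_hits|^w)` at genes in the set and
#' decreases by `1/(N - |S|)` at genes outside it. The enrichment score
#' (ES) is the signed maximum deviation of this running sum from zero; a
#' positive ES means the set concentrates at the top of the ranking. An
#' optional permutation p-value randomly reassigns the set labels.
#'
#' @param stats named numeric vector of ranking statistics (e.g. log2 fold
#'   changes); ranked decreasing internally, ties broken by gene id.
#' @param gene_set character vector of gene ids.
#' @param weight_exponent `w` above; 1 (default) is the classic weighted
#'   form, 0 the unweighted Kolmogorov-Smirnov-like form.
#' @param nperm number of gene-label permutations for the p-value (0 = no
#'   p-value).
#' @param seed RNG seed for the permutations.
#' @return list with `es`, `running` (profile along the ranking, named by
#'   gene), `p` (permutation p or `NA`), `n_hits`.
#' @export
gsea_es <- function(stats, gene_set, weight_exponent = 1, nperm = 0,
                    seed = NULL) {
  ranked <- rank_genes(stats)
  genes <- names(ranked)
  hits <- genes %in% gene_set
  if (!any(hits)) stop2("gene_set does not intersect the ranked list")
  if (all(hits)) stop2("gene_set covers the whole list: ES is undefined")

  compute_es <- function(hit_vec) {
    w <- abs(ranked)^weight_exponent
    hw <- w[hit_vec]
    inc <- if (sum(hw) > 0) w * hit_vec / sum(hw)
           else hit_vec / sum(hit_vec)
    dec <- (!hit_vec) / sum(!hit_vec)
    running <- cumsum(inc - dec)
    running[which.max(abs(running))]
  }

  w <- abs(ranked)^weight_exponent
  hw_sum <- sum(w[hits])
  inc <- if (hw_sum > 0) w * hits / hw_sum else hits / sum(hits)
  running <- cumsum(inc - (!hits) / sum(!hits))
  es <- running[which.max(abs(running))]

  p <- NA_real_
  if (nperm > 0) {
    n_hit <- sum(hits)
    perm_es <- with_seed(seed, vapply(seq_len(nperm), function(b) {
      idx <- sample(length(genes), n_hit)
      hv <- logical(length(genes)); hv[idx] <- TRUE
      compute_es(hv)
    }, numeric(1)))
    p <- (1 + sum(abs(perm_es) >= abs(es))) / (nperm + 1)
  }
  names(running) <- genes
  list(es = unname(es), running = running, p = p, n_hits = sum(hits))
}

#' Rank-rank hypergeometric overlap map
#'
#' Threshold-free comparison of two rankings of the same gene universe:
#' for each pair of rank thresholds (i, j) on a step grid, the overlap of
#' the top-i genes of list A with the top-j genes of list B is scored by
#' its hypergeometric enrichment p-value; the map holds `-log10 p`. A
#' concordant pair of rankings lights up along the diagonal; independent
#' rankings stay near zero everywhere.
#'
#' @param stats_A,stats_B named statistic vectors over the *same* genes.
#' @param step grid step in ranks; default `ceiling(N/100)`.
#' @return list with `map` (matrix of `-log10 p`, rows = A thresholds,
#'   cols = B thresholds, dimnames = rank cut-offs), `max` (largest value),
#'   `max_at` (its `(i, j)` rank coordinates), `step`.
#' @export
rrho_map <- function(stats_A, stats_B, step = NULL) {
  ra <- rank_genes(stats_A)
  rb <- rank_genes(stats_B)
  if (!identical(sort(names(ra)), sort(names(rb)))) {
    stop2("the two lists cover different gene universes")
  }
  N <- length(ra)
  if (is.null(step)) step <- ceiling(N / 100)
  if (step < 1 || step > N) stop2("step must be in [1, N]")

  rank_a <- setNames(seq_len(N), names(ra))
  rank_b <- setNames(seq_len(N), names(rb))[names(ra)]
  cuts <- seq(step, N, by = step)
  if (cuts[length(cuts)] < N) cuts <- c(cuts, N)

  # 2-D cumulative count of genes with rank_a <= i and rank_b <= j
  bin_a <- findInterval(rank_a, cuts, left.open = TRUE) + 1
  bin_b <- findInterval(rank_b, cuts, left.open = TRUE) + 1
  tab <- matrix(0, length(cuts), length(cuts))
  for (g in seq_len(N)) tab[bin_a[g], bin_b[g]] <- tab[bin_a[g], bin_b[g]] + 1
  k <- apply(apply(tab, 2, cumsum), 1, cumsum)
  k <- t(k)

  map <- matrix(NA_real_, length(cuts), length(cuts),
                dimnames = list(A = cuts, B = cuts))
  for (ii in seq_along(cuts)) {
    for (jj in seq_along(cuts)) {
      p <- hypergeom_overlap(cuts[ii], cuts[jj], N, k[ii, jj])$p_enrichment
      map[ii, jj] <- -log10(max(p, .Machine$double.xmin))
    }
  }
  mx <- which(map == max(map), arr.ind = TRUE)[1, ]
  list(map = map, max = max(map),
       max_at = c(A = cuts[mx[1]], B = cuts[mx[2]]), step = step)
}

#' Fixed-threshold set overlap against random expectation
#'
#' Observed overlap of two gene sets, the overlap expected by chance
#' (`|A| * |B| / N`), and exact hypergeometric p-values for depletion and
#' enrichment. An observed overlap far *below* expectation — as when two
#' perturbation studies share almost no concordant genes — is as
#' informative as one above it.
#'
#' @param set_A,set_B character vectors of gene ids.
#' @param universe_size number of genes both studies could have reported.
#' @return list with `observed`, `expected`, `p_depletion`,
#'   `p_enrichment`.
#' @export
set_overlap_test <- function(set_A, set_B, universe_size) {
  set_A <- unique(set_A); set_B <- unique(set_B)
  if (length(set_A) > universe_size || length(set_B) > universe_size) {
    stop2("set size exceeds universe size")
  }
  k <- length(intersect(set_A, set_B))
  h <- hypergeom_overlap(length(set_A), length(set_B), universe_size, k)
  list(observed = k, expected = h$expected,
       p_depletion = h$p_depletion, p_enrichment = h$p_enrichment)
}
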