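make_sample <- function(ip, input, ip_spike, input_spike, id = "s1",
                        genotype = "WT", state = "refed") {
  loci <- paste0("L", seq_along(ip))
  chip_sample(id, genotype, state, setNames(ip, loci),
              setNames(input, loci), ip_spike, input_spike)
}

test_that("spike-normalized scores follow the defining formula", {
  s <- make_sample(ip = 40, input = 10, ip_spike = 1000, input_spike = 500)
  expect_equal(unname(spike_normalized_scores(s, pseudocount = 0)), 1.0)

  # equal normalized enrichment -> score 0
  s0 <- make_sample(ip = 80, input = 40, ip_spike = 1000, input_spike = 500)
  expect_equal(unname(spike_normalized_scores(s0, pseudocount = 0)), 0)
})

test_that("scores are depth-invariant but spike-sensitive", {
  set.seed(10)
  ip <- rpois(50, 200); input <- rpois(50, 50)
  s <- make_sample(ip, input, 1500, 900)
  base <- spike_normalized_scores(s)

  # multiplying the entire IP side (loci + spike total) by c changes nothing
  s10 <- make_sample(ip * 10, input, 15000, 900)
  expect_equal(spike_normalized_scores(s10, pseudocount = 0),
               spike_normalized_scores(s, pseudocount = 0),
               tolerance = 1e-10)

  # doubling only the spike total lowers every score by exactly 1 log2 unit
  s2 <- make_sample(ip, input, 3000, 900)
  expect_equal(spike_normalized_scores(s2), base - 1, tolerance = 1e-12)

  expect_error(chip_sample("x", "WT", "refed",
                           c(L1 = 1), c(L1 = 1), 0, 10), "spike totals")
  expect_error(chip_sample("x", "WT", "refed", c(L1 = 1, L2 = 2),
                           c(L1 = 1), 10, 10), "absent from input")
})

test_that("the mixture cut-off separates well-separated modes", {
  set.seed(11)
  scores <- c(rnorm(120, -2, 0.3), rnorm(120, 4, 0.3))
  cm <- estimate_occupancy_cutoff(scores)
  expect_s3_class(cm, "cutoff_model")
  expect_gt(cm$cutoff, -1)
  expect_lt(cm$cutoff, 3)
  expect_gt(cm$cutoff, cm$means[1])
  expect_lt(cm$cutoff, cm$means[2])
  # every high-mode score is called occupied
  expect_true(all(call_occupied(scores[121:240], cm)))
  expect_false(any(call_occupied(scores[1:120], cm)))

  # parameter recovery at 2000 points
  set.seed(12)
  big <- c(rnorm(900, -1.5, 0.4), rnorm(1100, 3.5, 0.5))
  cm2 <- estimate_occupancy_cutoff(big)
  expect_equal(cm2$means, c(-1.5, 3.5), tolerance = 0.1)

  expect_error(estimate_occupancy_cutoff(rep(1, 100)), "identical")
  expect_error(estimate_occupancy_cutoff(rnorm(10)), "at least 50")
})

test_that("quantile classes are balanced and tie-break to the lower class", {
  s <- setNames(seq_len(100), paste0("L", 1:100))
  cls <- assign_quantile_classes(s, 5)
  expect_equal(as.vector(table(cls)), rep(20L, 5))
  expect_equal(unname(cls[1]), 1L)
  expect_equal(unname(cls[100]), 5L)

  s10 <- setNames(1:10, paste0("L", 1:10))
  expect_equal(as.vector(table(assign_quantile_classes(s10, 5))),
               rep(2L, 5))

  # a tie spanning a class boundary goes entirely to the lower class
  tied <- setNames(c(1, 2, 2, 3), paste0("L", 1:4))
  cls_t <- assign_quantile_classes(tied, 2)
  expect_equal(unname(cls_t), c(1L, 1L, 1L, 2L))
  expect_identical(assign_quantile_classes(tied, 2), cls_t) # deterministic

  expect_error(assign_quantile_classes(s10, 11), "exceeds")
  expect_error(assign_quantile_classes(s10, 1), ">= 2")
})

test_that("differential occupancy recovers simulated effects", {
  sim <- simulate_chip(n_loci = 500, effect_loci_fraction = 0.1,
                       effect_size = 2, n_reps = 3, rep_sd = 0.3, seed = 42)
  sc <- score_chip_samples(sim$samples)
  gr <- factor(attr(sc, "conditions")$genotype, levels = c("WT", "KO"))
  res <- differential_occupancy(sc, gr, alpha = 0.01)
  sig <- res$feature_id[res$significant & res$log2fc > 0]
  truth <- sim$truth$effect_loci
  recall <- length(intersect(sig, truth)) / length(truth)
  fdp <- if (length(sig)) length(setdiff(sig, truth)) / length(sig) else 0
  expect_gte(recall, 0.9)
  expect_lte(fdp, 0.1)

  # identical replicate matrices in both groups -> nothing significant
  null_sc <- cbind(sc[, 1:3], sc[, 1:3])
  colnames(null_sc) <- paste0("s", 1:6)
  res0 <- differential_occupancy(null_sc, gr, alpha = 0.01,
                                 prior = list(s0_sq = 0.1, d0 = 4))
  expect_equal(sum(res0$significant), 0L)

  # one replicate per group without a prior errors
  expect_error(differential_occupancy(sc[, c(1, 4)],
                                      factor(c("WT", "KO"))), "2 samples")

  # below-cutoff flag marks loci under the threshold in every sample
  res_c <- differential_occupancy(sc, gr, cutoff = 1)
  expect_equal(res_c$below_cutoff,
               unname(apply(sc < 1, 1, all)))
})

test_that("venn partition counts significant loci by direction", {
  mk <- function(ids, sig, lfc) {
    data.frame(feature_id = ids, log2fc = lfc, significant = sig,
               adj_p = ifelse(sig, 0.001, 0.5), stringsAsFactors = FALSE)
  }
  ids <- paste0("L", 1:10)
  a <- mk(ids, ids %in% paste0("L", 1:3), rep(1, 10))
  b <- mk(ids, ids %in% paste0("L", 4:7), rep(1, 10))
  expect_equal(venn_partition(a, b, "up"),
               c(A_only = 3L, both = 0L, B_only = 4L))
  expect_equal(venn_partition(a, a, "up"),
               c(A_only = 0L, both = 3L, B_only = 0L))
  # counts sum to the union of significant sets
  set.seed(13)
  a2 <- mk(ids, runif(10) < 0.5, rnorm(10))
  b2 <- mk(ids, runif(10) < 0.5, rnorm(10))
  v <- venn_partition(a2, b2, "up")
  union_size <- length(union(
    a2$feature_id[a2$significant & a2$log2fc > 0],
    b2$feature_id[b2$significant & b2$log2fc > 0]
  ))
  expect_equal(sum(v), union_size)
  expect_error(venn_partition(a, mk(paste0("M", 1:10), rep(TRUE, 10),
                                    rep(1, 10))), "universes")
})

test_that("cross-condition classes are exhaustive and exclusive", {
  mk <- function(adj_p, lfc) {
    data.frame(feature_id = paste0("L", seq_along(adj_p)), log2fc = lfc,
               adj_p = adj_p, stringsAsFactors = FALSE)
  }
  x <- mk(c(0.001, 0.5, 0.001, 0.5, 0.001), c(1, 1, 1, 1, 2))
  y <- mk(c(0.001, 0.5, 0.5, 0.001, 0.001), c(-1, 1, 1, -2, 3))
  cls <- cross_condition_classes(x, y, alpha = 0.01)
  expect_equal(unname(cls),
               c("reciprocal", "stable", "X_preferential",
                 "Y_preferential_down", "concordant"))
  # sig only in Y with positive lfc
  y2 <- mk(c(0.5, 0.001, 0.5, 0.5, 0.5), c(0, 2, 0, 0, 0))
  expect_equal(unname(cross_condition_classes(x, y2)[2]),
               "Y_preferential_up")
  # exhaustive on random inputs
  set.seed(14)
  xr <- mk(runif(200), rnorm(200))
  yr <- mk(runif(200), rnorm(200))
  cr <- cross_condition_classes(xr, yr, alpha = 0.3)
  expect_false(any(cr == ""))
  expect_length(cr, 200L)
})

test_that("group score aggregation is additive on linear scale", {
  cat <- pol3_catalog(data.frame(
    locus_id = c("a1", "a2", "b1"), chrom = "chr1",
    start = c(0L, 100L, 200L), end = c(50L, 150L, 250L), strand = "+",
    gene_class = "tRNA", isotype = c("Ile", "Ile", "Tyr"),
    anticodon = c("TAT", "TAT", "GTA"), stringsAsFactors = FALSE
  ))
  scores <- c(a1 = 1.0, a2 = 2.0, b1 = 3.0)
  agg <- aggregate_group_scores(scores, cat, "isotype")
  expect_equal(agg$cumulative_score[agg$group == "Ile"], log2(2 + 4))
  # a single-locus group keeps its locus score
  expect_equal(agg$cumulative_score[agg$group == "Tyr"], 3.0)
  # permutation within groups does not matter
  agg2 <- aggregate_group_scores(scores[c(3, 1, 2)], cat, "isotype")
  expect_equal(agg2[order(agg2$group), ]$cumulative_score,
               agg[order(agg$group), ]$cumulative_score)
  # identical score vectors give identical quartiles
  expect_equal(agg$quartile, agg2[match(agg$group, agg2$group), ]$quartile)
  # unscored group is omitted with a warning
  expect_warning(aggregate_group_scores(scores[1:2], cat, "isotype"),
                 "omitting")
})

test_that("positive score differences keep the full table", {
  wt <- c(L1 = 1, L2 = 2, L3 = 3)
  ko <- c(L1 = 2, L2 = 1.5, L3 = 4)
  d <- positive_score_differences(ko, wt)
  expect_equal(nrow(d$full), 3L)
  expect_equal(d$positive$locus_id, c("L1", "L3"))
  expect_true("L2" %in% d$full$locus_id)      # negative delta retained
  # KO = WT -> empty positive set
  expect_equal(nrow(positive_score_differences(wt, wt)$positive), 0L)
  # KO = WT + 1 -> all deltas 1
  expect_equal(positive_score_differences(wt + 1, wt)$full$delta,
               rep(1, 3))
  # occupancy restriction applies to the positive set only
  d2 <- positive_score_differences(ko, wt,
                                   occupied = c(L1 = FALSE, L2 = TRUE,
                                                L3 = TRUE))
  expect_equal(d2$positive$locus_id, "L3")
  expect_equal(nrow(d2$full), 3L)
})
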