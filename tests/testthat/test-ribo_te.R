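test_that("tag disambiguation removes common, unmapped and contaminant tags", {
  tags <- data.frame(
    tag_id = paste0("t", 1:5),
    maps_mouse = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    maps_spike = c(FALSE, TRUE, TRUE, FALSE, FALSE),
    transcript_id = c("m1", "m2", "d1", NA, "m3"),
    feature_class = c("CDS", "CDS", "CDS", "CDS", "rRNA"),
    stringsAsFactors = FALSE
  )
  expect_message(out <- disambiguate_tags(tags), "neither genome")
  expect_equal(out$tag_id, c("t1", "t3"))
  expect_equal(out$species, c("mouse", "spike"))
  expect_equal(attr(out, "n_common"), 1L)
  expect_equal(attr(out, "n_contaminant"), 1L)
  expect_equal(attr(out, "n_unmapped"), 1L)
})

make_spike_counts <- function() {
  # 90 mouse transcripts with equal counts, 10 spike transcripts
  mouse <- matrix(100, 90, 2, dimnames = list(paste0("m", 1:90),
                                              c("A", "B")))
  spike <- matrix(c(rep(100, 10), rep(200, 10)), 10, 2,
                  dimnames = list(paste0("sp", 1:10), c("A", "B")))
  # compensate mouse counts in B so totals are equal across samples
  mouse[, "B"] <- (sum(mouse[, "A"]) + 1000 - 2000) / 90
  rbind(mouse, spike)
}

test_that("the spike correction factor aligns samples to the reference", {
  counts <- make_spike_counts()
  is_spike <- grepl("^sp", rownames(counts))
  # identical spike signal -> zero corrections
  same <- cbind(A = counts[, "A"], B = counts[, "A"])
  n0 <- normalize_with_spike(same, is_spike, tmm = FALSE, pseudocount = 0)
  expect_equal(unname(n0$correction), c(0, 0))

  # spike uniformly 2x in B at equal totals -> correction_B = -1 (log2)
  n1 <- normalize_with_spike(counts, is_spike, reference_sample = "A",
                             tmm = FALSE, pseudocount = 0)
  expect_equal(unname(n1$correction), c(0, -1), tolerance = 1e-12)

  # defining property: per-transcript spike differences to the reference
  # have median zero after correction
  set.seed(20)
  rnd <- matrix(rnbinom(500 * 4, mu = 150, size = 5), 500, 4,
                dimnames = list(c(paste0("m", 1:450), paste0("sp", 1:50)),
                                paste0("s", 1:4)))
  is_sp <- grepl("^sp", rownames(rnd))
  nr <- normalize_with_spike(rnd, is_sp)
  for (j in 2:4) {
    expect_equal(median(nr$ntc[is_sp, 1] - nr$ntc[is_sp, j]), 0,
                 tolerance = 1e-9)
  }
  expect_error(normalize_with_spike(rnd, rep(FALSE, 500)), "no spike")
})

test_that("spike anchoring preserves global shifts but removes depth", {
  set.seed(21)
  counts <- matrix(rnbinom(400 * 3, mu = 200, size = 10), 400, 3,
                   dimnames = list(c(paste0("m", 1:360),
                                     paste0("sp", 1:40)),
                                   paste0("s", 1:3)))
  is_sp <- grepl("^sp", rownames(counts))
  base <- normalize_with_spike(counts, is_sp, tmm = FALSE,
                               pseudocount = 0)

  # scaling only the mouse rows of sample 3 by c shifts its mouse NTCs by
  # exactly log2(c): a real global change survives normalization
  c_fac <- 4
  shifted <- counts
  shifted[!is_sp, 3] <- shifted[!is_sp, 3] * c_fac
  n_sh <- normalize_with_spike(shifted, is_sp, tmm = FALSE,
                               pseudocount = 0)
  expect_equal(n_sh$ntc[!is_sp, 3] - base$ntc[!is_sp, 3],
               rep(log2(c_fac), sum(!is_sp)), ignore_attr = TRUE,
               tolerance = 1e-9)

  # scaling ALL rows of a sample changes nothing (depth invariance)
  deep <- counts
  deep[, 2] <- deep[, 2] * 7
  n_dp <- normalize_with_spike(deep, is_sp, tmm = FALSE, pseudocount = 0)
  expect_equal(n_dp$ntc, base$ntc, tolerance = 1e-9)
})

test_that("transcript scores average into gene scores", {
  map <- data.frame(transcript_id = c("t1", "t2a", "t2b"),
                    gene_id = c("g1", "g2", "g2"),
                    stringsAsFactors = FALSE)
  sc <- c(t1 = 5, t2a = 2, t2b = 4)
  g <- gene_scores(sc, map)
  expect_equal(g, c(g1 = 5, g2 = 3))
  # matrix input, and unmapped transcripts warn and are excluded
  m <- rbind(t1 = c(1, 2), t2a = c(3, 4), t2b = c(5, 6), tX = c(9, 9))
  expect_warning(gm <- gene_scores(m, map), "not in gene_map")
  expect_equal(gm["g2", ], c(4, 5))
  expect_false("tX" %in% rownames(gm))
})

test_that("TE is the RF/RNA log ratio and is antisymmetric", {
  rf <- c(g1 = 5, g2 = 2)
  rna <- c(g1 = 3, g2 = 2, g3 = 1)
  expect_message(te <- translation_efficiency(rf, rna), "excluded")
  expect_equal(te, c(g1 = 2, g2 = 0), ignore_attr = TRUE)
  te_swap <- suppressMessages(translation_efficiency(rna[1:2], rf))
  expect_equal(unname(te_swap), -unname(te[c("g1", "g2")]),
               ignore_attr = TRUE)
  expect_error(translation_efficiency(c(a = 1), c(b = 2)), "shared")
})

test_that("global TE shift has the closed-form percent change", {
  set.seed(22)
  te1 <- setNames(rnorm(500), paste0("g", 1:500))
  s0 <- global_te_shift(te1, te1)
  expect_equal(s0$shift, 0)
  expect_equal(s0$ks_d, 0)

  s <- global_te_shift(te1, te1 - 0.2)
  expect_equal(s$shift, -0.2, tolerance = 1e-12)
  expect_equal(s$percent_change, (2^-0.2 - 1) * 100, tolerance = 1e-12)
  expect_equal(round(s$percent_change, 1), -12.9)

  # KS D grows with the shift magnitude
  d_vals <- vapply(c(0.1, 0.3, 0.6, 1.2), function(delta) {
    global_te_shift(te1, te1 - delta + rnorm(500, 0, 0.05))$ks_d
  }, numeric(1))
  expect_true(all(diff(d_vals) >= 0))
})

test_that("a simulated global TE factor is recovered end to end", {
  sr <- simulate_ribo(n_genes = 5000, global_te_factor = 0.8, seed = 5)
  is_spike <- sr$counts$species[match(rownames(sr$rf_counts),
                                      sr$counts$transcript_id)] == "spike"
  rfn <- normalize_with_spike(sr$rf_counts, is_spike)
  rnan <- normalize_with_spike(sr$rna_counts, is_spike)
  map <- sr$counts[, c("transcript_id", "gene_id")]
  te <- translation_efficiency(
    gene_scores(rfn$ntc[!is_spike, ], map),
    gene_scores(rnan$ntc[!is_spike, ], map)
  )
  gr <- sr$samples$genotype
  sh <- global_te_shift(te[, gr == "WT"], te[, gr == "KO"])
  expect_equal(sh$shift, log2(0.8), tolerance = 0.03)
})

test_that("differential TE recovers per-gene effects at score level", {
  # 2000 genes, 100 with a -1 log2 TE effect, 3v3, per-observation TE
  # noise sd 0.25
  set.seed(31)
  n <- 2000
  base <- rnorm(n, 0, 0.4)
  effect <- c(rep(-1, 100), rep(0, n - 100))
  te <- sapply(1:6, function(s) {
    base + (s > 3) * effect + rnorm(n, 0, 0.25)
  })
  rownames(te) <- paste0("g", 1:n)
  gr <- factor(rep(c("WT", "KO"), each = 3), levels = c("WT", "KO"))
  res <- differential_te(te, gr)
  sig <- res$feature_id[res$sig_10 & res$log2fc < 0]
  truth <- paste0("g", 1:100)
  recall <- length(intersect(sig, truth)) / length(truth)
  fdp <- if (length(sig)) length(setdiff(sig, truth)) / length(sig) else 0
  expect_gte(recall, 0.8)
  expect_lte(fdp, 0.15)
  # the dual flags nest
  expect_true(all(res$sig_10[res$sig_05]))
})

test_that("count-level TE effects come out with the right sign", {
  sr <- simulate_ribo(n_genes = 1500, de_fraction = 0.05,
                      te_effect = -1.5, seed = 31)
  is_spike <- sr$counts$species[match(rownames(sr$rf_counts),
                                      sr$counts$transcript_id)] == "spike"
  map <- sr$counts[, c("transcript_id", "gene_id")]
  te <- translation_efficiency(
    gene_scores(normalize_with_spike(sr$rf_counts,
                                     is_spike)$ntc[!is_spike, ], map),
    gene_scores(normalize_with_spike(sr$rna_counts,
                                     is_spike)$ntc[!is_spike, ], map)
  )
  gr <- factor(sr$samples$genotype, levels = c("WT", "KO"))
  res <- differential_te(te, gr)
  truth <- sr$truth$de_genes
  # affected genes show a clearly negative estimated TE change
  est <- res$log2fc[match(truth, res$feature_id)]
  expect_lt(mean(est), -1)
  # and dominate the significant calls
  sig <- res$feature_id[res$sig_10 & res$log2fc < 0]
  if (length(sig)) {
    expect_gt(length(intersect(sig, truth)) / length(sig), 0.8)
  }
})
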