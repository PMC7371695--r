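# Seeded generators emulating the statistical structure of the three
# assays: spike-in ChIP-seq of pol III loci, spike-corrected ribosome
# profiling, and bulk RNA-seq. Each returns the simulated data together
# with the ground truth used by parameter-recovery and error-control
# tests. All generators are pure functions of (parameters, seed): the
# caller's RNG state is saved and restored, and per-sample sub-streams are
# derived from the seed so adding replicates does not reshuffle the
# counts of earlier samples.

# Negative-binomial draw parameterized by mean and dispersion phi
# (variance = mu + phi * mu^2), via the gamma-Poisson mixture.
rnbinom_mu_phi <- function(n, mu, phi) {
  if (phi <= 0) return(rpois(n, mu))
  rnbinom(n, size = 1 / phi, mu = mu)
}

sub_seed <- function(seed, block) (seed + 10007L * block) %% .Machine$integer.max

#' Simulate spike-in ChIP-seq samples of pol III loci
#'
#' Emulates a two-genotype spike-in ChIP design: a configurable fraction
#' of loci is occupied (scores drawn from a high mode) and the rest sit in
#' a background mode, giving the bimodal score distribution seen over pol
#' III loci. A fraction of the occupied loci carries a true occupancy
#' effect (log2) in the second genotype. Input counts are proportional to
#' locus length; IP counts follow the locus's true enrichment; spike
#' totals are `depth * spike_fraction` with multiplicative sample noise.
#'
#' @param n_loci number of loci (default 500).
#' @param occupied_fraction fraction of loci in the occupied mode
#'   (default 0.6).
#' @param effect_loci_fraction fraction of all loci (drawn from the
#'   occupied ones) with a true genotype effect (default 0.1).
#' @param effect_size true log2 effect added in genotype 2 (default 2).
#' @param n_reps replicates per genotype (default 2).
#' @param depth nominal library depth in tags (default 2e6).
#' @param spike_fraction fraction of chromatin that is spike material
#'   (default 0.025, i.e. 2.5%).
#' @param occupied_mean,unoccupied_mean,mode_sd means of the two score
#'   modes and their common spread.
#' @param rep_sd replicate-to-replicate score noise (log2).
#' @param seed integer seed.
#' @return list with `samples` (list of [chip_sample()], genotypes WT/KO),
#'   `truth` (list: `occupied`, `base_score`, `effect`, `effect_loci`,
#'   `params`).
#' @export
simulate_chip <- function(n_loci = 500, occupied_fraction = 0.6,
                          effect_loci_fraction = 0.1, effect_size = 2,
                          n_reps = 2, depth = 2e6, spike_fraction = 0.025,
                          occupied_mean = 4, unoccupied_mean = -2,
                          mode_sd = 0.7, rep_sd = 0.3, seed = 1) {
  stopifnot(occupied_fraction >= 0, occupied_fraction <= 1,
            effect_loci_fraction >= 0, effect_loci_fraction <= 1,
            n_reps >= 1, depth > 0, spike_fraction > 0, spike_fraction < 1)

  loci <- sprintf("locus_%04d", seq_len(n_loci))
  truth <- with_seed(seed, {
    occupied <- rep(FALSE, n_loci)
    occupied[sample(n_loci, round(n_loci * occupied_fraction))] <- TRUE
    base <- ifelse(occupied, rnorm(n_loci, occupied_mean, mode_sd),
                   rnorm(n_loci, unoccupied_mean, mode_sd))
    lengths <- round(runif(n_loci, 80, 300))
    n_eff <- round(n_loci * effect_loci_fraction)
    eligible <- which(occupied)
    effect_loci <- sort(sample(eligible, min(n_eff, length(eligible))))
    effect <- numeric(n_loci)
    effect[effect_loci] <- effect_size
    list(occupied = setNames(occupied, loci),
         base_score = setNames(base, loci),
         lengths = lengths,
         effect = setNames(effect, loci),
         effect_loci = loci[effect_loci])
  })

  genotypes <- rep(c("WT", "KO"), each = n_reps)
  samples <- vector("list", length(genotypes))
  input_total <- depth * (1 - spike_fraction)
  input_rate <- truth$lengths / sum(truth$lengths) * input_total * 0.05
  for (s in seq_along(genotypes)) {
    samples[[s]] <- with_seed(sub_seed(seed, s), {
      ip_spike <- round(depth * spike_fraction * rlnorm(1, 0, 0.15))
      input_spike <- round(depth * spike_fraction * rlnorm(1, 0, 0.15))
      input <- rpois(n_loci, input_rate)
      score <- truth$base_score +
        (genotypes[s] == "KO") * truth$effect +
        rnorm(n_loci, 0, rep_sd)
      ip_mu <- 2^score * pmax(input_rate, 0.5) * (ip_spike / input_spike)
      ip <- rpois(n_loci, ip_mu)
      chip_sample(
        sample_id = paste0(genotypes[s], "_rep",
                           ((s - 1) %% n_reps) + 1),
        genotype = genotypes[s], state = "refed",
        ip_counts = setNames(ip, loci),
        input_counts = setNames(input, loci),
        ip_spike_total = ip_spike, input_spike_total = input_spike
      )
    })
  }
  truth$params <- list(n_loci = n_loci, occupied_fraction = occupied_fraction,
                       effect_size = effect_size, n_reps = n_reps,
                       depth = depth, spike_fraction = spike_fraction,
                       seed = seed)
  list(samples = samples, truth = truth)
}

#' Simulate spike-in ribosome profiling (RF + RNA libraries)
#'
#' Emulates the paired footprint/RNA-seq design with a Drosophila spike
#' panel mixed in at a fixed ratio (default 1/15 of the mouse signal).
#' RNA counts are negative binomial around log-normal gene baselines; RF
#' counts follow the RNA means times a per-gene translation efficiency,
#' times `global_te_factor` in the second group (KO) — the spike panel is
#' *not* scaled by the global factor, which is what makes the shift
#' recoverable. A fraction of genes additionally carries a per-gene TE
#' effect in the KO. A minority of genes get two transcripts so
#' transcript-to-gene averaging is exercised.
#'
#' @param n_genes number of mouse genes (default 5000).
#' @param global_te_factor multiplicative global change in KO ribosome
#'   occupancy (default 1 = none; the study-like value is ~0.87).
#' @param de_fraction fraction of genes with a per-gene TE effect.
#' @param te_effect log2 TE effect for those genes (default -1).
#' @param dispersion NB dispersion of the mouse genes across biological
#'   replicates (default 0.05).
#' @param spike_dispersion NB dispersion of the spike transcripts
#'   (default 0.005): the spike is one homogeneous pool added to every
#'   sample, so only technical, near-Poisson variation applies to it.
#' @param n_reps replicates per group (default 3).
#' @param n_spike spike transcripts (default 200).
#' @param depth nominal tags per library (default 2e7).
#' @param spike_ratio spike-to-mouse signal ratio (default 1/15).
#' @param multi_tx_fraction fraction of genes with 2 transcripts.
#' @param seed integer seed.
#' @return list with `counts` (data.frame: transcript_id, gene_id,
#'   species), `rf_counts`, `rna_counts` (transcript x sample matrices),
#'   `samples` (data.frame sample_id, genotype), and `truth`.
#' @export
simulate_ribo <- function(n_genes = 5000, global_te_factor = 1,
                          de_fraction = 0, te_effect = -1,
                          dispersion = 0.05, spike_dispersion = 0.005,
                          n_reps = 3, n_spike = 200,
                          depth = 2e7, spike_ratio = 1 / 15,
                          multi_tx_fraction = 0.1, seed = 1) {
  stopifnot(global_te_factor > 0, dispersion > 0, de_fraction >= 0,
            de_fraction <= 1, n_reps >= 1, n_spike >= 1)

  genes <- sprintf("gene_%05d", seq_len(n_genes))
  layout <- with_seed(seed, {
    base <- rlnorm(n_genes, log(100), 1.1)
    te <- 2^rnorm(n_genes, 0, 0.4)
    de_idx <- sort(sample(n_genes, round(n_genes * de_fraction)))
    multi <- sort(sample(n_genes, round(n_genes * multi_tx_fraction)))
    spike_base <- rlnorm(n_spike, log(100), 0.6)
    # scale the spike panel so its total signal is spike_ratio x mouse
    spike_base <- spike_base * (sum(base) * spike_ratio / sum(spike_base))
    list(base = base, te = te, de_idx = de_idx, multi = multi,
         spike_base = spike_base)
  })

  # transcript table: multi-transcript genes split their mean 60/40
  tx_gene <- rep(genes, ifelse(seq_len(n_genes) %in% layout$multi, 2L, 1L))
  tx_id <- paste0(tx_gene, ".t",
                  unlist(lapply(rle(tx_gene)$lengths, seq_len)))
  share <- unlist(lapply(rle(tx_gene)$lengths,
                         function(k) if (k == 2L) c(0.6, 0.4) else 1))
  gi <- match(tx_gene, genes)
  spike_id <- sprintf("spike_%03d", seq_len(n_spike))

  rna_mu_tx <- layout$base[gi] * share
  te_gene <- layout$te
  de_effect <- numeric(n_genes)
  de_effect[layout$de_idx] <- te_effect

  sample_ids <- paste0(rep(c("WT", "KO"), each = n_reps), "_rep",
                       rep(seq_len(n_reps), 2))
  genotype <- rep(c("WT", "KO"), each = n_reps)

  n_tx <- length(tx_id)
  rf <- rna <- matrix(0L, n_tx + n_spike, length(sample_ids),
                      dimnames = list(c(tx_id, spike_id), sample_ids))
  scale_unit <- depth / (sum(layout$base) * (1 + spike_ratio))
  for (s in seq_along(sample_ids)) {
    ko <- genotype[s] == "KO"
    draws <- with_seed(sub_seed(seed, 100 + s), {
      df_rna <- rlnorm(1, 0, 0.1)
      df_rf <- rlnorm(1, 0, 0.1)
      rf_mu_tx <- rna_mu_tx * te_gene[gi] *
        if (ko) global_te_factor * 2^de_effect[gi] else 1
      list(
        rna = rnbinom_mu_phi(n_tx, rna_mu_tx * scale_unit * df_rna,
                             dispersion),
        rf = rnbinom_mu_phi(n_tx, rf_mu_tx * scale_unit * df_rf,
                            dispersion),
        rna_sp = rnbinom_mu_phi(n_spike,
                                layout$spike_base * scale_unit * df_rna,
                                spike_dispersion),
        rf_sp = rnbinom_mu_phi(n_spike,
                               layout$spike_base * scale_unit * df_rf,
                               spike_dispersion)
      )
    })
    rna[, s] <- c(draws$rna, draws$rna_sp)
    rf[, s] <- c(draws$rf, draws$rf_sp)
  }

  counts <- data.frame(
    transcript_id = c(tx_id, spike_id),
    gene_id = c(tx_gene, spike_id),
    species = c(rep("mouse", n_tx), rep("spike", n_spike)),
    stringsAsFactors = FALSE
  )
  truth <- list(
    global_te_factor = global_te_factor,
    global_shift_log2 = log2(global_te_factor),
    te_effect = setNames(de_effect, genes),
    de_genes = genes[layout$de_idx],
    gene_te = setNames(layout$te, genes),
    params = list(n_genes = n_genes, de_fraction = de_fraction,
                  te_effect = te_effect, dispersion = dispersion,
                  n_reps = n_reps, n_spike = n_spike,
                  spike_ratio = spike_ratio, seed = seed)
  )
  list(counts = counts, rf_counts = rf, rna_counts = rna,
       samples = data.frame(sample_id = sample_ids, genotype = genotype,
                            stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate a bulk RNA-seq count matrix with asymmetric DE
#'
#' Negative-binomial counts around log-normal baselines. A fraction of
#' genes is differentially expressed between the two groups, most of them
#' (per `down_bias`) downward in group 2 — the asymmetry characteristic
#' of losing a repressor-of-a-repressor regulatory layer.
#'
#' @param n_genes number of genes (default 12000).
#' @param de_fraction fraction of DE genes (default 0.078).
#' @param down_bias fraction of DE genes that go down in group 2
#'   (default 0.89).
#' @param effect_size absolute log2 fold change of DE genes (default 1).
#' @param dispersion NB dispersion (default 0.05).
#' @param n_per_group samples per group; length 1 or 2 (default c(7, 5)).
#' @param depth nominal library depth (default 2e7).
#' @param seed integer seed.
#' @return list with `counts` (gene x sample matrix), `groups` (factor
#'   WT/KO) and `truth` (`is_de`, `true_lfc`).
#' @export
simulate_rnaseq <- function(n_genes = 12000, de_fraction = 0.078,
                            down_bias = 0.89, effect_size = 1,
                            dispersion = 0.05, n_per_group = c(7, 5),
                            depth = 2e7, seed = 1) {
  stopifnot(de_fraction >= 0, de_fraction <= 1, down_bias >= 0,
            down_bias <= 1, dispersion > 0)
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2)
  genes <- sprintf("gene_%05d", seq_len(n_genes))

  layout <- with_seed(seed, {
    base <- rlnorm(n_genes, log(150), 1.4)
    de_idx <- sort(sample(n_genes, round(n_genes * de_fraction)))
    down <- rep(FALSE, length(de_idx))
    down[sample(length(de_idx), round(length(de_idx) * down_bias))] <- TRUE
    lfc <- numeric(n_genes)
    lfc[de_idx] <- ifelse(down, -effect_size, effect_size)
    list(base = base, lfc = lfc, de_idx = de_idx)
  })

  sample_ids <- c(paste0("WT_rep", seq_len(n_per_group[1])),
                  paste0("KO_rep", seq_len(n_per_group[2])))
  groups <- factor(rep(c("WT", "KO"), n_per_group), levels = c("WT", "KO"))
  counts <- matrix(0L, n_genes, length(sample_ids),
                   dimnames = list(genes, sample_ids))
  scale_unit <- depth / sum(layout$base)
  for (s in seq_along(sample_ids)) {
    ko <- groups[s] == "KO"
    counts[, s] <- with_seed(sub_seed(seed, 200 + s), {
      df <- rlnorm(1, 0, 0.1)
      mu <- layout$base * scale_unit * df * if (ko) 2^layout$lfc else 1
      rnbinom_mu_phi(n_genes, mu, dispersion)
    })
  }
  truth <- list(
    is_de = setNames(layout$lfc != 0, genes),
    true_lfc = setNames(layout$lfc, genes),
    params = list(n_genes = n_genes, de_fraction = de_fraction,
                  down_bias = down_bias, effect_size = effect_size,
                  dispersion = dispersion, n_per_group = n_per_group,
                  seed = seed)
  )
  list(counts = counts, groups = groups, truth = truth)
}
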