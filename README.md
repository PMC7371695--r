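# pol3seq

Quantitative analysis of RNA polymerase III regulation from spike-in
sequencing assays.

Pol III transcribes tRNA, 5S rRNA and other short non-coding genes, and its
genome-wide activity shifts with nutritional state and with loss of its
repressor MAF1. Detecting such shifts is exactly what internal
normalization destroys: scaling every library to a common size erases any
change that affects most of the signal. The assays this package supports
therefore carry exogenous spike-ins — a fixed fraction of foreign chromatin
in each ChIP sample, and *Drosophila* S2 material at a fixed ratio in
ribosome-profiling and RNA-seq libraries — and `pol3seq` implements the
downstream statistics that exploit them.

For a pol III locus with IP count *y*, input count *x*, pseudocount *a* and
spike-genome tag totals *S*<sub>IP</sub>, *S*<sub>in</sub>, the occupancy
score is

```
score = log2( ((y + a) / S_IP) / ((x + a) / S_in) )
```

which is invariant to sequencing depth but moves one-for-one with genuine
occupancy changes. Translation efficiency is
TE = RF-NTC − RNA-NTC per gene, where each NTC is a log2 tag count
normalized by library total and TMM factor and then anchored between
samples by a correction computed on the spike transcripts, so a global
reduction in ribosome occupancy survives normalization and is reported as
(2^shift − 1)·100 percent.

The package provides:

* **Locus catalog** — BED6 + annotation input, tRNA name parsing (iMet
  distinct from Met), grouping by isotype / isoacceptor / gene class.
* **Statistical core** — TMM scaling factors, empirical-Bayes moderated t
  with BH adjustment, two-sample Kolmogorov–Smirnov, hypergeometric
  overlap; each verified against an independent brute-force oracle and
  against edgeR / limma / base R in the test suite.
* **ChIP occupancy** — spike-normalized scores, a two-component Gaussian
  mixture cut-off for occupied/not-occupied calls, quantile classes,
  differential occupancy, Venn partitions, cross-experiment stability
  classes, isotype/isoacceptor cumulative scores.
* **Ribosome profiling** — tag disambiguation, spike-anchored NTC, per-gene
  TE, global-shift detection with KS comparison, differential TE at dual
  significance levels.
* **RNA-seq DE** — expression filtering, the dual adjusted-p / fold-change
  selection rule, reverse cumulative frequency curves.
* **Enrichment** — GSEA running enrichment score, rank–rank hypergeometric
  overlap maps, fixed-threshold set-overlap tests.
* **Synthetic data** — seeded negative-binomial generators for all three
  assays with recorded ground truth.
* **Pipeline** — `validate_config()` / `run_pipeline()` for config-driven
  end-to-end runs with manifest checksums.

## Worked example

Simulate a spike-in ChIP experiment (500 loci, 60% occupied, 50 loci with
a +2 log2 occupancy effect in the knockout, 3 replicates per genotype),
score it, estimate the occupied cut-off, and test differential occupancy:

```r
library(pol3seq)

sim    <- simulate_chip(n_loci = 500, effect_loci_fraction = 0.1,
                        effect_size = 2, n_reps = 3, rep_sd = 0.3, seed = 42)
scores <- score_chip_samples(sim$samples)
cutoff <- estimate_occupancy_cutoff(rowMeans(scores))
cutoff
#> cutoff_model: cutoff = 0.902; components N(-1.96, 0.75^2) w=0.40 /
#>   N(4.07, 0.81^2) w=0.60 (6 EM iterations)

groups <- factor(attr(scores, "conditions")$genotype, levels = c("WT", "KO"))
res <- differential_occupancy(scores, groups, alpha = 0.01, cutoff = cutoff)
sum(res$significant)                      # loci with adj. p < 0.01
#> [1] 50
sum(res$significant & res$log2fc > 0)     # all higher in the knockout
#> [1] 50
```

The mixture model recovers the two score modes the generator planted (−2
and +4) and places the cut-off between them; the moderated test recovers
exactly the 50 loci that truly changed, all in the right direction
(`log2fc` is KO − WT). `res` also carries the MvA quantities
(`avg_score`, `log2fc`) and a `below_cutoff` flag for loci unoccupied in
every sample.

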