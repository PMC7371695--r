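---
title: "Spike-anchored pol III occupancy and translation-efficiency analysis: models and choices"
author: "pol3seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-anchored pol III occupancy and translation-efficiency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pol3seq)
```

## The problem

RNA polymerase III (pol III) transcribes tRNA genes, 5S rRNA genes and a
small set of other short non-coding loci. Its genome-wide activity responds
to nutritional state and is restrained by the repressor MAF1. Measuring
*global* changes in pol III occupancy — or in translation — with sequencing
assays is impossible with purely internal normalization: any method that
scales libraries to a common size will, by construction, erase a shift that
affects most of the signal. The designs this package supports solve that
with exogenous spike-ins: a fixed proportion of foreign chromatin in each
ChIP sample (for example 2.5% human chromatin in mouse liver samples), and a
fixed ratio of *Drosophila* S2 cell material (1/15) in ribosome-profiling
and matched RNA-seq libraries. Because the spike is constant across samples,
it anchors the between-sample scale, and genuine global shifts survive
normalization.

`pol3seq` implements the downstream quantitative workflow: occupancy
scoring and occupied/not-occupied calls for a catalog of pol III loci,
differential occupancy, spike-corrected translation-efficiency (TE) scores
with global-shift detection, RNA-seq differential expression with a dual
cut-off, and the comparison statistics (GSEA running score, rank–rank
hypergeometric overlap, set-overlap tests) used to interpret the results.
The entry point is tag-count tables; read trimming, alignment and feature
counting happen upstream and are out of scope.

## Occupancy scores and the occupied cut-off

For locus $i$ in one ChIP sample, with IP count $y_i$, input count $x_i$,
pseudocount $a$, and spike-genome tag totals $S_{IP}$ and $S_{in}$:

$$\mathrm{score}_i \;=\; \log_2\frac{(y_i + a)/S_{IP}}{(x_i + a)/S_{in}}.$$

Two contracts define this score and are asserted as tests: scaling an entire
sample (all counts *and* its spike totals) by $c>0$ changes nothing
(sequencing-depth invariance), while doubling only $S_{IP}$ lowers every
score by exactly one log2 unit — the spike really is the anchor. The
pseudocount defaults to $a = 0.5$; it only matters at unoccupied loci with
zero or near-zero counts, where it bounds the score instead of letting it
diverge, and is negligible at occupied loci with hundreds of tags.

Score distributions over pol III loci are characteristically bimodal: a
background mode and an occupied mode. The occupied/not-occupied cut-off is
estimated by fitting a two-component Gaussian mixture with EM and placing
the threshold where posterior membership in the upper component crosses 0.5.
Initialization is deterministic (the sample is split at its median), so the
fit is reproducible; a fixed numeric threshold can be supplied instead
through the pipeline configuration. EM stops when the log-likelihood changes
by less than $10^{-8}$, errs after 500 iterations, and errs on constant
input. When the component weights are so unbalanced that the posterior never
crosses 0.5 between the means, the crossing point is taken on a fine grid
between the means; the cut-off always lies strictly between them.

Replicates are scored individually and kept for the differential test;
averages are taken only for display quantities (quantile classes, cumulative
group scores). Quantile classes come from a caller-chosen reference sample;
ties at a class boundary all fall to the lower class, which keeps the
assignment deterministic. Cumulative scores per tRNA isotype or isoacceptor
are computed on the linear scale, $\log_2 \sum_i 2^{s_i}$, so aggregation is
additive in tag enrichment rather than in log units; initiator methionine
(iMet) is its own isotype, giving 22 isotype classes in a complete catalog.

## Statistical primitives

The pipeline's statistics are implemented in the package and each is
verified in the test suite against an independent brute-force oracle and,
where one exists, against the standard implementation (`edgeR`
`calcNormFactors`, `limma` `eBayes`, `stats::p.adjust`, `stats::ks.test`).

**TMM scaling factors.** For sample $j$ against a reference $r$ (the sample
whose upper-quartile relative abundance is closest to the mean upper
quartile — a deterministic choice), per-feature M-values
$M_i = \log_2\frac{y_{ij}/N_j}{y_{ir}/N_r}$ are trimmed by 30% at each tail,
jointly with a 5% per-tail trim on the average abundance A, and averaged
with inverse delta-method-variance weights; the factor is $2$ to that mean,
and factors are rescaled to geometric mean 1. The trim fractions are
conventional defaults and configurable. One caveat documented by a test:
because the weights depend on absolute counts, multiplying one column by a
constant moves its factor by a tiny but nonzero amount (below $5\times
10^{-3}$ in the tested fixtures); exact invariance would require unweighted
averaging.

**Moderated t.** Per feature, the pooled two-group variance $s^2$ (on $d$
residual degrees of freedom) is shrunk toward a prior: $\tilde s^2 = (d_0
s_0^2 + d s^2)/(d_0 + d)$, and $t = (\bar x_2 - \bar x_1)/\left(\tilde s
\sqrt{1/n_1 + 1/n_2}\right)$ is referred to $t_{d_0 + d}$. When not
supplied, $(s_0^2, d_0)$ are estimated by method of moments on the log
sample variances (which follow a shifted log-F under the model), with $d_0$
capped at $10^9$ to represent an effectively infinite prior. With $d_0 = 0$
the statistic reduces exactly to the ordinary equal-variance t-test, and as
$d_0 \to \infty$ to a z-statistic with variance $s_0^2$ — both limits are
tested. Significance thresholds on the BH-adjusted p-value use a strict
`<` by default (configurable), applied uniformly.

Two deliberate omissions relative to full-scale practice: no
mean–variance precision weights (voom) and no unwanted-variation factors
(RUV). The moderated t here operates on log-scale scores directly. On the
simulated data this costs little — the null false-discovery proportion
stays controlled (tested over 50 seeded replicates) — but on real count
data with strong technical structure both devices matter, so dataset-level
results obtained with them are not expected to be reproduced exactly.

**BH adjustment, KS test, hypergeometric overlap.** BH is the step-up
procedure, monotone and capped at 1. The two-sample KS statistic is the
exact supremum of the ECDF difference over all distinct pooled values (a
deterministic treatment of ties), with the asymptotic Kolmogorov p-value —
appropriate at the thousands-of-genes scale this pipeline works at; exact
small-sample p-values are not implemented. Overlap expectations and tails
come from the hypergeometric distribution via `stats::phyper`; both tails
include the observed point mass, so depletion and enrichment p-values sum
to at least 1.

## The spike-corrected TE pipeline

Tags aligning to both genomes are discarded, as are tags on rRNA/scRNA
features. For each library type (ribosome footprints and RNA-seq,
processed separately), per-transcript normalized tag counts are

$$\mathrm{NTC}_{is} = \log_2(y_{is} + a) - \log_2(N_s f_s) + c_s,$$

with $N_s$ the total aligned tags, $f_s$ the TMM factor, and the spike
correction
$c_s = \mathrm{median}_{i \in \mathrm{spike}}\left(\mathrm{NTC}^0_{i,\mathrm{ref}} -
\mathrm{NTC}^0_{is}\right)$, a median over the spike transcripts of paired
differences to a designated reference sample. The median of paired
differences was chosen over the difference of medians for robustness to
individual outlier spike transcripts; the two coincide whenever the spike
panel shifts uniformly, and the defining property tested is that the
*paired* spike differences to the reference have median exactly zero after
correction. The correction is computed separately for footprint and RNA
libraries because the two library types have unrelated technical scale.

Transcript scores are averaged (arithmetic mean of log2 scores) into gene
scores, TE is $\mathrm{RF\text{-}NTC} - \mathrm{RNA\text{-}NTC}$ per gene,
and the global shift between groups is the mean per-gene TE difference,
reported also as $(2^{\mathrm{shift}} - 1)\cdot 100$ percent, with a KS
comparison of the per-gene TE distributions. The decisive property — the
module's reason to exist — is spike anchoring: multiplying only the mouse
counts of one sample by $c$ moves that sample's mouse NTCs by exactly
$\log_2 c$ after correction, while multiplying *all* counts (mouse plus
spike) moves nothing. Differential TE uses the moderated t with
significance flagged at both adjusted $p \le 0.05$ and $\le 0.1$, the two
levels conventionally displayed together.

## RNA-seq differential expression

Genes pass the expression filter with CPM $\ge 1$ in at least
min-group-size samples (defaults chosen to yield a realistic 10–14k
expressed-gene universe on simulated data). TMM-scaled log2-CPM scores are
tested with the moderated t, and genes are *selected* only under the dual
rule: adjusted $p < 0.01$ **and** $|\log_2 \mathrm{FC}| > 0.5$. The
fold-change bar is stated in the source conventions ambiguously ("fold
change > log2 |0.5|", elsewhere "a fold change > 1.7" is called similar);
this package reads it as 0.5 log2 units (linear ≈ 1.41) and exposes it as a
parameter. Reverse cumulative frequency curves
($\bar F_g(x) = $ fraction of genes with value $\ge x$) compare a selected
gene set between conditions across the expression range, with the first
group as the KS reference.

## Enrichment statistics

The GSEA running score increments by $|r_i|^w / \sum_{hits} |r|^w$ at set
members and decrements by $1/(N - |S|)$ elsewhere; the ES is the signed
maximum deviation. The weight defaults to $w = 1$ (the classic weighted
form) and $w = 0$ gives the unweighted KS-like form; permutation p-values
reassign set labels under an explicit seed. Ties in the ranking statistic
are broken by gene identifier, deterministically. The RRHO map evaluates
hypergeometric enrichment of top-$i$/top-$j$ overlaps on a rank grid with
step $\lceil N/100 \rceil$ by default; it is transpose-symmetric in the two
lists, lights the diagonal for concordant rankings, and stays below a
Bonferroni-style bound for independent ones (both tested). For the
fixed-threshold overlap of two external differential sets, the expectation
$|A||B|/N$ uses the expressed-gene universe as $N$; with sets of 937 and
958 in a universe of 12,056 this gives 74.5 — when the same comparison is
run on the 10,852 genes shared by two particular platforms the expectation
shifts only slightly, and the choice of universe is the caller's.

Cross-experiment stability classes combine two differential comparisons:
not significant in either (stable), significant in both with opposite signs
(reciprocal), significant in one only (preferential, split by sign for the
second comparison). Loci significant in both with the *same* sign have no
class in the source four-way scheme; the package adds `concordant` so the
classification is exhaustive and exclusive, which is asserted as an
invariant.

## The synthetic-data generators

Three seeded generators emulate the designs at desk scale and return the
ground truth alongside the data.

* `simulate_chip()`: 500 loci by default, 60% occupied, score modes at −2
  and +4 (sd 0.7) giving the characteristic bimodality, replicate noise sd
  0.3 in log2, spike fraction 2.5% of depth with multiplicative noise,
  Poisson counts with input rates proportional to locus length, and a 10%
  subset of occupied loci carrying a +2 log2 genotype effect.
* `simulate_ribo()`: 5,000 genes, negative-binomial counts (gamma–Poisson)
  with biological dispersion 0.05 for mouse genes, a 200-transcript spike
  panel at 1/15 of the mouse signal, 3 replicates per genotype, and a
  global TE factor applied to KO footprint counts only. The spike panel
  gets its own *technical* dispersion (0.005): the spike is one homogeneous
  pool pipetted into every sample, so biological replicate-to-replicate
  variance does not apply to it. This distinction matters quantitatively —
  with biological-level spike noise the sampling error of the spike-median
  correction (~0.03 log2) would dominate the global-shift estimate.
* `simulate_rnaseq()`: 12,000 genes, 7 vs 5 samples, 7.8% DE with 89% of
  effects downward by default, log-normal baselines, per-sample depth
  factors.

All generators are pure functions of (parameters, seed): identical calls
are bit-identical, the caller's RNG state is untouched, and per-sample
sub-streams mean that adding replicates does not reshuffle earlier samples.
Simulated marginal dispersions are checked against the requested values by
method of moments.

What the simulations do *not* model — and hence what passing tests do not
show about real data: mean–variance trends of counts (no voom weights are
used downstream either), correlated technical batch structure (no RUV),
positional/codon-level footprint structure, mappability and multi-mapping
artifacts, and the two-step CDS alignment upstream of tag tables. Published
dataset-level numbers (for example 937 differentially expressed genes, or
425 of 480 differentially occupied loci) depend on the real deposited data
plus those out-of-scope steps; they are reference points, not test targets.
The in-package reference quantities that *are* recomputed exactly are the
summary arithmetic (74 expected overlap genes from 937·958/12,056; 90% from
177/197; 60% from 172/288) and the recovery/error-control behavior of the
estimators under the stated simulation conditions.

## Problem sizes and runtime envelope

Tests and the acceptance script run at desk scale by design: oracle
equivalence on ≤20-feature fixtures; error control on 50 seeded null
simulations of 2,000 genes × 3v3; TE-shift recovery on 5,000 genes with a
200-transcript spike panel; occupancy recovery on 500 loci. These sizes are
large enough for the Monte-Carlo bounds being asserted (for example, the
spike-median correction error at panel size 200 contributes well under one
percentage point to the recovered global shift) while keeping the full
suite in seconds.

## Known limitations

* No voom precision weights or RUV factors (see above); no
  negative-binomial GLM for differential TE — the moderated t on TE scores
  stands in for count-model tests, with both significance levels reported.
* The KS p-value is asymptotic only.
* The mixture cut-off assumes two Gaussian components; heavily skewed or
  three-mode score distributions should use a fixed threshold override.
* BED parsing is deliberately minimal (BED6+, tab-separated); catalog
  abbreviations that do not follow the `tRNA-<isotype>-<anticodon>` dialect
  must be resolved through an annotation table.
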