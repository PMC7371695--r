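# Spike-corrected ribosome-profiling pipeline. Libraries (ribosome
# footprints and matched RNA-seq) contain mouse material plus Drosophila S2
# spike material at a fixed ratio (1/15), so a per-sample correction factor
# computed on the spike transcripts anchors normalized tag counts between
# samples and preserves genuine global shifts in translation.

#' Remove ambiguous and contaminant tags
#'
#' Drops tags that align to both the mouse and the spike genome (common
#' tags), tags on rRNA- or scRNA-encoding features, and tags mapping to
#' neither genome. Removal counts are attached as attributes and reported.
#'
#' @param tags data.frame with columns `tag_id`, `maps_mouse`,
#'   `maps_spike` (logical), `transcript_id`, `feature_class`
#'   (`CDS`/`rRNA`/`scRNA`/`other`).
#' @return filtered data.frame with an added `species` column
#'   (`"mouse"`/`"spike"`); attributes `n_common`, `n_contaminant`,
#'   `n_unmapped` give removal counts.
#' @export
disambiguate_tags <- function(tags) {
  req <- c("tag_id", "maps_mouse", "maps_spike", "transcript_id",
           "feature_class")
  if (!all(req %in% names(tags))) {
    stop2("tags needs columns: ", paste(req, collapse = ", "))
  }
  common <- tags$maps_mouse & tags$maps_spike
  unmapped <- !tags$maps_mouse & !tags$maps_spike
  contaminant <- tags$feature_class %in% c("rRNA", "scRNA")
  drop <- common | unmapped | contaminant
  out <- tags[!drop, , drop = FALSE]
  out$species <- ifelse(out$maps_mouse, "mouse", "spike")
  if (sum(unmapped) > 0) {
    message(sum(unmapped), " tag(s) mapped to neither genome: dropped")
  }
  attr(out, "n_common") <- sum(common)
  attr(out, "n_contaminant") <- sum(contaminant & !common & !unmapped)
  attr(out, "n_unmapped") <- sum(unmapped)
  out
}

#' Spike-anchored normalized tag counts (NTC)
#'
#' Per-transcript log2 normalized tag counts for one library type
#' (ribosome footprints or RNA-seq):
#' `ntc = log2(count + a) - log2(total * tmm_factor) + correction`, i.e.
#' counts are normalized (1) to the total aligned tags of each sample and
#' (2) by TMM scaling, then (3) a per-sample correction factor computed
#' from the spike transcripts — the median over spike transcripts of
#' `ntc_ref - ntc_s` — aligns every sample to the reference sample. The
#' correction is what lets a genuine global shift in the mouse signal
#' survive normalization instead of being scaled away.
#'
#' @param counts transcript x sample non-negative count matrix.
#' @param is_spike logical vector over rows: `TRUE` for spike transcripts.
#' @param reference_sample column name or index the corrections are
#'   anchored to (default: first column).
#' @param pseudocount added before log2 (default 0.5).
#' @param tmm if `FALSE` skip the TMM step (totals-only normalization).
#' @return list with `ntc` (matrix, all transcripts), `correction`
#'   (named per-sample log2 factors), `tmm_factors`.
#' @export
normalize_with_spike <- function(counts, is_spike, reference_sample = 1,
                                 pseudocount = 0.5, tmm = TRUE) {
  assert_count_matrix(counts)
  if (length(is_spike) != nrow(counts)) {
    stop2("is_spike must have one entry per transcript")
  }
  if (!any(is_spike)) stop2("no spike transcripts flagged")
  spike_ok <- colSums(counts[is_spike, , drop = FALSE]) > 0
  if (!all(spike_ok)) {
    stop2("sample(s) with zero spike counts: ",
          paste(colnames(counts)[!spike_ok], collapse = ", "))
  }
  totals <- colSums(counts)
  if (any(totals == 0)) stop2("sample(s) with zero total counts")
  ref <- if (is.character(reference_sample)) {
    match(reference_sample, colnames(counts))
  } else {
    as.integer(reference_sample)
  }
  if (is.na(ref) || ref < 1 || ref > ncol(counts)) {
    stop2("reference_sample not found")
  }

  f <- if (tmm) tmm_factors(counts) else rep(1, ncol(counts))
  eff <- totals * f
  ntc0 <- log2(sweep(counts + pseudocount, 2, eff, "/"))

  spike_ntc <- ntc0[is_spike, , drop = FALSE]
  correction <- apply(spike_ntc, 2, function(col) {
    median(spike_ntc[, ref] - col)
  })
  ntc <- sweep(ntc0, 2, correction, "+")
  names(correction) <- colnames(counts)
  list(ntc = ntc, correction = correction, tmm_factors = f)
}

#' Average transcript scores into gene scores
#'
#' A gene's score is the arithmetic mean of the (log2) scores of all its
#' transcripts — alternative TSSs, splice variants and poly(A) isoforms
#' collapse to one value per gene.
#'
#' @param transcript_scores matrix (transcripts x samples) or named vector
#'   of per-transcript scores.
#' @param gene_map data.frame with columns `transcript_id`, `gene_id`.
#' @return matrix (or vector) of per-gene scores; transcripts absent from
#'   the map are excluded with a warning giving the count.
#' @export
gene_scores <- function(transcript_scores, gene_map) {
  if (!all(c("transcript_id", "gene_id") %in% names(gene_map))) {
    stop2("gene_map needs columns transcript_id and gene_id")
  }
  vec <- is.null(dim(transcript_scores))
  m <- if (vec) cbind(score = transcript_scores) else transcript_scores
  tx <- rownames(m)
  if (is.null(tx)) stop2("transcript scores must be named by transcript_id")
  gene <- gene_map$gene_id[match(tx, gene_map$transcript_id)]
  unmapped <- is.na(gene)
  if (any(unmapped)) {
    warning(sum(unmapped), " transcript(s) not in gene_map: excluded")
    m <- m[!unmapped, , drop = FALSE]
    gene <- gene[!unmapped]
  }
  if (nrow(m) == 0L) stop2("no mappable transcripts")
  out <- rowsum(m, gene) / as.vector(table(gene)[sort(unique(gene))])
  if (vec) out[, 1] else out
}

#' Translation efficiency scores
#'
#' TE is the log2 ratio of ribosome-footprint to mRNA abundance:
#' `te = rf_ntc - rna_ntc` per gene (both already log2). Genes missing
#' from either input are excluded and their count reported.
#'
#' @param rf_ntc,rna_ntc per-gene score matrices (genes x samples) or
#'   named vectors, on a shared gene universe.
#' @return matrix/vector of TE scores on the common genes; attribute
#'   `n_excluded` counts genes present in only one input.
#' @export
translation_efficiency <- function(rf_ntc, rna_ntc) {
  vec <- is.null(dim(rf_ntc))
  rf <- if (vec) cbind(te = rf_ntc) else rf_ntc
  rna <- if (vec) cbind(te = rna_ntc) else rna_ntc
  common <- intersect(rownames(rf), rownames(rna))
  if (length(common) == 0L) stop2("no genes shared between RF and RNA tables")
  n_excl <- (nrow(rf) - length(common)) + (nrow(rna) - length(common))
  if (n_excl > 0) {
    message(n_excl, " gene(s) present in only one table: excluded")
  }
  te <- rf[common, , drop = FALSE] - rna[common, , drop = FALSE]
  if (vec) te <- te[, 1]
  attr(te, "n_excluded") <- n_excl
  te
}

#' Global shift in translation efficiency
#'
#' Mean per-gene shift in TE between two groups, its linear-scale percent
#' change `(2^shift - 1) * 100`, and a two-sample Kolmogorov-Smirnov
#' comparison of the per-gene mean TE distributions.
#'
#' @param te_group1,te_group2 matrices (genes x samples) or named vectors
#'   of TE scores; group 1 is the reference (e.g. WT).
#' @return list with `shift` (mean log2, group2 - group1),
#'   `percent_change`, `ks_d`, `ks_p`, `n_genes`.
#' @export
global_te_shift <- function(te_group1, te_group2) {
  m1 <- if (is.null(dim(te_group1))) te_group1 else rowMeans(te_group1)
  m2 <- if (is.null(dim(te_group2))) te_group2 else rowMeans(te_group2)
  common <- intersect(names(m1), names(m2))
  if (length(common) == 0L) stop2("no shared genes")
  m1 <- m1[common]; m2 <- m2[common]
  shift <- mean(m2 - m1)
  ks <- ks_two_sample(m1, m2)
  list(shift = shift, percent_change = (2^shift - 1) * 100,
       ks_d = ks$d, ks_p = ks$p, n_genes = length(common))
}

#' Differential translation efficiency
#'
#' Moderated t-test on per-gene TE scores, reporting significance at the
#' two adjusted-p levels conventionally plotted (<= 0.05 and <= 0.1).
#'
#' @param te_matrix gene x sample TE score matrix.
#' @param groups two-level factor over columns (log2fc = level 2 - level 1).
#' @param prior optional moderation prior.
#' @return moderated-test data.frame with extra logical columns
#'   `sig_05` (`adj_p <= 0.05`) and `sig_10` (`adj_p <= 0.1`).
#' @export
differential_te <- function(te_matrix, groups, prior = NULL) {
  res <- moderated_t(te_matrix, groups, prior = prior, alpha = 0.05,
                     strict = FALSE)
  res$sig_05 <- res$adj_p <= 0.05
  res$sig_10 <- res$adj_p <= 0.1
  res
}
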