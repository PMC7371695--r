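# Gene-level RNA-seq differential expression with the dual
# adjusted-p / fold-change cut-off, plus reverse cumulative frequency
# curves for comparing a selected gene set between conditions.

#' Counts per million
#'
#' @param counts gene x sample count matrix.
#' @param lib_sizes optional library sizes (default column sums).
#' @return CPM matrix.
#' @export
cpm <- function(counts, lib_sizes = NULL) {
  assert_count_matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop2("library sizes must be positive")
  sweep(counts, 2, lib_sizes, "/") * 1e6
}

#' Select expressed genes
#'
#' Keeps genes with counts-per-million at or above `cpm_min` in at least
#' `min_samples` samples — the usual guard against testing genes whose
#' counts are too sparse to carry information.
#'
#' @param counts gene x sample count matrix.
#' @param cpm_min CPM threshold (default 1).
#' @param min_samples minimum number of samples meeting it (default: size
#'   of the smallest group a caller would compare, here 2).
#' @return the filtered count matrix.
#' @export
filter_expressed <- function(counts, cpm_min = 1, min_samples = 2) {
  if (cpm_min < 0 || min_samples < 0) stop2("thresholds must be >= 0")
  if (cpm_min == 0) return(counts)
  keep <- rowSums(cpm(counts) >= cpm_min) >= min_samples
  counts[keep, , drop = FALSE]
}

# TMM-scaled log2 CPM with pseudocount.
log_cpm <- function(counts, pseudocount = 0.5) {
  f <- tmm_factors(counts)
  eff <- colSums(counts) * f
  log2(sweep(counts + pseudocount, 2, eff, "/") * 1e6)
}

#' Differential expression with a dual cut-off
#'
#' TMM-scaled log2-CPM scores are tested with the moderated t-test and
#' BH-adjusted; genes are *selected* only if they pass both the adjusted-p
#' threshold (`adj_p < alpha`) and the fold-change threshold
#' (`|log2fc| > lfc_min`). Requiring both avoids calling genes whose
#' change is statistically solid but biologically negligible.
#'
#' @param counts gene x sample count matrix (pre-filtering is applied with
#'   [filter_expressed()]).
#' @param groups two-level factor (log2fc = level 2 - level 1).
#' @param alpha adjusted-p threshold (default 0.01, strict `<`).
#' @param lfc_min absolute log2 fold-change threshold (default 0.5, i.e.
#'   linear fold change ~1.41).
#' @param cpm_min,min_samples expression-filter parameters; `min_samples`
#'   defaults to the smaller group size.
#' @param prior optional moderation prior.
#' @return list with `results` (data.frame: moderated-test columns plus
#'   `selected` and `direction`) and `summary`
#'   (`n_expressed`, `n_selected`, `n_up`, `n_down`).
#' @export
de_analysis <- function(counts, groups, alpha = 0.01, lfc_min = 0.5,
                        cpm_min = 1, min_samples = NULL, prior = NULL) {
  groups <- check_groups(groups, ncol(counts))
  if (is.null(min_samples)) min_samples <- min(table(groups))
  counts <- filter_expressed(counts, cpm_min, min_samples)
  if (nrow(counts) == 0L) stop2("no genes pass the expression filter")
  scores <- log_cpm(counts)
  res <- moderated_t(scores, groups, prior = prior, alpha = alpha,
                     strict = TRUE)
  res$selected <- res$significant & abs(res$log2fc) > lfc_min
  res$direction <- ifelse(res$log2fc > 0, "up", "down")
  summary <- list(
    n_expressed = nrow(res),
    n_selected = sum(res$selected),
    n_up = sum(res$selected & res$direction == "up"),
    n_down = sum(res$selected & res$direction == "down")
  )
  list(results = res, summary = summary)
}

#' Reverse cumulative frequency curves
#'
#' For each group, the fraction of genes with value >= x over a common
#' grid, plus a Kolmogorov-Smirnov comparison of the first group (the
#' reference) against each other group. Used to ask whether a selected
#' gene set shifts between conditions uniformly across expression levels.
#'
#' @param values_by_group named list of numeric vectors (first element is
#'   the reference group).
#' @param grid evaluation points; default is all distinct pooled values.
#' @return list with `curves` (data.frame: `x` plus one fraction column
#'   per group) and `ks` (data.frame: group, d, p vs the reference).
#' @export
reverse_cumulative <- function(values_by_group, grid = NULL) {
  if (!is.list(values_by_group) || length(values_by_group) < 1L) {
    stop2("values_by_group must be a non-empty named list")
  }
  if (any(vapply(values_by_group, length, integer(1)) == 0L)) {
    stop2("empty group")
  }
  if (is.null(names(values_by_group))) {
    names(values_by_group) <- paste0("group", seq_along(values_by_group))
  }
  if (is.null(grid)) grid <- sort(unique(unlist(values_by_group)))
  curves <- data.frame(x = grid)
  for (g in names(values_by_group)) {
    v <- values_by_group[[g]]
    curves[[g]] <- vapply(grid, function(x) mean(v >= x), numeric(1))
  }
  ref <- values_by_group[[1]]
  others <- names(values_by_group)[-1]
  ks <- do.call(rbind, lapply(others, function(g) {
    k <- ks_two_sample(ref, values_by_group[[g]])
    data.frame(group = g, d = k$d, p = k$p, stringsAsFactors = FALSE)
  }))
  if (is.null(ks)) {
    ks <- data.frame(group = character(), d = numeric(), p = numeric())
  }
  list(curves = curves, ks = ks)
}
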