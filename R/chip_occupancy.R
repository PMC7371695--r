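# Spike-in-normalized pol III occupancy: per-locus log2(IP/input) scores
# anchored on exogenous spike chromatin, mixture-model occupied/not-occupied
# calls, quantile classes, differential occupancy and tRNA aggregation.

#' Construct a ChIP sample
#'
#' Bundles the per-locus IP and input tag counts of one ChIP experiment
#' together with the tag totals mapped to the spike genome (exogenous
#' chromatin added at a fixed fraction, e.g. 2.5% human chromatin in mouse
#' samples), which anchor between-sample normalization.
#'
#' @param sample_id sample identifier.
#' @param genotype,state condition labels (e.g. `"WT"`/`"KO"`,
#'   `"fasted"`/`"refed"`).
#' @param ip_counts,input_counts named non-negative numeric vectors of tag
#'   counts per locus; names must agree.
#' @param ip_spike_total,input_spike_total positive totals of tags mapped
#'   to the spike genome in the IP and input libraries.
#' @return object of class `chip_sample`.
#' @export
chip_sample <- function(sample_id, genotype, state, ip_counts, input_counts,
                        ip_spike_total, input_spike_total) {
  if (is.null(names(ip_counts)) || is.null(names(input_counts))) {
    stop2("ip_counts and input_counts must be named by locus_id")
  }
  if (any(ip_counts < 0) || any(input_counts < 0)) {
    stop2("counts must be non-negative")
  }
  if (ip_spike_total <= 0 || input_spike_total <= 0) {
    stop2("spike totals must be > 0")
  }
  missing_loci <- setdiff(names(ip_counts), names(input_counts))
  if (length(missing_loci)) {
    stop2("locus absent from input table: ",
          paste(head(missing_loci, 5), collapse = ", "))
  }
  structure(
    list(sample_id = sample_id, genotype = genotype, state = state,
         ip_counts = ip_counts,
         input_counts = input_counts[names(ip_counts)],
         ip_spike_total = ip_spike_total,
         input_spike_total = input_spike_total),
    class = "chip_sample"
  )
}

#' @export
print.chip_sample <- function(x, ...) {
  cat("chip_sample", x$sample_id, sprintf("(%s, %s):", x$genotype, x$state),
      length(x$ip_counts), "loci; spike totals IP =", x$ip_spike_total,
      "input =", x$input_spike_total, "\n")
  invisible(x)
}

#' Spike-normalized occupancy scores
#'
#' Per-locus occupancy score
#' `log2( ((ip + a)/ip_spike_total) / ((input + a)/input_spike_total) )`:
#' IP and input tag counts are each scaled by the tags their library maps
#' to the spike genome, so the score is invariant to sequencing depth but
#' sensitive to genuine global occupancy shifts.
#'
#' @param sample a [chip_sample()].
#' @param pseudocount `a` above; default 0.5 avoids log of zero at
#'   unoccupied loci.
#' @return named numeric vector of scores per locus.
#' @export
spike_normalized_scores <- function(sample, pseudocount = 0.5) {
  if (!inherits(sample, "chip_sample")) stop2("sample must be a chip_sample")
  if (pseudocount < 0) stop2("pseudocount must be >= 0")
  a <- pseudocount
  ip <- sample$ip_counts
  input <- sample$input_counts[names(ip)]
  log2(((ip + a) / sample$ip_spike_total) /
       ((input + a) / sample$input_spike_total))
}

#' Score a set of ChIP samples into a locus x sample matrix
#'
#' @param samples list of [chip_sample()] objects over the same loci.
#' @param pseudocount passed to [spike_normalized_scores()].
#' @return numeric matrix, loci x samples, with a `conditions` attribute
#'   (data.frame of sample_id, genotype, state).
#' @export
score_chip_samples <- function(samples, pseudocount = 0.5) {
  if (length(samples) == 0L) stop2("no samples")
  loci <- names(samples[[1]]$ip_counts)
  scores <- vapply(samples, function(s) {
    if (!identical(sort(names(s$ip_counts)), sort(loci))) {
      stop2("samples cover different locus sets")
    }
    spike_normalized_scores(s, pseudocount)[loci]
  }, numeric(length(loci)))
  colnames(scores) <- vapply(samples, `[[`, character(1), "sample_id")
  rownames(scores) <- loci
  attr(scores, "conditions") <- data.frame(
    sample_id = colnames(scores),
    genotype = vapply(samples, `[[`, character(1), "genotype"),
    state = vapply(samples, `[[`, character(1), "state"),
    stringsAsFactors = FALSE
  )
  scores
}

#' Estimate the occupied/not-occupied score cut-off
#'
#' Occupancy score distributions over pol III loci are characteristically
#' bimodal: a low mode of background loci and a high mode of occupied ones.
#' A two-component Gaussian mixture is fit by EM with deterministic
#' initialization (the sample is split at its median), and the cut-off is
#' the score between the component means where posterior membership in the
#' upper component reaches 0.5.
#'
#' @param scores numeric vector of occupancy scores (>= `min_n` values with
#'   non-zero spread).
#' @param min_n minimum number of scores required (default 50).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return object of class `cutoff_model`: list with `cutoff`, `means`,
#'   `sds`, `weights`, `loglik`, `iterations`, `converged`.
#' @export
estimate_occupancy_cutoff <- function(scores, min_n = 50, max_iter = 500,
                                      tol = 1e-8) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < min_n) {
    stop2("need at least ", min_n, " finite scores, got ", length(scores))
  }
  if (sd(scores) == 0) stop2("all scores identical: no cut-off can be fit")

  # deterministic init: split at the median
  med <- median(scores)
  lo <- scores[scores <= med]; hi <- scores[scores > med]
  mu <- c(mean(lo), mean(hi))
  sdev <- pmax(c(sd(lo), sd(hi)), sd(scores) / 100, 1e-6)
  if (any(is.na(sdev))) sdev <- rep(sd(scores) / 2, 2)
  w <- c(length(lo), length(hi)) / length(scores)

  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(scores, mu[1], sdev[1])
    d2 <- w[2] * dnorm(scores, mu[2], sdev[2])
    tot <- d1 + d2
    if (any(tot == 0)) tot[tot == 0] <- .Machine$double.xmin
    g2 <- d2 / tot
    g1 <- 1 - g2
    n1 <- sum(g1); n2 <- sum(g2)
    if (n1 < 1e-8 || n2 < 1e-8) {
      stop2("EM degenerated: one component vanished")
    }
    mu <- c(sum(g1 * scores) / n1, sum(g2 * scores) / n2)
    sdev <- sqrt(c(sum(g1 * (scores - mu[1])^2) / n1,
                   sum(g2 * (scores - mu[2])^2) / n2))
    sdev <- pmax(sdev, 1e-6)
    w <- c(n1, n2) / length(scores)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    stop2("EM did not converge in ", max_iter, " iterations ",
          "(last log-likelihood change ", format(ll - ll_old), ")")
  }

  # order components so component 1 is the low mode
  o <- order(mu)
  mu <- mu[o]; sdev <- sdev[o]; w <- w[o]

  post_diff <- function(x) {
    w[2] * dnorm(x, mu[2], sdev[2]) - w[1] * dnorm(x, mu[1], sdev[1])
  }
  cutoff <- tryCatch(
    uniroot(post_diff, lower = mu[1], upper = mu[2], tol = 1e-10)$root,
    error = function(e) {
      # no sign change between the means (extreme weight imbalance):
      # take the posterior-0.5 point on a fine grid between the means
      grid <- seq(mu[1], mu[2], length.out = 10001)
      grid[which.min(abs(post_diff(grid)))]
    }
  )

  structure(
    list(cutoff = cutoff, means = mu, sds = sdev, weights = w,
         loglik = ll, iterations = iter, converged = converged),
    class = "cutoff_model"
  )
}

#' @export
print.cutoff_model <- function(x, ...) {
  cat(sprintf(
    "cutoff_model: cutoff = %.3f; components N(%.2f, %.2f^2) w=%.2f / N(%.2f, %.2f^2) w=%.2f (%d EM iterations)\n",
    x$cutoff, x$means[1], x$sds[1], x$weights[1],
    x$means[2], x$sds[2], x$weights[2], x$iterations))
  invisible(x)
}

#' Call loci occupied at or above a cut-off
#'
#' @param scores named score vector.
#' @param cutoff numeric threshold or a `cutoff_model`.
#' @return named logical vector; `TRUE` where `score >= cutoff`.
#' @export
call_occupied <- function(scores, cutoff) {
  if (inherits(cutoff, "cutoff_model")) cutoff <- cutoff$cutoff
  scores >= cutoff
}

#' Assign quantile classes from a reference sample
#'
#' Loci are binned into `q` classes by the empirical quantile of their
#' score in a caller-chosen reference sample; class sizes differ by at most
#' one when scores are distinct. Ties at a class boundary all go to the
#' lower class (rank ties take the minimum rank), which makes the
#' assignment deterministic.
#'
#' @param reference_scores named numeric vector.
#' @param q number of classes (>= 2 and <= number of loci).
#' @return named integer vector of classes in `1..q` (1 = lowest scores).
#' @export
assign_quantile_classes <- function(reference_scores, q) {
  n <- length(reference_scores)
  if (q < 2) stop2("q must be >= 2")
  if (q > n) stop2("q (", q, ") exceeds the number of loci (", n, ")")
  r <- rank(reference_scores, ties.method = "min")
  cls <- as.integer(floor((r - 1) * q / n) + 1)
  names(cls) <- names(reference_scores)
  cls
}

#' Differential occupancy between two conditions
#'
#' Moderated t-test on the locus x sample score matrix ([moderated_t()]),
#' with the MvA quantities (`avg_score`, `log2fc`) carried in the result.
#' When a cut-off is supplied, loci scoring below it in every sample are
#' flagged `below_cutoff` (the grey class of an MvA plot).
#'
#' @param scores locus x sample numeric matrix of occupancy scores.
#' @param groups two-level factor over columns; log2fc is level 2 minus
#'   level 1.
#' @param alpha adjusted-p significance threshold (default 0.01, strict
#'   `<`).
#' @param cutoff optional numeric or `cutoff_model`.
#' @param prior optional moderation prior (see [moderated_t()]).
#' @param strict strict (`<`) vs non-strict (`<=`) threshold comparison.
#' @return data.frame of moderated-test results with an extra
#'   `below_cutoff` column.
#' @export
differential_occupancy <- function(scores, groups, alpha = 0.01,
                                   cutoff = NULL, prior = NULL,
                                   strict = TRUE) {
  res <- moderated_t(scores, groups, prior = prior, alpha = alpha,
                     strict = strict)
  if (!is.null(cutoff)) {
    if (inherits(cutoff, "cutoff_model")) cutoff <- cutoff$cutoff
    res$below_cutoff <- apply(scores < cutoff, 1, all)
  } else {
    res$below_cutoff <- FALSE
  }
  res
}

sig_with_direction <- function(res, direction) {
  if (direction == "up") res$significant & res$log2fc > 0
  else res$significant & res$log2fc < 0
}

check_same_universe <- function(res_A, res_B) {
  if (!identical(sort(res_A$feature_id), sort(res_B$feature_id))) {
    stop2("the two result sets cover different locus universes")
  }
}

#' Two-way partition of significant loci (Venn counts)
#'
#' Counts loci significant with a given direction in comparison A only, in
#' both, and in B only — the numbers behind a two-set Venn diagram such as
#' loci with higher occupancy in the knockout under fed vs fasted
#' conditions.
#'
#' @param results_A,results_B data.frames from [differential_occupancy()]
#'   (or [moderated_t()]) over the same locus universe.
#' @param direction `"up"` (log2fc > 0, default) or `"down"`.
#' @return named integer vector `c(A_only, both, B_only)`.
#' @export
venn_partition <- function(results_A, results_B, direction = c("up", "down")) {
  direction <- match.arg(direction)
  check_same_universe(results_A, results_B)
  sa <- results_A$feature_id[sig_with_direction(results_A, direction)]
  sb <- results_B$feature_id[sig_with_direction(results_B, direction)]
  c(A_only = length(setdiff(sa, sb)),
    both = length(intersect(sa, sb)),
    B_only = length(setdiff(sb, sa)))
}

#' Cross-experiment stability classes
#'
#' Classifies each locus by the joint significance/direction pattern of two
#' differential comparisons X and Y: not significant in either is
#' `stable`; significant in both with opposite signs is `reciprocal` (and
#' with the same sign `concordant`); significant only in X is
#' `X_preferential`; significant only in Y is split by sign into
#' `Y_preferential_up` / `Y_preferential_down`. The classes are exhaustive
#' and mutually exclusive.
#'
#' @param res_X,res_Y moderated-test result data.frames over the same
#'   universe.
#' @param alpha adjusted-p threshold; recomputed from `adj_p` so both
#'   comparisons use the same rule.
#' @param strict strict (`<`) threshold comparison (default).
#' @return named character vector of classes per locus.
#' @export
cross_condition_classes <- function(res_X, res_Y, alpha = 0.01,
                                    strict = TRUE) {
  check_same_universe(res_X, res_Y)
  res_Y <- res_Y[match(res_X$feature_id, res_Y$feature_id), ]
  sx <- if (strict) res_X$adj_p < alpha else res_X$adj_p <= alpha
  sy <- if (strict) res_Y$adj_p < alpha else res_Y$adj_p <= alpha
  cls <- character(nrow(res_X))
  cls[!sx & !sy] <- "stable"
  cls[sx & !sy] <- "X_preferential"
  cls[!sx & sy & res_Y$log2fc > 0] <- "Y_preferential_up"
  cls[!sx & sy & res_Y$log2fc <= 0] <- "Y_preferential_down"
  both <- sx & sy
  cls[both & sign(res_X$log2fc) != sign(res_Y$log2fc)] <- "reciprocal"
  cls[both & sign(res_X$log2fc) == sign(res_Y$log2fc)] <- "concordant"
  names(cls) <- res_X$feature_id
  cls
}

#' Cumulative occupancy scores by tRNA isotype or isoacceptor
#'
#' Per-locus scores are log2 quantities; the cumulative score of a group is
#' the log2 of the *sum of linear-scale values*, `log2(sum(2^score))`, so
#' that aggregation is additive in tag enrichment. Groups are ranked and
#' assigned quartiles (4 = most occupied).
#'
#' @param scores named per-locus score vector covering the catalog's tRNA
#'   loci.
#' @param catalog a [pol3_catalog()].
#' @param level `"isotype"` or `"isoacceptor"`.
#' @return data.frame with `group`, `n_loci`, `cumulative_score`,
#'   `quartile`, ordered by decreasing cumulative score.
#' @export
aggregate_group_scores <- function(scores, catalog,
                                   level = c("isotype", "isoacceptor")) {
  level <- match.arg(level)
  groups <- group_loci(catalog, level)
  keep <- vapply(groups, function(ids) any(ids %in% names(scores)), logical(1))
  if (any(!keep)) {
    warning("omitting ", sum(!keep), " group(s) with no scored loci: ",
            paste(names(groups)[!keep], collapse = ", "))
    groups <- groups[keep]
  }
  if (length(groups) == 0L) stop2("no scored tRNA groups")
  cum <- vapply(groups, function(ids) {
    s <- scores[intersect(ids, names(scores))]
    log2(sum(2^s))
  }, numeric(1))
  n <- vapply(groups, function(ids) sum(ids %in% names(scores)), integer(1))
  quart <- if (length(cum) >= 2) {
    assign_quantile_classes(cum, q = min(4L, length(cum)))
  } else {
    setNames(1L, names(cum))
  }
  out <- data.frame(group = names(groups), n_loci = n,
                    cumulative_score = cum, quartile = quart,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$cumulative_score), ]
}

#' Per-locus occupancy score differences, positives highlighted
#'
#' Score differences (test minus reference, log2 scale — scores are
#' already log2, so a difference is a log2 ratio of enrichments) for loci
#' occupied in at least one sample. Loci with negative differences are
#' kept in the full table but excluded from the `positive` subset used for
#' plotting/export.
#'
#' @param scores_test,scores_ref named score vectors on a shared universe
#'   (e.g. knockout and wild type).
#' @param occupied optional named logical vector: occupied in >= 1 sample.
#'   `NULL` keeps all loci.
#' @return list with `full` (data.frame locus_id, delta, occupied) and
#'   `positive` (subset with delta > 0 and occupied).
#' @export
positive_score_differences <- function(scores_test, scores_ref,
                                       occupied = NULL) {
  if (!identical(sort(names(scores_test)), sort(names(scores_ref)))) {
    stop2("score vectors cover different locus universes")
  }
  ids <- names(scores_test)
  delta <- scores_test - scores_ref[ids]
  occ <- if (is.null(occupied)) rep(TRUE, length(ids)) else occupied[ids]
  full <- data.frame(locus_id = ids, delta = unname(delta),
                     occupied = unname(occ), stringsAsFactors = FALSE)
  positive <- full[full$delta > 0 & full$occupied, , drop = FALSE]
  list(full = full, positive = positive)
}
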