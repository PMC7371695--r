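#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Computes between-sample scaling factors that are robust to asymmetric
#' composition differences. For each sample a weighted mean of per-feature
#' log2 ratios (M-values) against a reference sample is taken after trimming
#' the most extreme M-values and the features with the most extreme average
#' abundance (A-values); the factor is 2 raised to that mean. Weights are the
#' inverse asymptotic (delta-method) variances of the M-values. Factors are
#' rescaled so their geometric mean is 1.
#'
#' @param counts non-negative numeric matrix, features x samples, with
#'   column names. Column sums must be positive.
#' @param ref_sample column name or index of the reference sample, or
#'   `NULL` (default) to pick the sample whose upper-quartile relative
#'   abundance is closest to the mean upper quartile.
#' @param trim_m fraction of features trimmed from *each* tail of the
#'   M-value distribution (default 0.30).
#' @param trim_a fraction trimmed from each tail of the A-value
#'   distribution (default 0.05).
#' @return named numeric vector of scaling factors, one per sample, with
#'   geometric mean 1.
#' @examples
#' m <- cbind(a = c(10, 20, 30, 40), b = c(20, 40, 60, 80))
#' tmm_factors(m) # identical composition: both factors are 1
#' @export
tmm_factors <- function(counts, ref_sample = NULL, trim_m = 0.30,
                        trim_a = 0.05) {
  assert_count_matrix(counts)
  if (ncol(counts) < 2L) stop2("TMM needs at least 2 samples")
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop2("column(s) with all-zero counts: ",
          paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  if (trim_m < 0 || trim_m >= 0.5 || trim_a < 0 || trim_a >= 0.5) {
    stop2("trim fractions must be in [0, 0.5)")
  }

  if (is.null(ref_sample)) {
    uq <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(counts))
           else as.integer(ref_sample)
    if (is.na(ref) || ref < 1 || ref > ncol(counts)) {
      stop2("ref_sample not found")
    }
  }

  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# One-sample-vs-reference weighted trimmed mean of M-values.
tmm_pair <- function(x, y, nx, ny, trim_m, trim_a) {
  keep <- x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0L) stop2("no features expressed in both samples")
  m <- log2((x / nx) / (y / ny))
  a <- 0.5 * log2((x / nx) * (y / ny))
  w <- 1 / ((nx - x) / (nx * x) + (ny - y) / (ny * y))
  if (max(abs(m)) < 1e-6) return(1) # identical composition
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m, ties.method = "first")
  ra_ <- rank(a, ties.method = "first")
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep2)) {
    stop2("no features remain after trimming; widen trim_m/trim_a")
  }
  2^(sum(w[keep2] * m[keep2]) / sum(w[keep2]))
}

#' Empirical-Bayes prior for variance moderation
#'
#' Estimates the prior variance `s0_sq` and prior degrees of freedom `d0`
#' of the scaled inverse-chi-square prior assumed for the per-feature true
#' variances, by method of moments on the log sample variances (which under
#' the model follow a shifted log-F distribution). `d0` is capped at 1e9,
#' which represents an effectively infinite prior (complete shrinkage to
#' `s0_sq`).
#'
#' @param s2 per-feature sample variances (pooled within groups).
#' @param df residual degrees of freedom of each `s2` (scalar).
#' @return list with elements `s0_sq` and `d0`.
#' @export
estimate_ebayes_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) {
    stop2("cannot estimate a variance prior: fewer than 2 positive ",
          "sample variances (degenerate prior)")
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    if (d0 > 1e9) d0 <- 1e9
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- 1e9
    s0_sq <- exp(emean)
  }
  list(s0_sq = s0_sq, d0 = d0)
}

# Newton inversion of the trigamma function (x > 0).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Moderated two-sample t-test
#'
#' Per-feature two-sample comparison in which the pooled sample variance is
#' shrunk toward a prior variance: the posterior variance is
#' `(d0 * s0_sq + d * s2) / (d0 + d)` with `d` the residual degrees of
#' freedom, and the moderated t statistic is referred to a t distribution
#' with `d0 + d` degrees of freedom. With `d0 = 0` this is the ordinary
#' equal-variance t-test.
#'
#' The log2 fold change is `mean(level 2) - mean(level 1)` in the order of
#' the factor levels of `groups`; `avg_score` is the mean of the two group
#' means (the MvA x-axis).
#'
#' @param x numeric matrix of scores (e.g. log2 values), features x samples.
#' @param groups two-level factor over the columns of `x`.
#' @param prior list with `s0_sq` and `d0`, or `NULL` to estimate it with
#'   [estimate_ebayes_prior()].
#' @param alpha significance threshold on the BH-adjusted p-value.
#' @param strict if `TRUE` (default) significance is `adj_p < alpha`,
#'   otherwise `adj_p <= alpha`.
#' @return data.frame with columns `feature_id`, `log2fc`, `avg_score`,
#'   `t_mod`, `p`, `adj_p`, `significant`; the estimated or supplied prior
#'   is attached as attribute `"prior"`.
#' @export
moderated_t <- function(x, groups, prior = NULL, alpha = 0.01,
                        strict = TRUE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (any(!is.finite(x))) stop2("scores must be finite")
  groups <- check_groups(groups, ncol(x))
  g1 <- groups == levels(groups)[1]
  g2 <- groups == levels(groups)[2]
  n1 <- sum(g1); n2 <- sum(g2)
  if (is.null(prior) && (n1 < 2L || n2 < 2L)) {
    stop2("each group needs >= 2 samples when the prior is estimated")
  }
  if (n1 < 1L || n2 < 1L) stop2("each group needs >= 1 sample")

  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  d <- n1 + n2 - 2L
  ss <- numeric(nrow(x))
  if (n1 > 1L) ss <- ss + rowSums((x[, g1, drop = FALSE] - m1)^2)
  if (n2 > 1L) ss <- ss + rowSums((x[, g2, drop = FALSE] - m2)^2)
  s2 <- if (d > 0) ss / d else rep(NA_real_, nrow(x))

  if (is.null(prior)) {
    if (all(ss == 0)) {
      stop2("all features have zero variance (degenerate prior)")
    }
    prior <- estimate_ebayes_prior(s2, d)
  }
  if (prior$s0_sq < 0 || prior$d0 < 0) stop2("invalid prior")

  s2_post <- (prior$d0 * prior$s0_sq + d * s2) / (prior$d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  delta <- m2 - m1
  t_mod <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, Inf * sign(delta)))
  df_tot <- prior$d0 + d
  p <- 2 * pt(abs(t_mod), df = df_tot, lower.tail = FALSE)
  adj <- bh_adjust(p)

  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("feature", seq_len(nrow(x)))
  res <- data.frame(
    feature_id = ids,
    log2fc = delta,
    avg_score = (m1 + m2) / 2,
    t_mod = t_mod,
    p = p,
    adj_p = adj,
    significant = if (strict) adj < alpha else adj <= alpha,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(res, "prior") <- prior
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values controlling the false discovery rate; the
#'   adjustment is monotone and bounded by 1.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop2("p-values must be finite and in [0, 1]")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of the absolute difference between the two empirical
#' cumulative distribution functions, evaluated at every distinct pooled
#' data point (so ties are handled deterministically). The p-value uses the
#' asymptotic Kolmogorov distribution, appropriate for the sample sizes
#' (thousands of genes) this pipeline works at.
#'
#' @param x,y non-empty numeric samples.
#' @return list with `d` (statistic) and `p` (asymptotic two-sided p-value).
#' @export
ks_two_sample <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0L || length(y) == 0L) stop2("samples must be non-empty")
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(v) mean(x <= v), numeric(1))
  fy <- vapply(pts, function(v) mean(y <= v), numeric(1))
  d <- max(abs(fx - fy))
  n <- length(x) * length(y) / (length(x) + length(y))
  lambda <- sqrt(n) * d
  p <- ks_asymptotic_p(lambda)
  list(d = d, p = p)
}

# Complementary asymptotic Kolmogorov distribution: 2 sum (-1)^(k-1) exp(-2 k^2 t^2)
ks_asymptotic_p <- function(t) {
  if (t <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(1, max(0, p))
}

#' Hypergeometric overlap of two gene sets
#'
#' Expected overlap under random draws and exact hypergeometric tail
#' probabilities for the observed overlap. The enrichment p-value is
#' `P(X >= k)` and the depletion p-value `P(X <= k)`; both tails include
#' the observed point mass, so they sum to >= 1.
#'
#' @param n1,n2 sizes of the two sets.
#' @param N universe size.
#' @param k_observed observed overlap, or `NULL` for expectation only.
#' @return list with `expected`, `p_depletion`, `p_enrichment`.
#' @examples
#' # two sets of ~950 genes in a 12,056-gene universe share ~74 by chance
#' hypergeom_overlap(937, 958, 12056)$expected
#' @export
hypergeom_overlap <- function(n1, n2, N, k_observed = NULL) {
  if (N < 1 || n1 < 0 || n2 < 0 || n1 > N || n2 > N) {
    stop2("need 0 <= n1, n2 <= N with N >= 1")
  }
  expected <- n1 * n2 / N
  p_dep <- p_enr <- NA_real_
  if (!is.null(k_observed)) {
    k <- k_observed
    if (k < 0 || k > min(n1, n2) || k < n1 + n2 - N) {
      stop2("k_observed inconsistent with set sizes")
    }
    p_enr <- phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)
    p_dep <- phyper(k, n1, N - n1, n2, lower.tail = TRUE)
  }
  list(expected = expected, p_depletion = p_dep, p_enrichment = p_enr)
}
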