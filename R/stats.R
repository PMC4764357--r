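# Cohort statistics: pooled two-sample t-tests per gene, Storey q-values,
# Spearman copy-number/expression correlation with limit-of-detection
# exclusion, replicate concordance and cohort summaries.

#' Pooled-variance t-test per gene
#'
#' Two-sided equal-variance t-test of amplified vs non-amplified group
#' means for every gene (row) of a normalized log2 expression matrix, on
#' `n1 + n2 - 2` degrees of freedom. Genes with zero pooled variance and
#' equal means are reported with `t = 0`, `p = 1` and `zero_variance =
#' TRUE` so cohort runs never abort on constant probes.
#'
#' @param values Genes x samples matrix of normalized log2 values.
#' @param amplified Logical per-sample group label (TRUE = amplified).
#' @return `data.frame`: `gene`, `mean_amp`, `mean_non`, `difference`
#'   (amplified minus non-amplified, log2 units), `t`, `df`, `p`,
#'   `zero_variance`.
#' @export
ttest_per_gene <- function(values, amplified) {
  values <- as.matrix(values)
  amplified <- as.logical(amplified)
  if (length(amplified) != ncol(values)) {
    stop("group labels must match the number of sample columns")
  }
  n1 <- sum(amplified); n2 <- sum(!amplified)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  a <- values[, amplified, drop = FALSE]
  b <- values[, !amplified, drop = FALSE]
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  ss1 <- rowSums((a - m1)^2); ss2 <- rowSums((b - m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, (m1 - m2) / se,
                  ifelse(abs(m1 - m2) < 1e-12, 0, Inf * sign(m1 - m2)))
  p <- ifelse(se > 0, 2 * stats::pt(-abs(tstat), df),
              ifelse(abs(m1 - m2) < 1e-12, 1, 0))
  genes <- rownames(values)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(values)))
  data.frame(gene = genes, mean_amp = m1, mean_non = m2,
             difference = m1 - m2, t = tstat, df = df, p = p,
             zero_variance = se == 0, row.names = NULL)
}

#' Storey q-values
#'
#' Estimates the null proportion at a single tuning point,
#' `pi0 = min(1, #\{p > lambda\} / ((1 - lambda) m))`, then computes
#' step-down q-values: with p sorted ascending,
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`, returned in input order.
#' Forcing `pi0 = 1` makes the result identical to Benjamini-Hochberg
#' adjusted p-values.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param lambda Tuning point for the null-proportion estimate.
#' @param pi0 Optional forced null proportion (overrides the estimate).
#' @return Vector of q-values in input order, with attribute `pi0`.
#' @export
storey_qvalues <- function(p, lambda = 0.5, pi0 = NULL) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  attr(q, "pi0") <- pi0
  q
}

#' Spearman correlation of copy number with expression, per gene
#'
#' Correlates each gene's expression across samples with a per-sample
#' copy-number covariate (e.g. FGFR1 qPCR inferred GCN). Genes not
#' detected in more than half of the samples are excluded (LOD rule), as
#' are genes whose values are all tied. rho uses average ranks for ties;
#' the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param values Genes x samples matrix of normalized log2 values.
#' @param detected Logical matrix of the same shape (raw-count detection
#'   flags).
#' @param cn Per-sample numeric copy number.
#' @param min_n Minimum paired observations required per gene.
#' @return `data.frame`: `gene`, `rho`, `p`, `n`, `excluded`, `reason`.
#' @export
spearman_cn_expression <- function(values, detected, cn, min_n = 4) {
  values <- as.matrix(values)
  if (length(cn) != ncol(values)) {
    stop("cn must have one value per sample column")
  }
  detected <- as.matrix(detected)
  genes <- rownames(values)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(values)))
  res <- lapply(seq_len(nrow(values)), function(g) {
    det_frac <- mean(!detected[g, ])
    if (det_frac > 0.5) {
      return(data.frame(gene = genes[g], rho = NA_real_, p = NA_real_,
                        n = ncol(values), excluded = TRUE,
                        reason = "not detected in >50% of samples"))
    }
    x <- cn; y <- values[g, ]
    if (length(x) < min_n) {
      stop("gene ", genes[g], ": fewer than ", min_n, " paired observations")
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(gene = genes[g], rho = NA_real_, p = NA_real_,
                        n = length(x), excluded = TRUE,
                        reason = "all values tied; rho undefined"))
    }
    rho <- stats::cor(rank(x), rank(y))
    n <- length(x)
    p <- if (abs(rho) >= 1) 0 else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tt), n - 2)
    }
    data.frame(gene = genes[g], rho = rho, p = p, n = n, excluded = FALSE,
               reason = "")
  })
  do.call(rbind, res)
}

#' Squared Pearson correlation of two replicate profiles
#'
#' @param values_a,values_b Equal-length numeric vectors (paired
#'   normalized values of two replicate assays).
#' @return Squared Pearson correlation coefficient.
#' @export
replicate_concordance <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) < 3) {
    stop("replicate vectors must be paired, length >= 3")
  }
  if (any(!is.finite(values_a)) || any(!is.finite(values_b))) {
    stop("replicate values must be finite")
  }
  if (stats::sd(values_a) == 0 || stats::sd(values_b) == 0) {
    stop("zero variance in a replicate vector; r^2 undefined")
  }
  stats::cor(values_a, values_b)^2
}

#' Summarize a cohort differential-expression run
#'
#' Splits genes significant at `q < q_threshold` by direction and, for
#' each gene, reports the fraction of amplified samples whose expression
#' exceeds the all-sample mean (the enrichment statistic commonly quoted
#' for FGFR1).
#'
#' @param results Output of [ttest_per_gene()] with a `q` column appended.
#' @param values Genes x samples matrix used for the tests.
#' @param amplified Logical per-sample group label.
#' @param q_threshold Significance cut-off on q.
#' @return List: `significant_up`, `significant_down` (gene vectors),
#'   `n_significant`, `above_mean_fraction` (named per-gene vector over
#'   amplified samples), `q_threshold`.
#' @export
summarize_cohort <- function(results, values, amplified,
                             q_threshold = 0.05) {
  if (!"q" %in% names(results)) stop("results need a q column")
  sig <- results$q < q_threshold
  values <- as.matrix(values)
  overall_mean <- rowMeans(values)
  amp_vals <- values[, as.logical(amplified), drop = FALSE]
  above <- rowMeans(amp_vals > overall_mean)
  names(above) <- rownames(values)
  list(
    significant_up = results$gene[sig & results$difference > 0],
    significant_down = results$gene[sig & results$difference < 0],
    n_significant = sum(sig),
    above_mean_fraction = above,
    q_threshold = q_threshold
  )
}

#' Recover the expression/copy-number coupling slope
#'
#' Regresses normalized log2 expression on `log2(CN/2)` gene by gene
#' across samples and averages the slopes over genes with copy-number
#' spread, estimating the generative coupling `beta`.
#'
#' @param values Genes x samples matrix of normalized log2 expression.
#' @param cn Genes x samples matrix of copy numbers (same dimnames).
#' @param min_spread Minimum SD of `log2(CN/2)` for a gene to contribute.
#' @return List: `beta_hat` (mean slope), `per_gene` slopes.
#' @export
estimate_cn_expression_slope <- function(values, cn, min_spread = 0.1) {
  values <- as.matrix(values); cn <- as.matrix(cn)
  common <- intersect(rownames(values), rownames(cn))
  if (length(common) == 0) stop("no genes shared between values and cn")
  slopes <- vapply(common, function(g) {
    x <- log2(cn[g, ] / 2)
    if (stats::sd(x) < min_spread) return(NA_real_)
    stats::cov(x, values[g, ]) / stats::var(x)
  }, numeric(1))
  list(beta_hat = mean(slopes, na.rm = TRUE), per_gene = slopes)
}
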