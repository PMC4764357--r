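# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use explicit loops / naive formulas, never the
# package's own code paths.

# Exhaustive circular-arc scan: same statistic and tie-break rules as the
# segmentation kernel, evaluated arc by arc in plain R.
oracle_best_arc <- function(x, mw = 2) {
  n <- length(x)
  S <- c(0, cumsum(x))
  ss <- sum(x^2)
  stot <- S[n + 1]
  best <- list(i = -1L, j = -1L, t = -1, k = n + 1L)
  for (i in 0:(n - mw)) {
    for (j in (i + mw):min(n, i + n - mw)) {
      k <- j - i
      m_in <- (S[j + 1] - S[i + 1]) / k
      m_out <- (stot - S[j + 1] + S[i + 1]) / (n - k)
      d <- abs(m_in - m_out)
      pv <- if (n > 2) {
        (ss - k * m_in^2 - (n - k) * m_out^2) / (n - 2)
      } else 0
      t <- if (pv <= 1e-12) {
        if (d > 1e-12) 1e12 + d else 0
      } else {
        d / sqrt(pv * (1 / k + 1 / (n - k)))
      }
      tol <- 1e-9 * max(1, t, best$t)
      if (t > best$t + tol ||
          (abs(t - best$t) <= tol && k < best$k)) {
        best <- list(i = i, j = j, t = t, k = k)
      }
    }
  }
  best
}

# FISH scoring by explicit loops over nuclei.
oracle_fish <- function(nuclei, ratio_thr = 2, cluster_thr = 0.10) {
  tot_f <- 0; tot_c <- 0; n_cl <- 0
  for (r in seq_len(nrow(nuclei))) {
    tot_f <- tot_f + nuclei$fgfr1_spots[r]
    tot_c <- tot_c + nuclei$cen8_spots[r]
    if (nuclei$cluster[r]) n_cl <- n_cl + 1
  }
  ratio <- tot_f / tot_c
  cf <- n_cl / nrow(nuclei)
  list(ratio = ratio, cluster_fraction = cf,
       amplified = ratio >= ratio_thr || cf >= cluster_thr)
}

# Spearman rho by ranking with explicit tie handling, then the Pearson
# product-moment formula computed with loops.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_along(rx)) {
    num <- num + (rx[i] - mx) * (ry[i] - my)
    dx <- dx + (rx[i] - mx)^2
    dy <- dy + (ry[i] - my)^2
  }
  num / sqrt(dx * dy)
}

# Per-gene copy number by averaging segment means base pair by base pair
# (coarse-grained to `step` bp for speed; exact when boundaries are
# multiples of step).
oracle_gene_cn <- function(segments, gene_start, gene_end, step = 1) {
  pos <- seq(gene_start, gene_end - 1, by = step)
  vals <- rep(NA_real_, length(pos))
  for (s in seq_len(nrow(segments))) {
    inside <- pos >= segments$start[s] & pos < segments$end[s]
    vals[inside] <- segments$mean_cn[s]
  }
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

# A small deterministic raw count matrix with the standard control layout.
make_test_raw <- function(n_lanes = 3, endo = NULL, seed = 1) {
  set.seed(seed)
  genes <- paste0("G", 1:5)
  if (is.null(endo)) {
    endo <- matrix(rpois(5 * n_lanes, 500), 5, n_lanes)
  }
  hk <- matrix(rpois(2 * n_lanes, 800), 2, n_lanes)
  pos <- matrix(rep(c(2000, 500, 125, 30, 8, 2), n_lanes), 6, n_lanes)
  neg <- matrix(rpois(8 * n_lanes, 5), 8, n_lanes)
  counts <- rbind(endo, hk, pos, neg)
  rownames(counts) <- c(genes, "HK1", "HK2", paste0("POS_", LETTERS[1:6]),
                        paste0("NEG_", LETTERS[1:8]))
  raw_count_matrix(counts,
                   c(rep("endogenous", 5), rep("housekeeping", 2),
                     rep("positive_control", 6), rep("negative_control", 8)),
                   c(rep(NA, 7), 128, 32, 8, 2, 0.5, 0.125, rep(NA, 8)))
}

# Hand-built ground-truth object with prescribed FGFR1 copy numbers and
# no expression noise, for closed-form assay checks.
make_test_truth <- function(cn_values, config, catalog = make_gene_catalog()) {
  n <- length(cn_values)
  ids <- sprintf("S%02d", seq_len(n))
  archs <- lapply(cn_values, function(cn) {
    if (cn == 2) {
      data.frame(start = 36e6, end = 42e6, cn = 2)
    } else {
      data.frame(start = c(36e6, 37.5e6, 39.5e6),
                 end = c(37.5e6, 39.5e6, 42e6), cn = c(2, cn, 2))
    }
  })
  names(archs) <- ids
  genes <- catalog[catalog$probe_class %in% c("endogenous", "housekeeping"), ]
  mid <- (genes$start + genes$end) / 2
  true_cn <- matrix(2, nrow(genes), n, dimnames = list(genes$gene, ids))
  for (j in seq_len(n)) {
    on8 <- genes$chromosome == "chr8" & mid >= 36e6 & mid < 42e6
    true_cn[on8, j] <- amplicon8p:::arch_cn(archs[[j]], mid[on8])
  }
  base <- rep(8, nrow(genes)); names(base) <- genes$gene
  expression <- base + config$beta * log2(true_cn / 2)
  truth <- list(
    samples = data.frame(sample = ids, amplified = cn_values > 4,
                         lane_factor = rep(1, n)),
    architectures = archs, true_cn = true_cn, expression = expression,
    base_log2 = base, config = config, catalog = catalog
  )
  class(truth) <- "amp_truth"
  truth
}
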