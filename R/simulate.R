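# Cohort simulator: amplicon architectures with ground truth, and the four
# assay read-outs (nanoString counts, qPCR Ct, FISH nuclei, aCGH ratios).
#
# RNG discipline: simulate_cohort() seeds with config$seed; the assay
# simulators seed with fixed offsets (+1 counts, +2 qPCR, +3 FISH) and
# simulate_acgh() with a per-sample offset (+4000 + sample index) so a
# subset of samples reproduces the same profiles as a full run.

#' Simulate a tumour cohort with ground-truth amplicon architectures
#'
#' Draws, for each sample, an 8p11-12 amplicon architecture (piecewise
#' constant copy number tiling the 36-42 Mb chr8 window), per-gene true copy
#' numbers (architecture CN at the gene midpoint; genes off the window are
#' diploid), latent log2 expression coupled to copy number with slope
#' `beta`, and a per-lane technical factor. Exactly
#' `round(n_samples * frac_amplified)` samples carry a plateau amplicon
#' covering FGFR1 with CN > 4 (optionally topped by a focal peak offset
#' from FGFR1); non-amplified samples may carry minor gains that never
#' include FGFR1.
#'
#' @param config A [sim_config()].
#' @param catalog A gene catalog from [make_gene_catalog()].
#' @return An object of class `amp_truth`: list with elements `samples`
#'   (data frame: sample, amplified, lane_factor), `architectures` (named
#'   list of (start, end, cn) data frames), `true_cn` and `expression`
#'   (gene x sample matrices over endogenous + housekeeping probes),
#'   `base_log2` (per-gene baseline log2 expression), `config`, `catalog`.
#' @export
simulate_cohort <- function(config, catalog = make_gene_catalog()) {
  config <- validate_sim_config(config)
  catalog <- validate_catalog(catalog)
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("SAMPLE_%03d", seq_len(n))
  n_amp <- round(n * config$frac_amplified)
  amplified <- rep(FALSE, n)
  if (n_amp > 0) amplified[sample.int(n, n_amp)] <- TRUE

  archs <- lapply(amplified, function(a) build_architecture(a, config))
  names(archs) <- ids

  genes <- catalog[catalog$probe_class %in% c("endogenous", "housekeeping"), ]
  mid <- (genes$start + genes$end) / 2
  on_arm <- genes$chromosome == "chr8" & mid >= ARM_START & mid < ARM_END

  true_cn <- matrix(2, nrow = nrow(genes), ncol = n,
                    dimnames = list(genes$gene, ids))
  for (j in seq_len(n)) {
    true_cn[on_arm, j] <- arch_cn(archs[[j]], mid[on_arm])
  }

  hk <- genes$probe_class == "housekeeping"
  base_log2 <- ifelse(hk, stats::runif(nrow(genes), 9.5, 11),
                      stats::runif(nrow(genes), 6, 11))
  names(base_log2) <- genes$gene
  eps <- matrix(stats::rnorm(nrow(genes) * n, 0, config$expr_noise_sd),
                nrow = nrow(genes))
  expression <- base_log2 + config$beta * log2(true_cn / 2) + eps
  dimnames(expression) <- dimnames(true_cn)

  lane_factor <- stats::rlnorm(n, 0, config$lane_factor_sdlog)

  truth <- list(
    samples = data.frame(sample = ids, amplified = amplified,
                         lane_factor = lane_factor),
    architectures = archs, true_cn = true_cn, expression = expression,
    base_log2 = base_log2, config = config, catalog = catalog
  )
  class(truth) <- "amp_truth"
  truth
}

# Piecewise-constant architecture over [ARM_START, ARM_END).
build_architecture <- function(amplified, cfg) {
  pieces <- list()  # list of c(start, end, cn), later overlaid on CN 2
  if (amplified) {
    w <- stats::runif(1, 1e6, 3e6)
    mode <- sample(c("telomeric", "at_fgfr1", "centromeric"), 1,
                   prob = cfg$p_center)
    if (mode == "at_fgfr1") {
      c0 <- (FGFR1_START + FGFR1_END) / 2
      left <- c0 - w / 2; right <- c0 + w / 2
    } else if (mode == "telomeric") {
      right <- FGFR1_END + stats::runif(1, 5e4, 3e5)
      left <- right - w
    } else {
      left <- FGFR1_START - stats::runif(1, 5e4, 3e5)
      right <- left + w
    }
    left <- max(left, ARM_START); right <- min(right, ARM_END)
    plateau_cn <- stats::runif(1, cfg$plateau_cn_range[1],
                               cfg$plateau_cn_range[2])
    pieces[[1]] <- c(left, right, plateau_cn)
    if (stats::runif(1) < cfg$focal_peak_prob) {
      pw <- stats::runif(1, 2e5, 5e5)
      gap <- stats::runif(1, 1e5, 4e5)
      if (mode == "centromeric") {
        pl <- FGFR1_END + gap; pr <- min(pl + pw, right)
      } else {
        pr <- FGFR1_START - gap; pl <- max(pr - pw, left)
      }
      if (pr - pl >= 5e4) {
        peak_cn <- stats::runif(1, cfg$focal_cn_range[1],
                                cfg$focal_cn_range[2])
        pieces[[2]] <- c(pl, pr, peak_cn)
      }
    }
  } else if (stats::runif(1) < cfg$minor_gain_prob) {
    n_gains <- sample(1:2, 1)
    for (k in seq_len(n_gains)) {
      gw <- stats::runif(1, 5e5, 1.5e6)
      side <- sample(c("telomeric", "centromeric"), 1)
      if (side == "telomeric") {
        gl <- stats::runif(1, ARM_START, FGFR1_START - gw - 5e4)
      } else {
        gl <- stats::runif(1, FGFR1_END + 5e4, ARM_END - gw)
      }
      cn <- stats::runif(1, cfg$minor_gain_cn_range[1],
                         cfg$minor_gain_cn_range[2])
      pieces[[length(pieces) + 1]] <- c(gl, gl + gw, cn)
    }
  }
  overlay_pieces(pieces)
}

# Overlay gain pieces (later pieces win) on a diploid arm and return the
# tiling segmentation.
overlay_pieces <- function(pieces) {
  bp <- sort(unique(c(ARM_START, ARM_END,
                      unlist(lapply(pieces, function(p) p[1:2])))))
  bp <- bp[bp >= ARM_START & bp <= ARM_END]
  starts <- bp[-length(bp)]; ends <- bp[-1]
  cn <- rep(2, length(starts))
  mids <- (starts + ends) / 2
  for (p in pieces) {
    hit <- mids >= p[1] & mids < p[2]
    cn[hit] <- p[3]
  }
  keep <- ends > starts
  arch <- data.frame(start = starts[keep], end = ends[keep], cn = cn[keep])
  # merge runs of identical CN so the architecture is minimal
  run <- cumsum(c(TRUE, diff(arch$cn) != 0))
  data.frame(start = as.numeric(tapply(arch$start, run, min)),
             end = as.numeric(tapply(arch$end, run, max)),
             cn = as.numeric(tapply(arch$cn, run, `[`, 1)),
             row.names = NULL)
}

# Copy number of an architecture at positions `pos` (vectorised).
arch_cn <- function(arch, pos) {
  idx <- findInterval(pos, arch$start)
  idx[idx < 1] <- 1
  arch$cn[idx]
}

#' Simulate nanoString-style raw counts for a cohort
#'
#' Endogenous and housekeeping counts are drawn with mean
#' `lane_factor * 2^latent_log2_expression`; negative controls with mean
#' `lambda_bg` (Poisson); positive controls with mean
#' `pos_scale * nominal_level * lane_factor`. Count noise is negative
#' binomial with the configured dispersion; a dispersion of exactly 0
#' returns the closed-form means themselves (deterministic validation
#' mode).
#'
#' @inheritParams simulate_cohort
#' @param truth Output of [simulate_cohort()].
#' @param catalog Catalog used to build `truth`.
#' @return A [raw_count_matrix()] (probes x lanes).
#' @export
simulate_nanostring <- function(truth, catalog = truth$catalog,
                                config = truth$config) {
  set.seed(config$seed + 1L)
  ids <- truth$samples$sample
  lf <- truth$samples$lane_factor
  mu <- matrix(NA_real_, nrow = nrow(catalog), ncol = length(ids),
               dimnames = list(catalog$gene, ids))
  expr_rows <- catalog$probe_class %in% c("endogenous", "housekeeping")
  mu[expr_rows, ] <- sweep(2^truth$expression[catalog$gene[expr_rows], ,
                                              drop = FALSE], 2, lf, `*`)
  pos <- catalog$probe_class == "positive_control"
  mu[pos, ] <- config$pos_scale * catalog$nominal_level[pos] %o% lf
  neg <- catalog$probe_class == "negative_control"
  mu[neg, ] <- config$lambda_bg

  if (config$dispersion == 0) {
    counts <- mu
  } else {
    counts <- mu
    nb <- expr_rows | pos
    counts[nb, ] <- stats::rnbinom(sum(nb) * length(ids),
                                   mu = mu[nb, ], size = 1 / config$dispersion)
    counts[neg, ] <- stats::rpois(sum(neg) * length(ids), mu[neg, ])
  }
  raw_count_matrix(counts, catalog$probe_class, catalog$nominal_level)
}

# Genomic positions probed by the three FGFR1 qPCR assays, and the cycle
# intercepts of each assay (Ct at one template copy... at CN 1).
QPCR_ASSAYS <- data.frame(
  assay = c("fgfr1_5p", "fgfr1_mid", "fgfr1_3p"),
  position = c(FGFR1_START + 1000, (FGFR1_START + FGFR1_END) / 2,
               FGFR1_END - 1000),
  c0 = c(26, 26.5, 27)
)
QPCR_REF_C0 <- 25

#' Simulate quadruplicate qPCR Ct values
#'
#' For each sample, each of the three FGFR1 assays (5', middle, 3') and the
#' reference locus (fixed CN 2) yields 4 replicate Ct values following
#' `Ct = c0_assay - log2(CN at assay locus) + Normal(0, sigma_ct)`. A
#' diploid calibrator sample (`CALIBRATOR`) is included for every assay.
#'
#' @inheritParams simulate_nanostring
#' @return A `data.frame` (sample, assay, replicate, ct) of class `ct_table`
#'   with attribute `calibrator = "CALIBRATOR"`.
#' @export
simulate_qpcr <- function(truth, config = truth$config) {
  set.seed(config$seed + 2L)
  ids <- c("CALIBRATOR", truth$samples$sample)
  rows <- list()
  for (s in ids) {
    for (a in seq_len(nrow(QPCR_ASSAYS))) {
      cn <- if (s == "CALIBRATOR") 2 else
        arch_cn(truth$architectures[[s]], QPCR_ASSAYS$position[a])
      ct <- QPCR_ASSAYS$c0[a] - log2(cn) +
        stats::rnorm(4, 0, config$sigma_ct)
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, assay = QPCR_ASSAYS$assay[a], replicate = 1:4, ct = ct)
    }
    ct <- QPCR_REF_C0 - log2(2) + stats::rnorm(4, 0, config$sigma_ct)
    rows[[length(rows) + 1]] <- data.frame(
      sample = s, assay = "reference", replicate = 1:4, ct = ct)
  }
  out <- do.call(rbind, rows)
  attr(out, "calibrator") <- "CALIBRATOR"
  class(out) <- c("ct_table", "data.frame")
  out
}

#' Simulate per-nucleus FISH spot counts
#'
#' Per nucleus, FGFR1 spots are Poisson with mean equal to the sample's
#' FGFR1 copy number (optionally perturbed per nucleus by log-normal
#' heterogeneity), CEN-8 spots are zero-truncated Poisson with mean 2, and
#' a gene-cluster flag is Bernoulli with a probability that is 0 for CN <= 4
#' and increases with CN above 4 (or a fixed configured probability).
#'
#' @inheritParams simulate_nanostring
#' @return A `data.frame` (sample, nucleus, fgfr1_spots, cen8_spots,
#'   cluster) of class `fish_table`.
#' @export
simulate_fish <- function(truth, config = truth$config) {
  set.seed(config$seed + 3L)
  fmid <- (FGFR1_START + FGFR1_END) / 2
  m <- config$nuclei_per_sample
  rows <- lapply(seq_len(nrow(truth$samples)), function(j) {
    s <- truth$samples$sample[j]
    cn <- arch_cn(truth$architectures[[s]], fmid)
    cn_i <- if (config$fish_cn_sd > 0) {
      cn * exp(stats::rnorm(m, 0, config$fish_cn_sd))
    } else rep(cn, m)
    fgfr1 <- stats::rpois(m, cn_i)
    cen8 <- stats::rpois(m, 2)
    # redraw nuclei with no signal at all (unscoreable); conditioning on
    # the joint event keeps the expected FGFR1/CEN-8 ratio unbiased
    while (any(z <- fgfr1 == 0 & cen8 == 0)) {
      fgfr1[z] <- stats::rpois(sum(z), cn_i[z])
      cen8[z] <- stats::rpois(sum(z), 2)
    }
    p <- fish_cluster_probability(cn_i, config)
    data.frame(sample = s, nucleus = seq_len(m), fgfr1_spots = fgfr1,
               cen8_spots = cen8,
               cluster = stats::runif(m) < p)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fish_table", "data.frame")
  out
}

fish_cluster_probability <- function(cn, config) {
  p <- numeric(length(cn))
  hi <- cn > 4
  if (!is.null(config$fish_cluster_prob)) {
    p[hi] <- config$fish_cluster_prob
  } else {
    p[hi] <- 0.9 * (1 - exp(-(cn[hi] - 4) / 4))
  }
  p
}

#' Simulate two-channel aCGH probe ratios
#'
#' Probes are laid on a regular grid over the chr8 window (spacing
#' `acgh_spacing`), plus `backbone_probes` genome-wide diploid
#' normalization probes spread over the other chromosomes (mirroring the
#' normalization backbone of custom locus-focused arrays; they anchor the
#' genome-wide diploid baseline). Each probe's ratio is
#' `acgh_scale * (CN(pos)/2) * exp(Normal(0, sigma_a))`.
#'
#' @inheritParams simulate_nanostring
#' @param samples Character vector of sample ids to simulate (default all).
#' @return A `data.frame` (sample, chrom, position, ratio) of class
#'   `acgh_table`.
#' @export
simulate_acgh <- function(truth, config = truth$config, samples = NULL) {
  ids <- truth$samples$sample
  if (is.null(samples)) samples <- ids
  stopifnot(all(samples %in% ids))
  win_pos <- seq(ARM_START, ARM_END - 1, by = config$acgh_spacing)
  nb <- config$backbone_probes
  if (nb > 0) {
    chroms <- paste0("chr", c(1:7, 9:22))
    per <- ceiling(nb / length(chroms))
    bb_chrom <- rep(chroms, each = per)[seq_len(nb)]
    bb_pos <- rep(1e6 + 5e4 * seq_len(per), length.out = nb)
  } else {
    bb_chrom <- character(0); bb_pos <- numeric(0)
  }
  rows <- lapply(samples, function(s) {
    j <- match(s, ids)
    set.seed(config$seed + 4000L + j)
    cn <- c(arch_cn(truth$architectures[[s]], win_pos),
            rep(2, length(bb_pos)))
    noise <- if (config$sigma_a > 0) {
      exp(stats::rnorm(length(cn), 0, config$sigma_a))
    } else 1
    data.frame(sample = s,
               chrom = c(rep("chr8", length(win_pos)), bb_chrom),
               position = c(win_pos, bb_pos),
               ratio = config$acgh_scale * (cn / 2) * noise)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("acgh_table", "data.frame")
  out
}
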