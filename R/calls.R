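# FGFR1 amplification calling from qPCR delta-delta-Ct copy numbers
# (mean of three assays > 4) and from FISH nucleus scores
# (FGFR1/CEN-8 ratio >= 2 or >= 10% clustered nuclei).

#' Infer gene copy number from a qPCR Ct table
#'
#' Replicate Ct values are averaged per (sample, assay); for each FGFR1
#' assay `dCt = mean Ct(assay) - mean Ct(reference)`, `ddCt = dCt -
#' dCt(calibrator)` and `GCN = 2 * 2^(-ddCt)` (the calibrator is diploid).
#' A sample is called amplified when the arithmetic mean of the three assay
#' GCNs is strictly greater than 4.
#'
#' @param ct A `data.frame` (sample, assay, replicate, ct) with assays
#'   `fgfr1_5p`, `fgfr1_mid`, `fgfr1_3p`, `reference`, e.g. from
#'   [simulate_qpcr()] or [read_ct_tsv()].
#' @param calibrator Sample id of the diploid calibrator (defaults to the
#'   table's `calibrator` attribute, else `"CALIBRATOR"`).
#' @param gcn_threshold Amplification cut-off on the mean GCN (strict `>`).
#' @return A `data.frame` per sample (calibrator excluded): `gcn_5p`,
#'   `gcn_mid`, `gcn_3p`, `gcn_mean`, `qpcr_amplified`.
#' @export
infer_gcn_qpcr <- function(ct, calibrator = NULL, gcn_threshold = 4) {
  needed <- c("sample", "assay", "replicate", "ct")
  if (!all(needed %in% names(ct))) {
    stop("Ct table needs columns: ", paste(needed, collapse = ", "))
  }
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  if (is.null(calibrator)) {
    calibrator <- attr(ct, "calibrator")
    if (is.null(calibrator)) calibrator <- "CALIBRATOR"
  }
  assays <- c("fgfr1_5p", "fgfr1_mid", "fgfr1_3p")
  mean_ct <- stats::aggregate(ct ~ sample + assay, data = ct, FUN = mean)
  get_ct <- function(s, a) {
    v <- mean_ct$ct[mean_ct$sample == s & mean_ct$assay == a]
    if (length(v) != 1) {
      stop("missing Ct rows for sample '", s, "', assay '", a, "'")
    }
    v
  }
  if (!calibrator %in% mean_ct$sample) {
    stop("calibrator sample '", calibrator, "' not present in Ct table")
  }
  dct_cal <- vapply(assays, function(a) {
    get_ct(calibrator, a) - get_ct(calibrator, "reference")
  }, numeric(1))
  samples <- setdiff(unique(ct$sample), calibrator)
  gcn <- t(vapply(samples, function(s) {
    ref <- get_ct(s, "reference")
    vapply(assays, function(a) {
      ddct <- (get_ct(s, a) - ref) - dct_cal[[a]]
      2 * 2^(-ddct)
    }, numeric(1))
  }, numeric(3)))
  out <- data.frame(sample = samples, gcn_5p = gcn[, 1], gcn_mid = gcn[, 2],
                    gcn_3p = gcn[, 3], row.names = NULL)
  out$gcn_mean <- rowMeans(gcn)
  out$qpcr_amplified <- out$gcn_mean > gcn_threshold
  out
}

#' Score one FISH sample
#'
#' The sample-level ratio is the sum of FGFR1 spots over all nuclei divided
#' by the sum of CEN-8 spots (robust to individual low-count nuclei); the
#' cluster fraction is the proportion of nuclei flagged as carrying a gene
#' cluster. Amplified when ratio >= `ratio_threshold` OR cluster fraction
#' >= `cluster_threshold` (both inclusive).
#'
#' @param nuclei `data.frame` with columns `fgfr1_spots`, `cen8_spots`,
#'   `cluster` for one sample's nuclei.
#' @param ratio_threshold FGFR1/CEN-8 ratio cut-off (default 2).
#' @param cluster_threshold Clustered-nucleus fraction cut-off (default
#'   0.10).
#' @return List `(ratio, cluster_fraction, amplified, n_nuclei)`.
#' @export
fish_evaluate <- function(nuclei, ratio_threshold = 2,
                          cluster_threshold = 0.10) {
  needed <- c("fgfr1_spots", "cen8_spots", "cluster")
  if (!all(needed %in% names(nuclei))) {
    stop("FISH table needs columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(nuclei) < 1) stop("FISH sample has no nuclei")
  tot_cen8 <- sum(nuclei$cen8_spots)
  if (tot_cen8 <= 0) stop("total CEN-8 spot count is zero; ratio undefined")
  ratio <- sum(nuclei$fgfr1_spots) / tot_cen8
  cf <- mean(as.logical(nuclei$cluster))
  list(ratio = ratio, cluster_fraction = cf,
       amplified = ratio >= ratio_threshold || cf >= cluster_threshold,
       n_nuclei = nrow(nuclei))
}

#' Score every sample of a per-nucleus FISH table
#'
#' @param fish `data.frame` with a `sample` column plus the per-nucleus
#'   columns of [fish_evaluate()].
#' @inheritParams fish_evaluate
#' @return `data.frame` per sample: `fish_ratio`, `cluster_fraction`,
#'   `fish_amplified`.
#' @export
fish_call_cohort <- function(fish, ratio_threshold = 2,
                             cluster_threshold = 0.10) {
  res <- lapply(split(fish, fish$sample), fish_evaluate,
                ratio_threshold = ratio_threshold,
                cluster_threshold = cluster_threshold)
  data.frame(sample = names(res),
             fish_ratio = vapply(res, `[[`, numeric(1), "ratio"),
             cluster_fraction = vapply(res, `[[`, numeric(1),
                                       "cluster_fraction"),
             fish_amplified = vapply(res, `[[`, logical(1), "amplified"),
             row.names = NULL)
}

#' Apply the FISH amplification rule to per-sample summary scores
#'
#' For score tables that record per-sample totals rather than per-nucleus
#' counts (sample, fgfr1_total, cen8_total, n_cluster, n_nuclei).
#'
#' @param scores Per-sample score `data.frame`.
#' @inheritParams fish_evaluate
#' @return `data.frame` per sample with `fish_ratio`, `cluster_fraction`,
#'   `fish_amplified`.
#' @export
fish_call_scores <- function(scores, ratio_threshold = 2,
                             cluster_threshold = 0.10) {
  needed <- c("sample", "fgfr1_total", "cen8_total", "n_cluster", "n_nuclei")
  if (!all(needed %in% names(scores))) {
    stop("score table needs columns: ", paste(needed, collapse = ", "))
  }
  if (any(scores$cen8_total <= 0)) stop("sample(s) with zero CEN-8 total")
  ratio <- scores$fgfr1_total / scores$cen8_total
  cf <- scores$n_cluster / scores$n_nuclei
  data.frame(sample = scores$sample, fish_ratio = ratio,
             cluster_fraction = cf,
             fish_amplified = ratio >= ratio_threshold |
               cf >= cluster_threshold)
}

#' Summarize FISH amplification calls over a cohort
#'
#' @param amplified Logical vector of per-sample amplification calls (or a
#'   data frame with a `fish_amplified` column).
#' @return List `(n_amplified, n, fraction, percent)`; `percent` is
#'   rounded to one decimal as conventionally reported.
#' @export
cohort_fish_summary <- function(amplified) {
  if (is.data.frame(amplified)) amplified <- amplified$fish_amplified
  if (length(amplified) < 1) stop("no FISH results to summarize")
  n_amp <- sum(amplified)
  list(n_amplified = n_amp, n = length(amplified),
       fraction = n_amp / length(amplified),
       percent = round(100 * n_amp / length(amplified), 1))
}
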