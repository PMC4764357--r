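# End-to-end pipeline: simulate (or read) a cohort, normalize counts, call
# amplification from FISH and qPCR, segment aCGH profiles, run cohort
# statistics and export the heatmap matrix. All stage outputs are TSV; a
# manifest records seed, thresholds and per-stage row counts so a run can
# be reproduced byte for byte.

#' Pipeline configuration
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed forwarded to the simulator.
#' @param sim A [sim_config()]; its `seed` is overridden by `seed`.
#' @param fish_ratio_threshold FISH FGFR1/CEN-8 amplification cut-off.
#' @param cluster_threshold FISH clustered-nucleus fraction cut-off.
#' @param gcn_threshold qPCR mean-GCN amplification cut-off (strict >).
#' @param q_threshold Significance cut-off on Storey q-values.
#' @param lod_sd LOD rule SD multiplier (fixed at 2 by
#'   [detection_flags()]; recorded for the manifest).
#' @param heatmap_percentiles Clip window for [heatmap_matrix()].
#' @param acgh_samples Number of samples profiled by aCGH (amplified
#'   samples first, topped up with non-amplified ones), mirroring a small
#'   locus-focused aCGH subset; `Inf` profiles everyone.
#' @param n_perm,alpha CBS permutation settings.
#' @param verbose Print stage messages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("amp8p_run_"), seed = 1L,
                            sim = sim_config(seed = seed),
                            fish_ratio_threshold = 2.0,
                            cluster_threshold = 0.10,
                            gcn_threshold = 4.0, q_threshold = 0.05,
                            lod_sd = 2.0,
                            heatmap_percentiles = c(5, 95),
                            acgh_samples = 5, n_perm = 1000, alpha = 0.01,
                            verbose = FALSE) {
  sim$seed <- as.integer(seed)
  cfg <- list(outdir = outdir, seed = as.integer(seed), sim = sim,
              fish_ratio_threshold = fish_ratio_threshold,
              cluster_threshold = cluster_threshold,
              gcn_threshold = gcn_threshold, q_threshold = q_threshold,
              lod_sd = lod_sd, heatmap_percentiles = heatmap_percentiles,
              acgh_samples = acgh_samples, n_perm = n_perm, alpha = alpha,
              verbose = verbose)
  thr <- c(cfg$fish_ratio_threshold, cfg$cluster_threshold,
           cfg$gcn_threshold, cfg$q_threshold, cfg$lod_sd)
  if (any(thr <= 0)) stop("thresholds must be positive")
  if (heatmap_percentiles[1] < 0 || heatmap_percentiles[2] > 100 ||
      heatmap_percentiles[1] >= heatmap_percentiles[2]) {
    stop("heatmap percentiles must satisfy 0 <= low < high <= 100")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full simulate-and-analyse pipeline
#'
#' Stages: simulate cohort and assays; write raw TSVs; read them back
#' (exercising the validated readers); normalize counts; call FGFR1
#' amplification from FISH and qPCR; baseline-adjust and segment the aCGH
#' subset with CBS and summarize per-gene copy number; run cohort
#' statistics (pooled t-tests, Storey q-values, Spearman vs qPCR copy
#' number); export the heatmap matrix; write a manifest. Re-running with
#' the same config produces byte-identical TSVs.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "run.log")
  logf <- function(...) {
    line <- paste0(...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (config$verbose) message(line)
  }
  stage <- function(name, expr) {
    logf("stage ", name, ": start")
    out <- tryCatch(expr, error = function(e) {
      logf("stage ", name, ": FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logf("stage ", name, ": done")
    out
  }
  unlink(log_path)
  p <- function(f) file.path(config$outdir, f)

  catalog <- make_gene_catalog()
  truth <- stage("simulate", {
    truth <- simulate_cohort(config$sim, catalog)
    write_truth_tsv(truth, p("truth.tsv"))
    write_catalog_tsv(catalog, p("catalog.tsv"))
    truth
  })
  n_acgh <- min(config$acgh_samples, nrow(truth$samples))
  acgh_ids <- with(truth$samples,
                   c(sample[amplified], sample[!amplified]))[seq_len(n_acgh)]
  stage("write_assays", {
    write_counts_tsv(simulate_nanostring(truth), p("counts.tsv"))
    write_ct_tsv(simulate_qpcr(truth), p("ct.tsv"))
    write_fish_tsv(simulate_fish(truth), p("fish.tsv"))
    write_acgh_tsv(simulate_acgh(truth, samples = acgh_ids), p("acgh.tsv"))
  })

  raw <- stage("read", read_counts_tsv(p("counts.tsv")))
  ct <- read_ct_tsv(p("ct.tsv"))
  fish <- read_fish_tsv(p("fish.tsv"))
  acgh <- read_acgh_tsv(p("acgh.tsv"))

  norm <- stage("normalize", {
    norm <- normalize_counts(raw)
    write_tsv(data.frame(probe = rownames(norm$values), norm$values,
                         check.names = FALSE), p("normalized.tsv"))
    write_tsv(data.frame(probe = rownames(norm$detected),
                         norm$detected * 1L, check.names = FALSE),
              p("detected.tsv"))
    write_tsv(norm$report, p("normalization_report.tsv"))
    norm
  })

  calls <- stage("callcn", {
    qpcr <- infer_gcn_qpcr(ct, gcn_threshold = config$gcn_threshold)
    fishc <- fish_call_cohort(fish,
                              ratio_threshold = config$fish_ratio_threshold,
                              cluster_threshold = config$cluster_threshold)
    calls <- merge(qpcr, fishc, by = "sample", sort = TRUE)
    write_tsv(calls, p("calls.tsv"))
    calls
  })

  seg <- stage("segment", {
    gene_cn <- list()
    all_segs <- list()
    for (s in acgh_ids) {
      prof <- adjust_baseline(acgh[acgh$sample == s, ])
      segs <- segment_profile(prof, chromosomes = "chr8",
                              alpha = config$alpha, n_perm = config$n_perm,
                              seed = config$seed)
      all_segs[[s]] <- cbind(sample = s, as.data.frame(segs))
      gcn <- gene_copy_number(segs, catalog)
      gene_cn[[s]] <- cbind(sample = s, gcn)
    }
    segs_df <- do.call(rbind, c(all_segs, list(make.row.names = FALSE)))
    write_tsv(segs_df[, c("sample", "chrom", "start", "end", "mean_cn",
                          "n_probes")], p("segments.tsv"))
    cn_df <- do.call(rbind, c(gene_cn, list(make.row.names = FALSE)))
    write_tsv(cn_df, p("gene_cn.tsv"))
    list(segments = segs_df, gene_cn = cn_df)
  })

  stats_out <- stage("stats", {
    endo <- norm$probe_class == "endogenous"
    values <- norm$values[endo, truth$samples$sample, drop = FALSE]
    detected <- norm$detected[endo, truth$samples$sample, drop = FALSE]
    amplified <- calls$fish_amplified[match(truth$samples$sample,
                                            calls$sample)]
    tt <- ttest_per_gene(values, amplified)
    tt$q <- as.numeric(storey_qvalues(tt$p))
    write_tsv(tt, p("stats.tsv"))
    gcn <- calls$gcn_mean[match(truth$samples$sample, calls$sample)]
    sp <- spearman_cn_expression(values, detected, gcn)
    write_tsv(sp, p("spearman.tsv"))
    summary <- summarize_cohort(tt, values, amplified,
                                q_threshold = config$q_threshold)
    volcano <- data.frame(gene = tt$gene, difference = tt$difference,
                          neg_log10_q = -log10(pmax(tt$q, 1e-300)))
    write_tsv(volcano, p("volcano.tsv"))
    list(tests = tt, spearman = sp, summary = summary,
         amplified = amplified, values = values, detected = detected,
         gcn = gcn)
  })

  hm <- stage("heatmap", {
    hm <- heatmap_matrix(stats_out$values, stats_out$detected, catalog,
                         order_by = "gcn", gcn = stats_out$gcn,
                         percentiles = config$heatmap_percentiles)
    write_tsv(data.frame(gene = rownames(hm), hm, check.names = FALSE),
              p("heatmap.tsv"))
    hm
  })

  fish_summary <- cohort_fish_summary(calls)
  manifest <- data.frame(
    key = c("package_version", "seed", "n_samples", "frac_amplified",
            "fish_ratio_threshold", "cluster_threshold", "gcn_threshold",
            "q_threshold", "lod_sd", "heatmap_p_low", "heatmap_p_high",
            "cbs_alpha", "cbs_n_perm", "n_fish_amplified",
            "fish_amplified_percent", "n_qpcr_amplified",
            "n_significant_genes", "n_acgh_samples", "rows_counts",
            "rows_ct", "rows_fish", "rows_acgh", "rows_segments"),
    value = c(as.character(utils::packageVersion("amplicon8p")),
              config$seed, config$sim$n_samples, config$sim$frac_amplified,
              config$fish_ratio_threshold, config$cluster_threshold,
              config$gcn_threshold, config$q_threshold, config$lod_sd,
              config$heatmap_percentiles[1], config$heatmap_percentiles[2],
              config$alpha, config$n_perm, fish_summary$n_amplified,
              fish_summary$percent, sum(calls$qpcr_amplified),
              stats_out$summary$n_significant, length(acgh_ids),
              nrow(raw$counts), nrow(ct), nrow(fish), nrow(acgh),
              nrow(seg$segments))
  )
  write_tsv(manifest, p("manifest.tsv"))
  logf("pipeline complete")
  invisible(list(truth = truth, raw = raw, norm = norm, calls = calls,
                 segments = seg, stats = stats_out, heatmap = hm,
                 fish_summary = fish_summary, manifest = manifest,
                 outdir = config$outdir))
}
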