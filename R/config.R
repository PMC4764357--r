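#' Simulation configuration
#'
#' Collects every tunable of the cohort simulator with defaults chosen to
#' emulate the squamous-NSCLC study conditions: 90 tumours of which 14.4%
#' carry an FGFR1 amplification, a broad plateau amplicon (copy number
#' 4.5-9) with an optional focal peak (CN 9-14) offset from FGFR1, minor
#' non-FGFR1 gains (CN 2.4-2.7) in a fraction of non-amplified samples,
#' expression coupled to copy number with slope `beta` on the log2 scale,
#' negative-binomial count noise, quadruplicate qPCR Ct values, 50 scored
#' nuclei per FISH sample and log-normally perturbed two-channel aCGH
#' ratios on a 6 kb probe grid over the 36-42 Mb chr8 window plus a
#' genome-wide diploid normalization backbone.
#'
#' @param n_samples Number of tumour samples in the cohort.
#' @param frac_amplified Fraction of samples carrying an FGFR1 amplification
#'   (true FGFR1 copy number > 4).
#' @param seed Integer seed; every `simulate_*` function derives its stream
#'   from it, so an identical config reproduces the cohort bit for bit.
#' @param plateau_cn_range Range (min, max) of the broad-amplicon plateau
#'   copy number covering FGFR1.
#' @param focal_cn_range Range of the focal-peak copy number.
#' @param focal_peak_prob Probability an amplified sample carries a focal
#'   peak offset from FGFR1 on top of the plateau.
#' @param p_center Length-3 probability vector that the amplicon center is
#'   telomeric of FGFR1, at FGFR1, or centromeric (sums to 1).
#' @param minor_gain_prob Probability a non-amplified sample carries a minor
#'   gain not covering FGFR1.
#' @param minor_gain_cn_range Copy-number range of such minor gains.
#' @param beta Expression/copy-number coupling: latent log2 expression gains
#'   `beta * log2(CN/2)`.
#' @param expr_noise_sd SD (log2 units) of per-gene, per-sample biological
#'   expression noise.
#' @param lane_factor_sdlog Log-normal SD of the per-lane technical factor.
#' @param dispersion Negative-binomial dispersion of counts
#'   (variance = mu + dispersion * mu^2); 0 switches to exact deterministic
#'   means.
#' @param lambda_bg Mean of negative-control (background) counts.
#' @param pos_scale Counts per fM of positive-control spike-in at lane
#'   factor 1.
#' @param sigma_ct SD (cycles) of qPCR Ct replicate noise.
#' @param acgh_spacing Probe spacing (bp) on the chr8 window.
#' @param sigma_a SD of the log-normal aCGH ratio noise.
#' @param acgh_scale Global two-channel intensity scale `s`; makes baseline
#'   adjustment non-trivial.
#' @param backbone_probes Number of genome-wide diploid normalization probes
#'   emitted outside chr8 (they anchor the genome-wide mean used by
#'   [adjust_baseline()]).
#' @param nuclei_per_sample Nuclei scored per FISH sample.
#' @param fish_cluster_prob Optional fixed cluster probability for nuclei
#'   with FGFR1 CN > 4; `NULL` uses the increasing default link
#'   `0.9 * (1 - exp(-(CN - 4)/4))`.
#' @param fish_cn_sd Log-normal SD of per-nucleus copy-number heterogeneity
#'   (0 = all nuclei share the sample copy number).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 90,
                       frac_amplified = 0.144,
                       seed = 1L,
                       plateau_cn_range = c(4.5, 9),
                       focal_cn_range = c(9, 14),
                       focal_peak_prob = 0.5,
                       p_center = c(telomeric = 0.45, at_fgfr1 = 0.30,
                                    centromeric = 0.25),
                       minor_gain_prob = 0.3,
                       minor_gain_cn_range = c(2.4, 2.7),
                       beta = 1,
                       expr_noise_sd = 0.5,
                       lane_factor_sdlog = 0.25,
                       dispersion = 0.02,
                       lambda_bg = 5,
                       pos_scale = 150,
                       sigma_ct = 0.05,
                       acgh_spacing = 6000,
                       sigma_a = 0.1,
                       acgh_scale = 1.15,
                       backbone_probes = 60000,
                       nuclei_per_sample = 50,
                       fish_cluster_prob = NULL,
                       fish_cn_sd = 0) {
  cfg <- list(
    n_samples = as.integer(n_samples), frac_amplified = frac_amplified,
    seed = as.integer(seed), plateau_cn_range = plateau_cn_range,
    focal_cn_range = focal_cn_range, focal_peak_prob = focal_peak_prob,
    p_center = p_center, minor_gain_prob = minor_gain_prob,
    minor_gain_cn_range = minor_gain_cn_range, beta = beta,
    expr_noise_sd = expr_noise_sd, lane_factor_sdlog = lane_factor_sdlog,
    dispersion = dispersion, lambda_bg = lambda_bg, pos_scale = pos_scale,
    sigma_ct = sigma_ct, acgh_spacing = acgh_spacing, sigma_a = sigma_a,
    acgh_scale = acgh_scale, backbone_probes = as.integer(backbone_probes),
    nuclei_per_sample = as.integer(nuclei_per_sample),
    fish_cluster_prob = fish_cluster_prob, fish_cn_sd = fish_cn_sd
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_samples < 2) stop("n_samples must be >= 2")
  if (cfg$frac_amplified < 0 || cfg$frac_amplified > 1) {
    stop("frac_amplified must lie in [0, 1]")
  }
  pos <- c("lane_factor_sdlog", "pos_scale", "acgh_spacing", "acgh_scale")
  for (p in pos) if (cfg[[p]] <= 0) stop(p, " must be strictly positive")
  nonneg <- c("expr_noise_sd", "dispersion", "lambda_bg", "sigma_ct",
              "sigma_a", "fish_cn_sd", "backbone_probes")
  for (p in nonneg) if (cfg[[p]] < 0) stop(p, " must be non-negative")
  if (cfg$nuclei_per_sample < 1) stop("nuclei_per_sample must be >= 1")
  if (length(cfg$p_center) != 3 || abs(sum(cfg$p_center) - 1) > 1e-8) {
    stop("p_center must be 3 probabilities summing to 1")
  }
  for (r in c("plateau_cn_range", "focal_cn_range", "minor_gain_cn_range")) {
    if (length(cfg[[r]]) != 2 || cfg[[r]][1] > cfg[[r]][2] || cfg[[r]][1] < 0) {
      stop(r, " must be a non-negative (min, max) pair")
    }
  }
  if (!is.null(cfg$fish_cluster_prob) &&
      (cfg$fish_cluster_prob < 0 || cfg$fish_cluster_prob > 1)) {
    stop("fish_cluster_prob must lie in [0, 1]")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Genomic frame shared by the simulator and the catalog: the profiled chr8
# window, FGFR1 position, and pseudo-chromosomes for backbone probes.
ARM_START <- 36e6
ARM_END <- 42e6
FGFR1_START <- 38270000
FGFR1_END <- 38330000
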