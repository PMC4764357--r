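# Count normalization chain: truncated-Poisson background subtraction from
# negative controls, positive-control technical scaling, log2, then a
# sigmoid-shrunk housekeeping (input-amount) correction. Detection flags
# come from the raw counts alone (mean of negatives + 2 SD).

#' Construct a raw count matrix
#'
#' @param counts Numeric probes x lanes matrix of non-negative counts
#'   (integers for real data; the deterministic simulator mode may produce
#'   fractional means).
#' @param probe_class Character vector, one of `endogenous`,
#'   `housekeeping`, `positive_control`, `negative_control` per probe.
#' @param nominal_level Spike-in level for positive controls (`NA`
#'   elsewhere).
#' @return An object of class `raw_counts`.
#' @export
raw_count_matrix <- function(counts, probe_class, nominal_level = NULL) {
  counts <- as.matrix(counts)
  if (length(probe_class) != nrow(counts)) {
    stop("probe_class length must match the number of probe rows")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  for (cls in c("negative_control", "positive_control", "housekeeping")) {
    if (!any(probe_class == cls)) stop("raw counts need at least one ", cls, " probe")
  }
  if (is.null(nominal_level)) nominal_level <- rep(NA_real_, nrow(counts))
  obj <- list(counts = counts, probe_class = probe_class,
              nominal_level = nominal_level)
  class(obj) <- "raw_counts"
  obj
}

#' Estimate per-lane background from negative controls
#'
#' The Poisson maximum-likelihood background estimate is the arithmetic
#' mean of the lane's negative-control counts.
#'
#' @param negative_counts Numeric vector (one lane) or matrix
#'   (negative-control probes x lanes).
#' @return Background mean(s), one per lane.
#' @export
estimate_background <- function(negative_counts) {
  if (length(negative_counts) == 0) stop("no negative-control counts supplied")
  if (is.matrix(negative_counts)) return(colMeans(negative_counts))
  mean(negative_counts)
}

#' Flag probes below the limit of detection
#'
#' A probe is called not detected in a lane when its raw count is below the
#' lane's mean negative-control count plus 2 sample standard deviations
#' (n-1 denominator), approximating a 95% upper bound on background.
#'
#' @param raw A [raw_count_matrix()].
#' @return Logical probes x lanes matrix: `TRUE` = detected.
#' @export
detection_flags <- function(raw) {
  stopifnot(inherits(raw, "raw_counts"))
  neg <- raw$counts[raw$probe_class == "negative_control", , drop = FALSE]
  if (nrow(neg) < 2) {
    stop("detection thresholds need at least 2 negative controls")
  }
  thr <- colMeans(neg) + 2 * apply(neg, 2, stats::sd)
  flags <- sweep(raw$counts, 2, thr, `>=`)
  dimnames(flags) <- dimnames(raw$counts)
  flags
}

#' Background-correct counts (truncated Poisson subtraction)
#'
#' Subtracts the lane background estimate and truncates at zero:
#' `max(count - lambda, 0)`.
#'
#' @param counts Probes x lanes matrix.
#' @param lambda Per-lane background (length 1 or `ncol(counts)`).
#' @return Corrected matrix of the same shape.
#' @export
background_correct <- function(counts, lambda) {
  if (any(lambda < 0)) stop("background lambda must be >= 0")
  pmax(sweep(as.matrix(counts), 2, lambda, `-`), 0)
}

#' Positive-control (technical) normalization
#'
#' Each lane is scaled by `factor_j = mean over lanes of the per-lane
#' positive-control mean / lane j's positive-control mean`, so the grand
#' positive-control level is preserved while lane-to-lane binding
#' efficiency differences are removed.
#'
#' @param corrected Probes x lanes matrix to scale (typically
#'   background-corrected non-control rows).
#' @param positive_counts Raw positive-control counts (probes x lanes).
#' @param summary Per-lane positive-control summary: arithmetic (default)
#'   or geometric mean.
#' @return List with `scaled` (matrix) and `factors` (per lane).
#' @export
technical_normalize <- function(corrected, positive_counts,
                                summary = c("arithmetic", "geometric")) {
  summary <- match.arg(summary)
  positive_counts <- as.matrix(positive_counts)
  lane_mean <- if (summary == "arithmetic") {
    colMeans(positive_counts)
  } else {
    exp(colMeans(log(positive_counts + 0.5)))
  }
  if (any(lane_mean <= 0)) {
    stop("lane(s) with zero positive-control mean: ",
         paste(which(lane_mean <= 0), collapse = ", "))
  }
  factors <- mean(lane_mean) / lane_mean
  list(scaled = sweep(as.matrix(corrected), 2, factors, `*`),
       factors = factors)
}

#' Housekeeping (content) correction with sigmoid shrinkage
#'
#' Computes each lane's offset of mean housekeeping log2 expression from
#' the grand mean and subtracts a shrunk correction
#' `a_j = tau * tanh(offset_j / tau)` from every value in the lane. The
#' correction equals the offset near zero and saturates at `tau`, so
#' input-amount differences are corrected without over-normalizing lanes
#' with extreme housekeeping behaviour.
#'
#' @param log2_matrix Log2-scale probes x lanes matrix (endogenous +
#'   housekeeping rows).
#' @param hk_rows Logical/integer index of housekeeping rows.
#' @param tau Saturation bound in log2 units.
#' @return List with `corrected`, `offsets`, `applied`.
#' @export
housekeeping_correct <- function(log2_matrix, hk_rows, tau = 2) {
  log2_matrix <- as.matrix(log2_matrix)
  hk <- log2_matrix[hk_rows, , drop = FALSE]
  if (nrow(hk) < 1) stop("no housekeeping probes to correct with")
  lane_hk <- colMeans(hk)
  offsets <- lane_hk - mean(lane_hk)
  applied <- tau * tanh(offsets / tau)
  list(corrected = sweep(log2_matrix, 2, applied, `-`),
       offsets = offsets, applied = applied)
}

#' Normalize a raw count matrix
#'
#' Full chain: background correction from negative controls, technical
#' normalization from raw positive controls, `log2(x + 1)`, then the
#' sigmoid-shrunk housekeeping correction. Detection flags are computed
#' from the raw counts before any correction.
#'
#' @param raw A [raw_count_matrix()].
#' @param tau Housekeeping shrinkage bound (log2 units).
#' @param summary Positive-control summary passed to
#'   [technical_normalize()].
#' @return List of class `normalized_counts`: `values` (log2 matrix over
#'   endogenous + housekeeping probes), `detected` (logical matrix, same
#'   rows), `probe_class` for those rows, and `report` (per-lane
#'   data frame: lane, lambda, factor, hk_offset, hk_applied).
#' @export
normalize_counts <- function(raw, tau = 2,
                             summary = c("arithmetic", "geometric")) {
  stopifnot(inherits(raw, "raw_counts"))
  summary <- match.arg(summary)
  neg <- raw$probe_class == "negative_control"
  pos <- raw$probe_class == "positive_control"
  expr <- raw$probe_class %in% c("endogenous", "housekeeping")

  lambda <- estimate_background(raw$counts[neg, , drop = FALSE])
  detected <- detection_flags(raw)[expr, , drop = FALSE]
  corrected <- background_correct(raw$counts[expr, , drop = FALSE], lambda)
  tech <- technical_normalize(corrected, raw$counts[pos, , drop = FALSE],
                              summary)
  logged <- log2(tech$scaled + 1)
  hk <- housekeeping_correct(logged,
                             raw$probe_class[expr] == "housekeeping", tau)
  lanes <- colnames(raw$counts)
  if (is.null(lanes)) lanes <- as.character(seq_len(ncol(raw$counts)))
  out <- list(
    values = hk$corrected, detected = detected,
    probe_class = raw$probe_class[expr],
    report = data.frame(lane = lanes, lambda = lambda,
                        factor = tech$factors, hk_offset = hk$offsets,
                        hk_applied = hk$applied, row.names = NULL)
  )
  class(out) <- "normalized_counts"
  out
}
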