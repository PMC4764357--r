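# aCGH analysis: baseline adjustment to a genome-wide diploid mean,
# circular binary segmentation of the per-chromosome copy-number series,
# and overlap-weighted per-gene copy number summaries.

#' Adjust two-channel ratios to the diploid baseline
#'
#' Rescales raw probe ratios so that the mean adjusted copy number over
#' all probes of the sample (genome-wide, across chromosomes) equals 2:
#' `CN_i = ratio_i * 2 / mean(ratio)`.
#'
#' @param series `data.frame` (chrom, position, ratio) for one sample;
#'   positions must be strictly increasing within a chromosome and ratios
#'   positive.
#' @return The series with an added `cn` column, class `cn_profile`.
#' @export
adjust_baseline <- function(series) {
  if (nrow(series) < 1) stop("empty probe series")
  if (!all(c("chrom", "position", "ratio") %in% names(series))) {
    stop("probe series needs columns chrom, position, ratio")
  }
  if (any(series$ratio <= 0)) stop("ratios must be positive")
  for (chr in unique(series$chrom)) {
    p <- series$position[series$chrom == chr]
    if (any(diff(p) <= 0)) {
      stop("positions not strictly increasing on ", chr)
    }
  }
  series$cn <- series$ratio * 2 / mean(series$ratio)
  class(series) <- c("cn_profile", "data.frame")
  series
}

#' Circular binary segmentation of one copy-number series
#'
#' Recursively splits the series: each interval is treated as a circle and
#' the arc maximizing the absolute pooled-variance t statistic (arc vs
#' complement) is found by exhaustive scan; the split is accepted when its
#' within-interval permutation p-value is at most `alpha`. Accepted arcs
#' cut the interval into up to three linear pieces that are segmented
#' recursively. Adjacent segments whose means differ by less than
#' `merge_sd` times the within-segment residual SD of the profile are
#' merged post hoc (the "undo" step). Ties in the arc statistic go to the
#' shorter arc, then the lower start index, so results are deterministic
#' given the seed.
#'
#' @param cn Numeric vector of adjusted copy numbers in genomic order
#'   (one chromosome).
#' @param positions Optional probe positions (bp); segment bp spans are
#'   taken at midpoints between flanking probes. Defaults to probe index.
#' @param alpha Permutation significance level for accepting a split.
#' @param n_perm Number of within-interval permutations.
#' @param min_width Minimum probes per segment.
#' @param seed Optional integer seed set before the permutation streams.
#' @param merge_sd Undo threshold in residual-SD units.
#' @return `data.frame` of class `segment_set`: `first`, `last` (probe
#'   indices), `start`, `end` (bp, 0-based half-open), `mean_cn`,
#'   `n_probes`.
#' @export
cbs_segment <- function(cn, positions = NULL, alpha = 0.01, n_perm = 1000,
                        min_width = 2, seed = NULL, merge_sd = 0.5) {
  if (min_width < 1) stop("min_width must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  n <- length(cn)
  if (n < 1) stop("empty profile")
  if (is.null(positions)) positions <- seq_len(n)
  if (length(positions) != n) stop("positions must match profile length")
  if (!is.null(seed)) set.seed(seed)

  boundaries <- integer(0)  # probe index after which a cut falls
  recurse <- function(lo, hi) {
    m <- hi - lo + 1
    if (m < 2 * min_width) return(invisible(NULL))
    seg <- cn[lo:hi]
    scan <- .cbs_scan_cpp(seg, min_width)
    if (scan$i < 0) return(invisible(NULL))
    p <- .cbs_perm_p_cpp(seg, min_width, scan$t, n_perm, alpha)
    if (p > alpha) return(invisible(NULL))
    c1 <- lo - 1 + scan$i   # cut after probe c1 (0 = no left cut)
    c2 <- lo - 1 + scan$j   # cut after probe c2 (n = no right cut)
    if (c1 >= lo) boundaries <<- c(boundaries, c1)
    if (c2 < hi) boundaries <<- c(boundaries, c2)
    pieces_lo <- c(lo, if (c1 >= lo) c1 + 1, if (c2 < hi) c2 + 1)
    pieces_hi <- c(if (c1 >= lo) c1, if (c2 < hi) c2, hi)
    for (k in seq_along(pieces_lo)) recurse(pieces_lo[k], pieces_hi[k])
    invisible(NULL)
  }
  recurse(1, n)

  cuts <- sort(unique(boundaries))
  first <- c(1, cuts + 1)
  last <- c(cuts, n)
  segs <- data.frame(first = first, last = last)
  segs$mean_cn <- vapply(seq_len(nrow(segs)), function(k) {
    mean(cn[segs$first[k]:segs$last[k]])
  }, numeric(1))
  segs <- merge_segments(segs, cn, merge_sd)
  segs$n_probes <- segs$last - segs$first + 1

  b <- segment_bp_bounds(positions)
  segs$start <- b[segs$first]
  segs$end <- b[segs$last + 1]
  segs <- segs[, c("first", "last", "start", "end", "mean_cn", "n_probes")]
  class(segs) <- c("segment_set", "data.frame")
  segs
}

# Midpoint boundaries between probes; outermost bounds extend half the
# median spacing beyond the terminal probes.
segment_bp_bounds <- function(positions) {
  n <- length(positions)
  if (n == 1) {
    return(c(floor(positions - 0.5), ceiling(positions + 0.5)))
  }
  half <- stats::median(diff(positions)) / 2
  c(floor(positions[1] - half),
    floor((positions[-n] + positions[-1]) / 2),
    ceiling(positions[n] + half))
}

# Post-hoc undo: repeatedly merge the adjacent pair with the smallest mean
# difference while that difference is below merge_sd * residual SD. The
# residual SD is estimated from deviations of probes around their segment
# means, so a noiseless piecewise-constant profile never merges.
merge_segments <- function(segs, cn, merge_sd) {
  repeat {
    if (nrow(segs) < 2) break
    fitted <- rep(segs$mean_cn, segs$last - segs$first + 1)
    resid_sd <- stats::sd(cn - fitted)
    if (!is.finite(resid_sd)) resid_sd <- 0
    diffs <- abs(diff(segs$mean_cn))
    k <- which.min(diffs)
    if (diffs[k] >= merge_sd * resid_sd) break
    segs$last[k] <- segs$last[k + 1]
    segs$mean_cn[k] <- mean(cn[segs$first[k]:segs$last[k]])
    segs <- segs[-(k + 1), , drop = FALSE]
    rownames(segs) <- NULL
  }
  segs
}

#' Segment every chromosome of a copy-number profile
#'
#' Runs [cbs_segment()] independently on each chromosome of a
#' baseline-adjusted profile (baseline adjustment itself is global).
#'
#' @param profile A `cn_profile` from [adjust_baseline()].
#' @param chromosomes Chromosomes to segment (default: all in the
#'   profile).
#' @inheritParams cbs_segment
#' @return A `segment_set` with a `chrom` column.
#' @export
segment_profile <- function(profile, chromosomes = NULL, alpha = 0.01,
                            n_perm = 1000, min_width = 2, seed = NULL,
                            merge_sd = 0.5) {
  stopifnot(inherits(profile, "cn_profile"))
  if (is.null(chromosomes)) chromosomes <- unique(profile$chrom)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(chromosomes, function(chr) {
    sel <- profile[profile$chrom == chr, ]
    segs <- cbs_segment(sel$cn, sel$position, alpha = alpha,
                        n_perm = n_perm, min_width = min_width,
                        seed = NULL, merge_sd = merge_sd)
    cbind(chrom = chr, as.data.frame(segs))
  })
  res <- do.call(rbind, out)
  class(res) <- c("segment_set", "data.frame")
  res
}

#' Per-gene inferred copy number from a segmentation
#'
#' Each gene's copy number is the overlap-weighted mean of the means of
#' the segments intersecting `[start, end)`; genes with no overlapping
#' segment are flagged absent (`NA` copy number).
#'
#' @param segments A `segment_set` (with `chrom` column, or assumed to be
#'   on `chrom`).
#' @param catalog Gene catalog; only genomic probes are summarized.
#' @param chrom Chromosome of `segments` when they carry no `chrom`
#'   column.
#' @return `data.frame`: `gene`, `chromosome`, `cn`, `n_probes` (probes in
#'   overlapping segments), `absent`.
#' @export
gene_copy_number <- function(segments, catalog, chrom = "chr8") {
  segs <- as.data.frame(segments)
  if (!"chrom" %in% names(segs)) segs$chrom <- chrom
  genes <- catalog[catalog$probe_class %in% c("endogenous", "housekeeping"), ]
  res <- lapply(seq_len(nrow(genes)), function(g) {
    sel <- segs[segs$chrom == genes$chromosome[g], , drop = FALSE]
    ov <- pmin(sel$end, genes$end[g]) - pmax(sel$start, genes$start[g])
    hit <- which(ov > 0)
    if (length(hit) == 0) {
      return(data.frame(gene = genes$gene[g],
                        chromosome = genes$chromosome[g], cn = NA_real_,
                        n_probes = 0L, absent = TRUE))
    }
    data.frame(gene = genes$gene[g], chromosome = genes$chromosome[g],
               cn = sum(ov[hit] * sel$mean_cn[hit]) / sum(ov[hit]),
               n_probes = as.integer(sum(sel$n_probes[hit])),
               absent = FALSE)
  })
  do.call(rbind, res)
}
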