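# Heatmap matrix export: per-gene 5th-95th percentile clipping rescaled to
# [0, 1] (the red/green display convention), with not-detected entries kept
# as missing ("grey"), never as zero.

#' Build a clipped, rescaled heatmap matrix
#'
#' Rows are genes in genomic order; per gene, detected values are clipped
#' to the gene's `[p_low, p_high]` percentiles (computed over detected
#' entries only) and rescaled linearly to `[0, 1]`. Not-detected entries
#' become `NA`. A gene whose detected values are constant maps to 0.5;
#' genes with fewer than 2 detected values are emitted all-missing.
#'
#' @param values Genes x samples matrix of normalized log2 values.
#' @param detected Logical matrix of the same shape.
#' @param catalog Gene catalog providing genomic order.
#' @param order_by Column ordering: `"sample"` (by id), `"amplified"`
#'   (non-amplified first), or `"gcn"` (increasing copy number).
#' @param amplified Logical per-sample labels (for `order_by =
#'   "amplified"`).
#' @param gcn Per-sample copy numbers (for `order_by = "gcn"`).
#' @param percentiles Clip window, default `c(5, 95)` (percent).
#' @return Matrix in `[0, 1]` with `NA` for missing, genes ordered by
#'   (chromosome, start), columns reordered per `order_by`.
#' @export
heatmap_matrix <- function(values, detected, catalog,
                           order_by = c("sample", "amplified", "gcn"),
                           amplified = NULL, gcn = NULL,
                           percentiles = c(5, 95)) {
  order_by <- match.arg(order_by)
  if (percentiles[1] < 0 || percentiles[2] > 100 ||
      percentiles[1] >= percentiles[2]) {
    stop("percentiles must satisfy 0 <= low < high <= 100")
  }
  values <- as.matrix(values); detected <- as.matrix(detected)
  genes <- intersect(catalog$gene, rownames(values))
  cat_sub <- catalog[match(genes, catalog$gene), ]
  ord <- order(cat_sub$chromosome, cat_sub$start)
  genes <- genes[ord]
  values <- values[genes, , drop = FALSE]
  detected <- detected[genes, , drop = FALSE]

  out <- matrix(NA_real_, nrow(values), ncol(values),
                dimnames = dimnames(values))
  for (g in seq_len(nrow(values))) {
    det <- detected[g, ]
    if (sum(det) < 2) next
    v <- values[g, det]
    qs <- stats::quantile(v, probs = percentiles / 100, names = FALSE)
    if (qs[2] - qs[1] <= 0) {
      out[g, det] <- 0.5
    } else {
      out[g, det] <- pmin(pmax((values[g, det] - qs[1]) /
                                 (qs[2] - qs[1]), 0), 1)
    }
  }

  cols <- switch(order_by,
    sample = order(colnames(values)),
    amplified = {
      if (is.null(amplified)) stop("order_by='amplified' needs labels")
      order(amplified, colnames(values))
    },
    gcn = {
      if (is.null(gcn)) stop("order_by='gcn' needs per-sample copy numbers")
      order(gcn)
    })
  out[, cols, drop = FALSE]
}
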