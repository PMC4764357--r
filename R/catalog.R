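#' Build the default gene/probe catalog
#'
#' The catalog describes every probe in the codeset: the 21 chromosome
#' 8p11-12 amplicon genes around \emph{FGFR1} (approximate, order-correct
#' coordinates on a 36-42 Mb window of chr8), a background set of endogenous
#' genes on other chromosomes, housekeeping genes, 6 positive-control and 8
#' negative-control probes. Control probes carry no genomic coordinates;
#' positive controls carry a spike-in `nominal_level` (fM).
#'
#' Gene order, not exact base-pair accuracy, drives all downstream logic
#' (per-gene copy number lookup, heatmap row order).
#'
#' @param overrides Optional data frame replacing the default catalog. Must
#'   have columns `gene`, `chromosome`, `start`, `end`, `probe_class`,
#'   `nominal_level` and satisfy the catalog invariants (see
#'   [validate_catalog()]).
#' @param n_filler Number of additional synthetic background endogenous genes
#'   (named `FILLER001`, ...) appended to the default catalog, spread over
#'   non-chr8 chromosomes. Useful to emulate larger codesets (the platform
#'   validation used 194 genes).
#' @return A `data.frame` with one row per probe, class `amp_catalog`.
#' @examples
#' cat8p <- make_gene_catalog()
#' subset(cat8p, probe_class == "negative_control")
#' @export
make_gene_catalog <- function(overrides = NULL, n_filler = 0) {
  if (!is.null(overrides)) {
    return(validate_catalog(as.data.frame(overrides)))
  }
  amplicon <- data.frame(
    gene = c("ZNF703", "ERLIN2", "PROSC", "GPR124", "BRF2", "RAB11FIP1",
             "GOT1L1", "ADRB3", "EIF4EBP1", "ASH2L", "LSM1", "BAG4",
             "DDHD2", "PPAPDC1B", "WHSC1L1", "LETM2", "FGFR1", "TACC1",
             "PLEKHA2", "ADAM9", "ADAM32"),
    chromosome = "chr8",
    start = c(37550000, 37585000, 37615000, 37640000, 37700000, 37715000,
              37790000, 37820000, 37885000, 37960000, 38000000, 38025000,
              38080000, 38126000, 38140000, 38240000, 38270000, 38580000,
              38740000, 38850000, 38960000),
    end = c(37560000, 37610000, 37635000, 37685000, 37710000, 37755000,
            37800000, 37825000, 37915000, 37995000, 38015000, 38060000,
            38125000, 38135000, 38235000, 38265000, 38330000, 38710000,
            38800000, 38910000, 39080000),
    probe_class = "endogenous",
    nominal_level = NA_real_
  )
  background <- data.frame(
    gene = c("FGFR2", "FGFR3", "FGFR4", "FGF2", "FOS", "ARTN", "EGR1",
             "ZEB1", "EGFR", "MET", "KRAS", "MYC", "CCND1", "PIK3CA",
             "PTEN", "SOX2", "TP63", "KEAP1", "DDR2", "IGF1R"),
    chromosome = c("chr10", "chr4", "chr5", "chr4", "chr14", "chr1", "chr5",
                   "chr10", "chr7", "chr7", "chr12", "chr8", "chr11", "chr3",
                   "chr10", "chr3", "chr3", "chr19", "chr1", "chr15"),
    start = c(123200000, 1795000, 176500000, 123700000, 75740000, 44400000,
              137800000, 31600000, 55000000, 116310000, 25360000, 128750000,
              69450000, 178900000, 89620000, 181430000, 189350000, 10600000,
              162600000, 99190000),
    end = c(123350000, 1810000, 176520000, 123770000, 75750000, 44410000,
            137810000, 31800000, 55200000, 116440000, 25400000, 128755000,
            69460000, 178950000, 89730000, 181432000, 189600000, 10615000,
            162730000, 99510000),
    probe_class = "endogenous",
    nominal_level = NA_real_
  )
  housekeeping <- data.frame(
    gene = c("ACTB", "PGK1", "GAPDH", "GUSB"),
    chromosome = c("chr7", "chrX", "chr12", "chr7"),
    start = c(5566000, 77320000, 6643000, 65425000),
    end = c(5570000, 77385000, 6648000, 65447000),
    probe_class = "housekeeping",
    nominal_level = NA_real_
  )
  positives <- data.frame(
    gene = paste0("POS_", LETTERS[1:6]),
    chromosome = NA_character_, start = NA_real_, end = NA_real_,
    probe_class = "positive_control",
    nominal_level = c(128, 32, 8, 2, 0.5, 0.125)
  )
  negatives <- data.frame(
    gene = paste0("NEG_", LETTERS[1:8]),
    chromosome = NA_character_, start = NA_real_, end = NA_real_,
    probe_class = "negative_control",
    nominal_level = NA_real_
  )
  catalog <- rbind(amplicon, background, housekeeping, positives, negatives)
  if (n_filler > 0) {
    chroms <- paste0("chr", c(1:7, 9:22))
    filler <- data.frame(
      gene = sprintf("FILLER%03d", seq_len(n_filler)),
      chromosome = rep_len(chroms, n_filler),
      start = 10e6 + 2e5 * seq_len(n_filler),
      end = 10e6 + 2e5 * seq_len(n_filler) + 1e5,
      probe_class = "endogenous",
      nominal_level = NA_real_
    )
    catalog <- rbind(catalog, filler)
  }
  validate_catalog(catalog)
}

#' Validate a gene/probe catalog
#'
#' Checks the catalog invariants: required columns, `start < end` for genomic
#' probes, no genomic coordinates on control probes, no overlapping genes
#' within a chromosome, exactly 8 negative-control and 6 positive-control
#' probes, positive `nominal_level` on positive controls, and at least one
#' housekeeping probe.
#'
#' @param catalog A catalog data frame.
#' @return The catalog, invisibly classed `amp_catalog`, or an error.
#' @export
validate_catalog <- function(catalog) {
  required <- c("gene", "chromosome", "start", "end", "probe_class",
                "nominal_level")
  missing <- setdiff(required, names(catalog))
  if (length(missing) > 0) {
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "))
  }
  classes <- c("endogenous", "housekeeping", "positive_control",
               "negative_control")
  if (!all(catalog$probe_class %in% classes)) {
    stop("unknown probe_class: ",
         paste(setdiff(catalog$probe_class, classes), collapse = ", "))
  }
  if (anyDuplicated(catalog$gene)) {
    stop("duplicated gene symbols in catalog")
  }
  genomic <- catalog$probe_class %in% c("endogenous", "housekeeping")
  g <- catalog[genomic, ]
  if (any(is.na(g$start) | is.na(g$end))) {
    stop("genomic probes must have start/end coordinates")
  }
  if (any(g$start >= g$end)) {
    bad <- g$gene[g$start >= g$end]
    stop("gene(s) with start >= end: ", paste(bad, collapse = ", "))
  }
  for (chr in unique(g$chromosome)) {
    gc <- g[g$chromosome == chr, ]
    gc <- gc[order(gc$start), ]
    if (nrow(gc) > 1 && any(gc$start[-1] < gc$end[-nrow(gc)])) {
      i <- which(gc$start[-1] < gc$end[-nrow(gc)])[1]
      stop("overlapping genes on ", chr, ": ", gc$gene[i], " and ",
           gc$gene[i + 1])
    }
  }
  ctrl <- catalog[!genomic, ]
  if (any(!is.na(ctrl$start) | !is.na(ctrl$end))) {
    stop("control probes must not carry genomic coordinates")
  }
  n_neg <- sum(catalog$probe_class == "negative_control")
  n_pos <- sum(catalog$probe_class == "positive_control")
  if (n_neg != 8) stop("catalog must contain exactly 8 negative-control probes, found ", n_neg)
  if (n_pos != 6) stop("catalog must contain exactly 6 positive-control probes, found ", n_pos)
  pos <- catalog[catalog$probe_class == "positive_control", ]
  if (any(is.na(pos$nominal_level) | pos$nominal_level <= 0)) {
    stop("positive controls require a positive nominal_level")
  }
  if (sum(catalog$probe_class == "housekeeping") < 1) {
    stop("catalog needs at least one housekeeping probe")
  }
  class(catalog) <- c("amp_catalog", "data.frame")
  catalog
}
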