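# Plain-text TSV dialects for every table the pipeline exchanges: counts,
# Ct, FISH (per nucleus and per-sample scores), aCGH ratios, catalog,
# segments (BED-like, 0-based half-open) and ground truth. Readers
# validate schema and invariants and name the first offending line.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(path, ": missing column(s): ", paste(missing, collapse = ", "))
  }
}

#' Write / read a raw count matrix TSV
#'
#' Layout: columns `probe`, `class`, `nominal_level`, then one column per
#' lane.
#'
#' @param raw A [raw_count_matrix()].
#' @param path Output/input file path.
#' @return `write_counts_tsv`: the path, invisibly. `read_counts_tsv`: a
#'   `raw_counts` object.
#' @export
write_counts_tsv <- function(raw, path) {
  stopifnot(inherits(raw, "raw_counts"))
  df <- data.frame(probe = rownames(raw$counts), class = raw$probe_class,
                   nominal_level = raw$nominal_level,
                   raw$counts, check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("probe", "class", "nominal_level"), path)
  lanes <- setdiff(names(df), c("probe", "class", "nominal_level"))
  if (length(lanes) == 0) stop(path, ": no lane columns")
  counts <- as.matrix(df[, lanes, drop = FALSE])
  if (!is.numeric(counts)) stop(path, ": non-numeric count values")
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(path, ": negative count at line ", bad[1, 1] + 1, " (probe ",
         df$probe[bad[1, 1]], ", lane ", lanes[bad[1, 2]], ")")
  }
  rownames(counts) <- df$probe
  raw_count_matrix(counts, df$class, df$nominal_level)
}

#' Write / read a qPCR Ct TSV (sample, assay, replicate, ct)
#'
#' @param ct A `ct_table`.
#' @param path File path.
#' @return The path / a `ct_table` with the calibrator attribute restored.
#' @export
write_ct_tsv <- function(ct, path) {
  write_tsv(as.data.frame(ct)[, c("sample", "assay", "replicate", "ct")],
            path)
  invisible(path)
}

#' @rdname write_ct_tsv
#' @export
read_ct_tsv <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("sample", "assay", "replicate", "ct"), path)
  bad <- which(!is.finite(df$ct) | df$ct <= 0)
  if (length(bad) > 0) {
    stop(path, ": non-positive Ct at line ", bad[1] + 1)
  }
  if ("CALIBRATOR" %in% df$sample) attr(df, "calibrator") <- "CALIBRATOR"
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Write / read a per-nucleus FISH TSV
#'
#' Columns: sample, nucleus, fgfr1_spots, cen8_spots, cluster (0/1).
#'
#' @param fish A `fish_table`.
#' @param path File path.
#' @return The path / a `fish_table`.
#' @export
write_fish_tsv <- function(fish, path) {
  df <- as.data.frame(fish)
  df$cluster <- as.integer(df$cluster)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_fish_tsv
#' @export
read_fish_tsv <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("sample", "nucleus", "fgfr1_spots", "cen8_spots",
                        "cluster"), path)
  for (col in c("fgfr1_spots", "cen8_spots")) {
    bad <- which(df[[col]] < 0 | df[[col]] != round(df[[col]]))
    if (length(bad) > 0) {
      stop(path, ": invalid ", col, " at line ", bad[1] + 1)
    }
  }
  df$cluster <- as.logical(df$cluster)
  class(df) <- c("fish_table", "data.frame")
  df
}

#' Read a per-sample FISH score TSV
#'
#' Columns: sample, fgfr1_total, cen8_total, n_cluster, n_nuclei. The
#' packaged synthetic scoring table
#' (`system.file("extdata", "fish_scores_s1_synthetic.tsv", package =
#' "amplicon8p")`) uses this layout.
#'
#' @param path File path.
#' @return A `data.frame` of per-sample scores.
#' @export
read_fish_scores_tsv <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("sample", "fgfr1_total", "cen8_total", "n_cluster",
                        "n_nuclei"), path)
  bad <- which(df$cen8_total <= 0)
  if (length(bad) > 0) {
    stop(path, ": zero CEN-8 total at line ", bad[1] + 1)
  }
  df
}

#' Write / read an aCGH probe TSV (sample, chrom, position, ratio)
#'
#' @param acgh An `acgh_table`.
#' @param path File path.
#' @return The path / an `acgh_table`.
#' @export
write_acgh_tsv <- function(acgh, path) {
  write_tsv(as.data.frame(acgh), path)
  invisible(path)
}

#' @rdname write_acgh_tsv
#' @export
read_acgh_tsv <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("sample", "chrom", "position", "ratio"), path)
  bad <- which(!is.finite(df$ratio) | df$ratio <= 0)
  if (length(bad) > 0) {
    stop(path, ": non-positive ratio at line ", bad[1] + 1)
  }
  class(df) <- c("acgh_table", "data.frame")
  df
}

#' Write a segment set as BED-like TSV (0-based half-open)
#'
#' @param segments A `segment_set` (with or without a `chrom` column).
#' @param path File path.
#' @param chrom Chromosome used when `segments` has no `chrom` column.
#' @return The path, invisibly.
#' @export
write_segments_tsv <- function(segments, path, chrom = "chr8") {
  df <- as.data.frame(segments)
  if (!"chrom" %in% names(df)) df$chrom <- chrom
  write_tsv(df[, c("chrom", "start", "end", "mean_cn", "n_probes")], path)
  invisible(path)
}

#' Write the simulator's ground truth as TSV
#'
#' @param truth An `amp_truth`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  fmid <- (FGFR1_START + FGFR1_END) / 2
  df <- truth$samples
  df$fgfr1_cn <- vapply(df$sample, function(s) {
    arch_cn(truth$architectures[[s]], fmid)
  }, numeric(1))
  write_tsv(df, path)
  invisible(path)
}

#' Write / read a gene catalog TSV
#'
#' @param catalog An `amp_catalog`.
#' @param path File path.
#' @return The path / a validated catalog.
#' @export
write_catalog_tsv <- function(catalog, path) {
  write_tsv(as.data.frame(catalog), path)
  invisible(path)
}

#' @rdname write_catalog_tsv
#' @export
read_catalog_tsv <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("gene", "chromosome", "start", "end", "probe_class",
                        "nominal_level"), path)
  validate_catalog(df)
}
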