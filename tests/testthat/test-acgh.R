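chr8_series <- function(ratio, spacing = 10000) {
  data.frame(chrom = "chr8",
             position = 36e6 + spacing * (seq_along(ratio) - 1),
             ratio = ratio)
}

test_that("baseline adjustment rescales to a genome-wide mean of two", {
  prof <- adjust_baseline(chr8_series(rep(1.3, 10)))
  expect_equal(prof$cn, rep(2, 10))

  prof2 <- adjust_baseline(chr8_series(c(1, 1, 1, 3)))
  expect_equal(prof2$cn, c(4 / 3, 4 / 3, 4 / 3, 4))
  expect_equal(mean(prof2$cn), 2, tolerance = 1e-12)

  set.seed(30)
  for (rep in 1:10) {
    prof3 <- adjust_baseline(chr8_series(rlnorm(200, 0, 0.4)))
    expect_lt(abs(mean(prof3$cn) - 2), 1e-9)
  }
  empty <- data.frame(chrom = character(0), position = numeric(0),
                      ratio = numeric(0))
  expect_error(adjust_baseline(empty), "empty")
  expect_error(adjust_baseline(chr8_series(c(1, -1))), "positive")
})

test_that("CBS leaves a constant profile unsegmented", {
  segs <- cbs_segment(rep(2, 120), seed = 1, n_perm = 200)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$mean_cn, 2)
  expect_equal(segs$n_probes, 120)
})

test_that("CBS finds a noiseless step exactly", {
  x <- c(rep(2, 200), rep(6, 100))
  segs <- cbs_segment(x, seed = 2, n_perm = 200)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$last[1], 200)
  expect_equal(segs$mean_cn, c(2, 6))
})

test_that("first CBS split equals the exhaustive circular-arc argmax", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(10:50, 1)
    x <- rnorm(n, 2, 0.3)
    if (rep %% 2 == 0) {   # add a real step half the time
      a <- sample(2:(n - 4), 1)
      b <- sample((a + 2):(n - 1), 1)
      x[a:b] <- x[a:b] + runif(1, 1, 4)
    }
    got <- .cbs_scan_cpp(x, 2L)
    want <- oracle_best_arc(x, 2)
    expect_equal(got$i, want$i)
    expect_equal(got$j, want$j)
    expect_equal(got$t, want$t, tolerance = 1e-9)
  }
})

test_that("segmentations partition the probes and conserve the mean", {
  set.seed(12)
  x <- c(rnorm(150, 2, 0.2), rnorm(60, 5, 0.2), rnorm(90, 2, 0.2))
  segs <- cbs_segment(x, seed = 5, n_perm = 300)
  expect_equal(segs$first[1], 1)
  expect_equal(segs$last[nrow(segs)], length(x))
  if (nrow(segs) > 1) {
    expect_equal(segs$first[-1], segs$last[-nrow(segs)] + 1)
  }
  # probe-weighted mean of segment means = profile mean
  expect_equal(sum(segs$mean_cn * segs$n_probes) / length(x), mean(x))
  # segment means recompute from their probes
  for (k in seq_len(nrow(segs))) {
    expect_equal(segs$mean_cn[k], mean(x[segs$first[k]:segs$last[k]]))
  }
})

test_that("CBS is deterministic given a seed and validates inputs", {
  set.seed(3)
  x <- c(rnorm(80, 2, 0.3), rnorm(40, 4, 0.3))
  a <- cbs_segment(x, seed = 9, n_perm = 300)
  b <- cbs_segment(x, seed = 9, n_perm = 300)
  expect_identical(a, b)
  expect_error(cbs_segment(x, alpha = 0), "alpha")
  expect_error(cbs_segment(x, min_width = 0), "min_width")
})

test_that("per-gene copy number is the overlap-weighted segment mean", {
  cat8p <- make_gene_catalog()
  # one segment covering FGFR1 at the published-style plateau value
  segs <- data.frame(chrom = "chr8", start = 37e6, end = 39.5e6,
                     mean_cn = 4.58, n_probes = 100)
  gcn <- gene_copy_number(segs, cat8p)
  expect_equal(gcn$cn[gcn$gene == "FGFR1"], 4.58)

  # gene straddling two equal-length overlaps of means 2 and 6 -> 4
  cat2 <- cat8p
  cat2$start[cat2$gene == "FGFR1"] <- 38.0e6
  cat2$end[cat2$gene == "FGFR1"] <- 38.2e6
  cat2 <- make_gene_catalog(overrides = cat2[cat2$gene %in%
    c("FGFR1", "ACTB", "PGK1", paste0("POS_", LETTERS[1:6]),
      paste0("NEG_", LETTERS[1:8])), ])
  segs2 <- data.frame(chrom = "chr8", start = c(37e6, 38.1e6),
                      end = c(38.1e6, 39e6), mean_cn = c(2, 6),
                      n_probes = c(10, 10))
  gcn2 <- gene_copy_number(segs2, cat2)
  expect_equal(gcn2$cn[gcn2$gene == "FGFR1"], 4)

  # absent genes flagged
  expect_true(gcn$absent[gcn$gene == "FGFR2"])
  expect_true(is.na(gcn$cn[gcn$gene == "FGFR2"]))
})

test_that("gene copy number matches a per-bp averaging oracle", {
  set.seed(41)
  for (rep in 1:10) {
    cuts <- sort(sample(seq(100, 900, by = 10), 4))
    segs <- data.frame(chrom = "chr8",
                       start = c(0, cuts), end = c(cuts, 1000),
                       mean_cn = round(runif(5, 1, 8), 2),
                       n_probes = 10)
    g_start <- sample(50:700, 1)
    g_end <- g_start + sample(c(40, 120, 350), 1)
    cat_min <- make_gene_catalog()
    cat_min$start[cat_min$gene == "FGFR1"] <- g_start
    cat_min$end[cat_min$gene == "FGFR1"] <- g_end
    gcn <- gene_copy_number(segs, cat_min)
    expect_equal(gcn$cn[gcn$gene == "FGFR1"],
                 oracle_gene_cn(segs, g_start, g_end), tolerance = 1e-9)
  }
})

test_that("CBS recovers a plateau-plus-focal-peak architecture", {
  cfg <- sim_config(n_samples = 2, seed = 21, sigma_a = 0.1,
                    acgh_scale = 1.1, backbone_probes = 60000)
  truth <- make_test_truth(c(2, 7), cfg)
  # add a focal peak at 12.5 on the plateau, offset telomeric of FGFR1
  truth$architectures[["S02"]] <- data.frame(
    start = c(36e6, 37.5e6, 37.7e6, 38.0e6, 39.5e6),
    end = c(37.5e6, 37.7e6, 38.0e6, 39.5e6, 42e6),
    cn = c(2, 7, 12.5, 7, 2))
  prof <- adjust_baseline(simulate_acgh(truth, samples = "S02"))
  segs <- segment_profile(prof, chromosomes = "chr8", seed = 31)
  gcn <- gene_copy_number(segs, truth$catalog)
  expect_lt(abs(gcn$cn[gcn$gene == "FGFR1"] - 7), 0.3)
  # the ERLIN2/PROSC focal peak is recovered as a separate high segment
  expect_lt(abs(max(segs$mean_cn) - 12.5), 0.75)
  # breakpoints within 3 probes (18 kb) of the truth
  bp_true <- c(37.5e6, 37.7e6, 38.0e6, 39.5e6)
  bp_got <- segs$start[-1]
  for (b in bp_true) {
    expect_lte(min(abs(bp_got - b)), 3 * cfg$acgh_spacing)
  }
})
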