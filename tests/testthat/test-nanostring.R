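test_that("background estimate is the negative-control mean", {
  expect_equal(estimate_background(c(4, 6, 5, 5, 5, 5, 5, 5)), 5)
  expect_equal(estimate_background(rep(0, 8)), 0)
  expect_error(estimate_background(numeric(0)), "no negative-control")
  set.seed(1)
  expect_equal(estimate_background(rpois(1e5, 7)), 7, tolerance = 0.015)
})

test_that("detection flags implement the mean + 2 SD rule on raw counts", {
  counts <- rbind(G1 = c(9, 10), G2 = c(10, 16),
                  HK1 = c(100, 100),
                  matrix(rep(c(2000, 500, 125, 30, 8, 2), 2), 6, 2,
                         dimnames = list(paste0("POS_", LETTERS[1:6]), NULL)),
                  matrix(10, 8, 2, dimnames = list(paste0("NEG_", 1:8), NULL)))
  raw <- raw_count_matrix(counts,
                          c("endogenous", "endogenous", "housekeeping",
                            rep("positive_control", 6),
                            rep("negative_control", 8)))
  det <- detection_flags(raw)
  # negatives all 10 (sd 0): threshold 10; 9 not detected, 10 detected
  expect_false(det["G1", 1])
  expect_true(det["G2", 1])
  expect_true(det["G1", 2])

  # negatives (8, 12): sample SD 2.828..., threshold 15.657
  counts2 <- rbind(G1 = c(15, 16), HK1 = c(100, 100),
                   POS_A = c(2000, 2000),
                   NEGa = c(8, 8), NEGb = c(12, 12))
  raw2 <- raw_count_matrix(counts2,
                           c("endogenous", "housekeeping",
                             "positive_control",
                             rep("negative_control", 2)))
  det2 <- detection_flags(raw2)
  expect_false(det2["G1", 1])   # 15 < 15.657
  expect_true(det2["G1", 2])    # 16 >= 15.657
  # an extreme count is always detected
  counts2["G1", 1] <- 1e6
  raw3 <- raw_count_matrix(counts2, raw2$probe_class)
  expect_true(detection_flags(raw3)["G1", 1])
})

test_that("detection flags match a brute-force recomputation", {
  for (seed in 1:5) {
    raw <- make_test_raw(n_lanes = 4, seed = seed)
    det <- detection_flags(raw)
    neg <- raw$counts[raw$probe_class == "negative_control", ]
    for (j in 1:4) {
      thr <- mean(neg[, j]) + 2 * sd(neg[, j])
      expect_equal(unname(det[, j]), unname(raw$counts[, j] >= thr))
    }
  }
  expect_error(
    detection_flags(raw_count_matrix(
      matrix(1, 4, 2), c("endogenous", "housekeeping", "positive_control",
                         "negative_control"))),
    "at least 2 negative")
})

test_that("background correction subtracts then truncates at zero", {
  m <- matrix(c(0, 1000, 3, 7), 2, 2)
  expect_equal(background_correct(m, 5), matrix(c(0, 995, 0, 2), 2, 2))
  expect_equal(background_correct(m, 0), m)
  expect_error(background_correct(m, -1), ">= 0")
})

test_that("technical factors rescale lanes to the cohort positive mean", {
  pos <- cbind(rep(100, 6), rep(200, 6))
  res <- technical_normalize(matrix(1, 2, 2), pos)
  expect_equal(res$factors, c(1.5, 0.75))
  expect_equal(technical_normalize(matrix(1, 2, 3),
                                   matrix(50, 6, 3))$factors, rep(1, 3))
  expect_equal(technical_normalize(matrix(1, 2, 1),
                                   matrix(7, 6, 1))$factors, 1)
  expect_error(technical_normalize(matrix(1, 2, 2),
                                   cbind(rep(0, 6), rep(10, 6))),
               "zero positive-control mean")
})

test_that("housekeeping correction shrinks offsets through tanh", {
  m <- matrix(8, 4, 3)
  res <- housekeeping_correct(m, hk_rows = c(3, 4), tau = 2)
  expect_equal(res$applied, rep(0, 3))
  expect_equal(res$corrected, m)

  m2 <- cbind(rep(8, 4), rep(8.1, 4))
  res2 <- housekeeping_correct(m2, hk_rows = c(3, 4), tau = 2)
  expect_equal(res2$offsets, c(-0.05, 0.05))
  expect_equal(res2$applied, 2 * tanh(c(-0.025, 0.025)))

  m3 <- cbind(rep(8, 4), rep(58, 4))
  res3 <- housekeeping_correct(m3, hk_rows = c(3, 4), tau = 2)
  expect_true(all(abs(res3$applied) < 2))
  expect_true(all(abs(res3$applied) <= abs(res3$offsets)))
})

test_that("identical lanes normalize identically", {
  raw <- make_test_raw(n_lanes = 1, seed = 3)
  counts <- raw$counts[, c(1, 1, 1)]
  colnames(counts) <- paste0("L", 1:3)
  raw3 <- raw_count_matrix(counts, raw$probe_class, raw$nominal_level)
  norm <- normalize_counts(raw3)
  expect_equal(norm$values[, 1], norm$values[, 2])
  expect_equal(norm$values[, 2], norm$values[, 3])
  expect_equal(norm$report$factor, rep(1, 3))
})

test_that("scaling one lane x4 is cancelled to within 0.05 log2 units", {
  # noise-free lanes so the invariance is attributable to the chain itself;
  # at cohort scale (90 lanes) the positive-control anchor moves by only
  # log2(1 + 3/90) = 0.047 when one lane quadruples
  cfg <- sim_config(n_samples = 90, seed = 4, dispersion = 0,
                    expr_noise_sd = 0, lambda_bg = 5)
  truth <- make_test_truth(rep(c(2, 6), 45), cfg)
  raw <- simulate_nanostring(truth)
  base <- normalize_counts(raw)
  scaled <- raw
  scaled$counts[, 3] <- scaled$counts[, 3] * 4
  norm4 <- normalize_counts(scaled)
  endo <- base$probe_class == "endogenous"
  expect_lt(max(abs(norm4$values[endo, 3] - base$values[endo, 3])), 0.05)
})

test_that("normalized values are monotone in raw counts within a lane", {
  raw <- make_test_raw(n_lanes = 3, seed = 8)
  norm <- normalize_counts(raw)
  bumped <- raw
  bumped$counts["G1", 2] <- bumped$counts["G1", 2] + 50
  norm2 <- normalize_counts(bumped)
  expect_gt(norm2$values["G1", 2], norm$values["G1", 2])
})

test_that("an all-zero probe floors at log2(1) before lane corrections", {
  raw <- make_test_raw(n_lanes = 2, seed = 2)
  raw$counts["G1", ] <- 0
  norm <- normalize_counts(raw)
  expect_equal(unname(norm$values["G1", ]),
               unname(0 - norm$report$hk_applied))
  expect_true(all(!norm$detected["G1", ]))
})

test_that("full normalization report is reproducible from raw counts", {
  raw <- make_test_raw(n_lanes = 4, seed = 6)
  norm <- normalize_counts(raw)
  neg <- raw$counts[raw$probe_class == "negative_control", ]
  expect_equal(norm$report$lambda, unname(colMeans(neg)))
  pos <- raw$counts[raw$probe_class == "positive_control", ]
  expect_equal(norm$report$factor,
               unname(mean(colMeans(pos)) / colMeans(pos)))
})
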