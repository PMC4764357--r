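test_that("pooled t-test matches the textbook formula and t.test oracle", {
  vals <- rbind(G1 = c(0, 0, 1, 1, 2, 2, 3, 3),
                G2 = c(1, 2, 3, 0, 1, 2, 3, 0))
  amplified <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  res <- ttest_per_gene(vals, amplified)
  # hand computation for G1: means 0.5 vs 2.5, pooled var 1/3,
  # se = sqrt(1/3 * (1/4 + 1/4)) -> t = -2 / sqrt(1/6) = -sqrt(24)
  expect_equal(res$t[1], -sqrt(24))
  expect_equal(res$df[1], 6)
  or <- t.test(vals["G1", amplified], vals["G1", !amplified],
               var.equal = TRUE)
  expect_equal(res$t[1], unname(or$statistic))
  expect_equal(res$p[1], or$p.value)
})

test_that("degenerate t-test inputs follow the documented conventions", {
  vals <- rbind(G1 = rep(5, 6), G2 = c(1, 2, 3, 1, 2, 3))
  amplified <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- ttest_per_gene(vals, amplified)
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)
  expect_true(res$zero_variance[1])
  expect_equal(res$t[2], 0)      # identical groups
  expect_equal(res$p[2], 1)
  expect_false(res$zero_variance[2])
  expect_error(ttest_per_gene(vals, c(TRUE, rep(FALSE, 5))),
               "at least 2 samples")
})

test_that("Storey q-values follow the step-down definition", {
  expect_equal(as.numeric(storey_qvalues(1)), 1)
  q <- storey_qvalues(c(0.01, 0.02, 0.9, 0.95), lambda = 0.5)
  expect_equal(attr(q, "pi0"), 1)
  expect_equal(as.numeric(q), c(0.04, 0.04, 0.95, 0.95))
  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Storey with pi0 = 1 reduces to Benjamini-Hochberg", {
  set.seed(91)
  for (rep in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    q <- storey_qvalues(p, pi0 = 1)
    expect_equal(as.numeric(q), p.adjust(p, method = "BH"))
  }
})

test_that("Storey pi0 estimate shrinks q-values under signal", {
  p <- c(rep(1e-4, 30), seq(0.05, 0.95, length.out = 20))
  # 10 of 50 p-values exceed lambda = 0.5 -> pi0 = 10 / 25 = 0.4
  q <- storey_qvalues(p, lambda = 0.5)
  expect_equal(attr(q, "pi0"), 0.4)
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted p
})

test_that("Spearman correlation matches the brute-force rank oracle", {
  det <- matrix(TRUE, 1, 5)
  v <- matrix(c(2, 1, 4, 3, 5), 1, dimnames = list("G1", NULL))
  # ranks are the values themselves; sum d^2 = 4 -> rho = 1 - 24/120 = 0.8
  res <- spearman_cn_expression(v, det, cn = c(1, 2, 3, 4, 5))
  expect_equal(res$rho, 0.8)
  expect_equal(res$rho, oracle_spearman(c(1, 2, 3, 4, 5), v[1, ]))

  set.seed(55)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    cn <- sample(1:6, n, replace = TRUE)   # ties on purpose
    y <- matrix(rnorm(n), 1, dimnames = list("G1", NULL))
    res <- spearman_cn_expression(y, matrix(TRUE, 1, n), cn)
    expect_equal(res$rho, oracle_spearman(cn, y[1, ]), tolerance = 1e-12)
  }
})

test_that("Spearman handles perfect monotone and transformed inputs", {
  n <- 10
  cn <- 1:n
  up <- matrix(2^(seq_len(n)), 1, dimnames = list("G1", NULL))
  det <- matrix(TRUE, 1, n)
  expect_equal(spearman_cn_expression(up, det, cn)$rho, 1)
  expect_equal(spearman_cn_expression(-up, det, cn)$rho, -1)
  # invariance to strictly monotone transforms
  expect_equal(spearman_cn_expression(log2(up), det, cn)$rho, 1)
  expect_equal(spearman_cn_expression(up, det, exp(cn / 3))$rho, 1)
})

test_that("LOD and tie exclusions are applied before correlating", {
  v <- rbind(G1 = rnorm(10), G2 = rnorm(10), G3 = rep(1, 10))
  det <- rbind(c(rep(FALSE, 6), rep(TRUE, 4)),  # 60% not detected
               rep(TRUE, 10), rep(TRUE, 10))
  res <- spearman_cn_expression(v, det, cn = 1:10)
  expect_true(res$excluded[1])
  expect_match(res$reason[1], ">50%")
  expect_false(res$excluded[2])
  expect_true(res$excluded[3])
  expect_match(res$reason[3], "tied")
})

test_that("replicate concordance is the squared Pearson correlation", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(replicate_concordance(a, a), 1)
  expect_equal(replicate_concordance(a, -a), 1)
  expect_error(replicate_concordance(a, rep(1, 5)), "zero variance")
  expect_error(replicate_concordance(a, 1:4), "paired")

  # two low-dispersion re-simulations of one sample concord at r^2 > 0.98
  cfg <- sim_config(n_samples = 2, seed = 33, dispersion = 0.005,
                    expr_noise_sd = 0.5)
  tr <- simulate_cohort(cfg)
  raw <- simulate_nanostring(tr)
  cfg2 <- cfg; cfg2$seed <- 34L
  tr2 <- tr; tr2$config <- cfg2
  raw2 <- simulate_nanostring(tr2)
  endo <- raw$probe_class %in% c("endogenous", "housekeeping")
  r2 <- replicate_concordance(log2(raw$counts[endo, 1] + 1),
                              log2(raw2$counts[endo, 1] + 1))
  expect_gt(r2, 0.98)
})

test_that("cohort summaries split significant genes and count enrichment", {
  res <- data.frame(gene = c("A", "B", "C"),
                    difference = c(2, -1, 0.5),
                    q = c(0.01, 0.02, 0.5))
  vals <- matrix(rnorm(3 * 10), 3, dimnames = list(c("A", "B", "C"), NULL))
  amp <- c(rep(TRUE, 4), rep(FALSE, 6))
  s <- summarize_cohort(res, vals, amp)
  expect_equal(s$significant_up, "A")
  expect_equal(s$significant_down, "B")
  expect_equal(s$n_significant, 2)
  # all q = 1 -> nothing significant
  res$q <- 1
  expect_equal(summarize_cohort(res, vals, amp)$n_significant, 0)
  # above-mean fraction arithmetic
  v2 <- matrix(c(rep(10, 11), rep(0, 2), rep(1, 77)), 1,
               dimnames = list("A", NULL))
  amp2 <- c(rep(TRUE, 13), rep(FALSE, 77))
  s2 <- summarize_cohort(data.frame(gene = "A", difference = 1, q = 0.01),
                         v2, amp2)
  expect_equal(unname(s2$above_mean_fraction["A"]), 11 / 13)
})
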