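# Quantification arithmetic and multiplicity-adjusted comparisons.

test_that("2^-ddCt closed forms", {
  expect_equal(fold_change_ddct(20, 20, 20, 20), 1.0)
  expect_equal(fold_change_ddct(19, 20, 20, 20), 2.0)  # ddCt = -1
  expect_equal(fold_change_ddct(20, 18, 22, 18), 4.0)  # ddCt = -2
  # vectorized over replicates
  expect_equal(fold_change_ddct(c(20, 19), c(20, 20), 20, 20), c(1, 2))
  expect_error(fold_change_ddct(NA, 20, 20, 20), "finite")
})

test_that("swapping sample and control inverts the fold change", {
  set.seed(1)
  cts <- matrix(runif(4 * 20, 15, 30), ncol = 4)
  fwd <- fold_change_ddct(cts[, 1], cts[, 2], cts[, 3], cts[, 4])
  rev <- fold_change_ddct(cts[, 3], cts[, 4], cts[, 1], cts[, 2])
  expect_equal(fwd, 1 / rev, tolerance = 1e-12)
})

test_that("band ratios and control normalization", {
  expect_equal(band_ratio(50, 100), 0.5)
  expect_equal(band_ratio(3 * 50, 3 * 100), 0.5)   # exposure-invariant
  expect_error(band_ratio(10, 0), "> 0")
  ctrl <- c(0.8, 1.0, 1.2)
  expect_equal(mean(normalize_to_control(ctrl, ctrl)), 1.0)
  expect_equal(normalize_to_control(2, ctrl), 2)
})

test_that("identical groups give statistic 0 and p-values 1", {
  g <- list(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4))
  res <- pairwise_compare(g, method = "holm_sidak")
  expect_equal(res$statistic, 0)
  expect_equal(res$raw_p, 1)
  expect_equal(res$adj_p, 1)
})

test_that("single-comparison Holm-Sidak is the identity", {
  p <- 0.0371
  expect_equal(holm_sidak_adjust(p), p)
})

test_that("Holm-Sidak matches the brute-force step-down oracle", {
  set.seed(99)
  for (i in 1:20) {
    p <- runif(4)
    expect_equal(holm_sidak_adjust(p), holm_sidak_oracle(p),
                 tolerance = 1e-12)
  }
  # adjusted values dominate raw and stay in [0, 1], monotone in raw order
  p <- runif(8)
  adj <- holm_sidak_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("pooled t matches t.test and Welch flag switches variants", {
  set.seed(5)
  g <- list(A = rnorm(10), B = rnorm(12, 1, 2))
  pooled <- pairwise_compare(g, method = "none")
  welch <- pairwise_compare(g, method = "none", var_equal = FALSE)
  expect_equal(pooled$raw_p, t.test(g$A, g$B, var.equal = TRUE)$p.value)
  expect_equal(welch$raw_p, t.test(g$A, g$B)$p.value)
  expect_false(isTRUE(all.equal(pooled$raw_p, welch$raw_p)))
})

test_that("Tukey adjusted p-values match TukeyHSD across all pairs", {
  set.seed(42)
  g <- list(A = rnorm(8), B = rnorm(10, 1), C = rnorm(7, 0.5),
            D = rnorm(9))
  res <- pairwise_compare(g, method = "tukey")
  df <- data.frame(v = unlist(g), grp = rep(names(g), lengths(g)))
  tk <- TukeyHSD(stats::aov(v ~ grp, df))$grp
  key <- paste(res$group2, res$group1, sep = "-")
  expect_true(all(key %in% rownames(tk)))
  expect_equal(res$adj_p, unname(tk[key, "p adj"]), tolerance = 1e-8)
  expect_true(all(res$adj_p >= res$raw_p - 1e-12))
})

test_that("undersized groups are skipped with a reason", {
  g <- list(A = rnorm(5), B = 1.2, C = rnorm(5))
  res <- suppressWarnings(pairwise_compare(g, method = "holm_sidak"))
  bad <- res$group1 == "B" | res$group2 == "B"
  expect_true(all(is.na(res$raw_p[bad])))
  expect_true(all(grepl("skipped", res$note[bad])))
  expect_true(all(!is.na(res$adj_p[!bad])))
})

test_that("family-wise type-I error is controlled under the null", {
  # 2000 null simulations, 5 groups of n = 20, the 4 treatment-vs-control
  # comparisons adjusted by Holm-Sidak
  n_sim <- 2000
  set.seed(2024)
  hits <- vapply(seq_len(n_sim), function(i) {
    g <- lapply(1:5, function(j) rnorm(20))
    names(g) <- c("ctrl", "t1", "t2", "t3", "t4")
    res <- pairwise_compare(g, comparisons = list(c("ctrl", "t1"),
                                                  c("ctrl", "t2"),
                                                  c("ctrl", "t3"),
                                                  c("ctrl", "t4")),
                            method = "holm_sidak")
    any(res$adj_p < 0.05)
  }, logical(1))
  fwer <- mean(hits)
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lte(fwer, 0.05 + 3 * se)
})
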