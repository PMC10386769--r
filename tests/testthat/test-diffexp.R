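test_that("log2 fold change is exact, symmetric and antisymmetric", {
  expect_equal(log2_fold_change(c(3, 3), c(1, 1), 1), 1)
  expect_equal(log2_fold_change(c(2, 4), c(2, 4), 1), 0)
  lfc <- log2_fold_change(c(5, 9), c(1, 2), 0.5)
  expect_equal(log2_fold_change(c(1, 2), c(5, 9), 0.5), -lfc)
  expect_error(log2_fold_change(numeric(0), 1), "non-empty")
  expect_error(log2_fold_change(1, 2, pseudocount = 0), "positive")
})

test_that("welch t matches the hand formula and the t.test oracle", {
  r <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4, tolerance = 1e-12)
  expect_equal(r$p_value, 0.02131164, tolerance = 1e-6)

  set.seed(42)
  for (i in 1:40) {
    a <- rnorm(sample(2:8, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:8, 1), mean = runif(1, -2, 2))
    mine <- welch_t_test(a, b)
    ref <- stats::t.test(a, b, var.equal = FALSE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    # positive rescaling of both groups leaves t and p unchanged
    sc <- welch_t_test(3.7 * a, 3.7 * b)
    expect_equal(sc$statistic, mine$statistic, tolerance = 1e-10)
    expect_equal(sc$p_value, mine$p_value, tolerance = 1e-10)
  }
})

test_that("welch degenerate conventions hold", {
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  r <- welch_t_test(c(2, 2), c(2, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_warning(r2 <- welch_t_test(c(2, 2), c(5, 5)), "zero variance")
  expect_equal(r2$p_value, 0)
  expect_error(welch_t_test(1, c(2, 3)), "at least 2")
})

test_that("exact wilcoxon equals full enumeration for small groups", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  set.seed(7)
  for (i in 1:40) {
    n_a <- sample(2:6, 1); n_b <- sample(2:6, 1)
    repeat {  # untied draws
      a <- round(rnorm(n_a, sd = 5), 3)
      b <- round(rnorm(n_b, 1, 5), 3)
      if (!anyDuplicated(c(a, b))) break
    }
    mine <- wilcoxon_rank_sum(a, b)
    expect_true(mine$exact)
    expect_equal(mine$p_value, oracle_wilcoxon_enum(a, b), tolerance = 1e-12)
  }
})

test_that("tied data use the corrected normal approximation", {
  a <- c(1, 1, 2, 3, 5, 5, 6)
  b <- c(2, 2, 3, 4, 5, 7, 7)
  mine <- wilcoxon_rank_sum(a, b)
  expect_false(mine$exact)
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE, exact = FALSE))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  # all values tied: no evidence either way
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2))$p_value, 1)
})

test_that("exact and approximate wilcoxon branches agree at moderate n", {
  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(15); b <- rnorm(15, 0.5)
    p_exact <- wilcoxon_rank_sum(a, b)$p_value
    p_approx <- wilcoxon_rank_sum(a, b, exact_limit = 0L)$p_value
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("benjamini-hochberg reproduces hand-derived q-values", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  # step-up on a worked example: p = (.005, .04, .03), m = 3
  # sorted (.005, .03, .04) -> (.015, .045, .04) -> cummin from top = (.015, .04, .04)
  expect_equal(benjamini_hochberg(c(0.005, 0.04, 0.03)), c(0.015, 0.04, 0.04))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("lowering any single p never raises any BH q", {
  set.seed(3)
  for (i in 1:20) {
    p <- runif(15)
    q <- benjamini_hochberg(p)
    j <- sample(15, 1)
    p2 <- p; p2[j] <- p2[j] * runif(1)
    q2 <- benjamini_hochberg(p2)
    expect_true(all(q2 <= q + 1e-12))
  }
})

de_fixture <- function() {
  set.seed(21)
  vals <- matrix(rlnorm(50 * 8, log(40), 0.25), 50, 8)
  vals[7, 1:4] <- rlnorm(4, log(900), 0.05)   # planted: high in A
  vals[7, 5:8] <- rlnorm(4, log(2), 0.05)
  vals[13, ] <- 0                              # all-zero gene, must be dropped
  m <- make_em(vals, unit = "CPM")
  g <- sample_groups(list(A = sample_ids(m)[1:4], B = sample_ids(m)[5:8]))
  list(m = m, g = g)
}

test_that("a strongly planted gene attains the minimum q and zeros are dropped", {
  f <- de_fixture()
  for (tst in c("welch", "wilcoxon")) {
    de <- run_differential_expression(f$m, f$g, "A", "B", test = tst)
    expect_equal(nrow(de), 49)
    expect_equal(attr(de, "n_dropped"), 1L)
    expect_false("g13" %in% de$gene)
    # the planted gene attains the minimum q (shared under the discrete
    # wilcoxon null, where many genes sit at the exact-p floor)
    expect_equal(de$q_value[de$gene == "g07"], min(de$q_value))
    expect_equal(de$gene[which.max(abs(de$log2_fold_change))], "g07")
    expect_true(de$log2_fold_change[de$gene == "g07"] > 3)
  }
})

test_that("swapping group labels flips effect signs but not p-values", {
  f <- de_fixture()
  ab <- run_differential_expression(f$m, f$g, "A", "B", test = "welch")
  ba <- run_differential_expression(f$m, f$g, "B", "A", test = "welch")
  expect_equal(ba$p_value, ab$p_value, tolerance = 1e-12)
  expect_equal(ba$log2_fold_change, -ab$log2_fold_change, tolerance = 1e-12)
  expect_equal(ba$statistic, -ab$statistic, tolerance = 1e-12)
})

test_that("differential expression guards its preconditions", {
  f <- de_fixture()
  counts <- make_em(matrix(1:16, 4, 4))
  g4 <- sample_groups(list(A = c("s01", "s02"), B = c("s03", "s04")))
  expect_error(run_differential_expression(counts, g4, "A", "B"), "normalized")
  expect_error(run_differential_expression(f$m, f$g, "A", "A"), "differ")
  expect_error(run_differential_expression(f$m, f$g, "A", "Z"), "unknown group")
  g1 <- sample_groups(list(A = "s01", B = c("s02", "s03")))
  m3 <- make_em(matrix(rlnorm(9), 3, 3), unit = "CPM")
  expect_error(run_differential_expression(m3, g1, "A", "B", test = "welch"),
               ">= 2 samples")
})

test_that("log2-unit input uses the difference of group means as fold change", {
  f <- de_fixture()
  lg <- log_transform(f$m)
  de <- run_differential_expression(lg, f$g, "A", "B", test = "welch")
  v <- em_values(lg)[de$gene, , drop = FALSE]
  expect_equal(de$log2_fold_change,
               unname(rowMeans(v[, 1:4]) - rowMeans(v[, 5:8])),
               tolerance = 1e-12)
})
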