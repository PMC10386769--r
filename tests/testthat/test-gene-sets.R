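test_that("ranked lists sort descending with identifier tie-breaks", {
  de <- data.frame(gene = c("gA", "gB", "gC"),
                   log2_fold_change = c(2, -1, 0.5))
  rk <- make_ranked_list(de)
  expect_identical(rk$gene, c("gA", "gC", "gB"))

  de2 <- data.frame(gene = c("gz", "ga"), log2_fold_change = c(1, 1))
  expect_identical(make_ranked_list(de2)$gene, c("ga", "gz"))

  de3 <- data.frame(gene = c("g1", "g2", "g3"),
                    log2_fold_change = c(Inf, 1, NaN))
  rk3 <- make_ranked_list(de3)
  expect_identical(rk3$gene, "g2")
  expect_identical(attr(rk3, "n_dropped"), 2L)
})

test_that("enrichment score hits 1 for the top-ranked singleton set", {
  rk <- ranked_from_stats(c(a = 3, b = 2, c = 1, d = 0.5))
  es <- enrichment_score(rk, "a", weight = 1)
  expect_equal(es$es, 1)
  expect_equal(es$running_sum[1], 1)
  expect_identical(es$leading_edge, "a")
})

test_that("enrichment score equals the brute-force running-sum oracle", {
  set.seed(13)
  for (i in 1:60) {
    n <- sample(8:50, 1)
    k <- sample(1:min(10, n - 1), 1)
    stats <- stats::setNames(round(rnorm(n), 4), sprintf("g%03d", seq_len(n)))
    rk <- ranked_from_stats(stats)
    members <- sample(rk$gene, k)
    w <- sample(c(0, 0.5, 1, 1.5), 1)
    es <- enrichment_score(rk, members, weight = w)$es
    oracle <- oracle_enrichment_score(rk$stat, rk$gene %in% members, w)
    expect_equal(es, oracle, tolerance = 1e-12)
    expect_lte(abs(es), 1 + 1e-12)
  }
})

test_that("negating every statistic mirrors the enrichment score exactly", {
  set.seed(17)
  stats <- stats::setNames(rnorm(40), sprintf("g%03d", 1:40))
  stats <- stats[!duplicated(stats)]
  rk <- ranked_from_stats(stats)
  rk_neg <- ranked_from_stats(-stats)
  members <- sample(names(stats), 8)
  expect_equal(enrichment_score(rk_neg, members)$es,
               -enrichment_score(rk, members)$es, tolerance = 1e-12)
})

test_that("weight zero reduces to the classical unweighted KS statistic", {
  set.seed(19)
  stats <- stats::setNames(sort(rnorm(30), decreasing = TRUE),
                           sprintf("g%03d", 1:30))
  rk <- ranked_from_stats(stats)
  members <- sample(names(stats), 6)
  es0 <- enrichment_score(rk, members, weight = 0)$es
  # classical KS running sum: every hit steps 1/k, every miss 1/(N-k)
  hit <- rk$gene %in% members
  rs <- cumsum(ifelse(hit, 1 / sum(hit), -1 / sum(!hit)))
  ks <- if (max(rs) >= -min(rs)) max(rs) else min(rs)
  expect_equal(es0, ks, tolerance = 1e-12)
})

test_that("enrichment score agrees with the fgsea reference statistic", {
  set.seed(29)
  stats <- stats::setNames(sort(rnorm(100), decreasing = TRUE),
                           sprintf("g%03d", 1:100))
  rk <- ranked_from_stats(stats)
  for (i in 1:10) {
    members <- sample(names(stats), sample(3:20, 1))
    mine <- enrichment_score(rk, members, weight = 1)$es
    ref <- fgsea::calcGseaStat(stats::setNames(rk$stat, rk$gene),
                               selectedStats = which(rk$gene %in% members),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("enrichment score degenerate sets are refused", {
  rk <- ranked_from_stats(c(a = 2, b = 1, c = 0.5))
  expect_error(enrichment_score(rk, "zz"), "no member")
  expect_error(enrichment_score(rk, c("a", "b", "c")), "whole")
})

test_that("preranked GSEA detects a planted top-ranked set", {
  set.seed(47)
  stats <- stats::setNames(sort(rnorm(500), decreasing = TRUE),
                           sprintf("g%04d", 1:500))
  rk <- ranked_from_stats(stats)
  sets <- list(PLANTED = rk$gene[1:20])
  for (j in 1:20) sets[[sprintf("BG%02d", j)]] <- sample(rk$gene, 20)
  res <- preranked_gsea(rk, gene_set_collection(sets),
                        n_permutations = 500, seed = 5)
  planted <- res[res$set == "PLANTED", ]
  expect_lte(planted$p_value, 0.01)
  expect_gt(planted$es, 0.5)
  expect_gt(planted$nes, 1)
})

test_that("GSEA is reproducible and invariant to collection ordering", {
  set.seed(53)
  stats <- stats::setNames(rnorm(200), sprintf("g%03d", 1:200))
  rk <- ranked_from_stats(stats)
  sets <- lapply(1:8, function(j) sample(names(stats), 15))
  names(sets) <- sprintf("S%02d", 1:8)
  coll <- gene_set_collection(sets)
  r1 <- preranked_gsea(rk, coll, n_permutations = 200, seed = 9)
  r2 <- preranked_gsea(rk, coll, n_permutations = 200, seed = 9)
  expect_identical(r1, r2)
  # permute collection order and member order within sets
  sets_perm <- lapply(rev(sets), sample)
  r3 <- preranked_gsea(rk, gene_set_collection(sets_perm),
                       n_permutations = 200, seed = 9)
  expect_equal(r3$p_value[match(r1$set, r3$set)], r1$p_value, tolerance = 1e-12)
  expect_equal(r3$es[match(r1$set, r3$set)], r1$es, tolerance = 1e-12)
})

test_that("GSEA size bounds filter sets and can empty the collection", {
  set.seed(59)
  stats <- stats::setNames(rnorm(100), sprintf("g%03d", 1:100))
  rk <- ranked_from_stats(stats)
  coll <- gene_set_collection(list(BIG = sample(names(stats), 40),
                                   SMALL = sample(names(stats), 3)))
  res <- preranked_gsea(rk, coll, n_permutations = 100, min_size = 5,
                        max_size = 50, seed = 1)
  expect_identical(res$set, "BIG")
  expect_identical(attr(res, "n_skipped_size"), 1L)
  expect_error(preranked_gsea(rk, coll, n_permutations = 100,
                              min_size = 45, max_size = 50, seed = 1),
               "size bounds")
})

test_that("hypergeometric ORA matches the closed form", {
  r <- overrepresentation_test(letters[1:5], letters[1:10], letters[1:5])
  expect_equal(r$p_value, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(r$overlap, 5)
  expect_equal(r$expected, 2.5)

  r0 <- overrepresentation_test(letters[1:3], letters[1:10], letters[8:10])
  expect_equal(r0$overlap, 0)
  expect_equal(r0$p_value, 1)

  rall <- overrepresentation_test(letters[1:10], letters[1:10], letters[3:6])
  expect_equal(rall$overlap, 4)
  expect_equal(rall$p_value, 1)

  expect_error(overrepresentation_test(character(0), letters, letters[1:3]),
               "non-empty")
  expect_error(overrepresentation_test(c("a", "zz"), letters[1:5], "a"),
               "outside")
})

test_that("ORA equals choose()-enumeration across small universes", {
  for (n_u in c(6, 11, 17, 23, 30)) {
    universe <- sprintf("u%02d", seq_len(n_u))
    set.seed(n_u)
    for (i in 1:20) {
      set_g <- sample(universe, sample(n_u, 1))
      query <- sample(universe, sample(n_u, 1))
      r <- overrepresentation_test(query, universe, set_g)
      expect_equal(r$p_value,
                   oracle_hypergeom_upper(r$overlap, length(set_g), n_u,
                                          length(query)),
                   tolerance = 1e-12)
    }
  }
})

test_that("set-level comparison detects planted shifts and respects ties", {
  set.seed(61)
  vals <- matrix(rlnorm(200 * 10, log(50), 0.4), 200, 10)
  members <- sprintf("g%03d", 1:30)
  m0 <- make_em(vals, genes = sprintf("g%03d", 1:200))
  g <- sample_groups(list(A = sample_ids(m0)[1:5], B = sample_ids(m0)[6:10]))
  # +4 log2 units in group A for the member genes
  vals_shift <- vals
  vals_shift[1:30, 1:5] <- vals_shift[1:30, 1:5] * 16
  m_shift <- make_em(vals_shift, genes = sprintf("g%03d", 1:200), unit = "CPM")
  res <- compare_set_expression(m_shift, members, g, "A", "B")
  expect_lt(res$p_value, 0.01)
  expect_identical(res$direction, "A")
  expect_equal(res$n_genes, 30)
  expect_equal(nrow(res$values), 30)

  # duplicated columns: identical per-gene means in both groups, p = 1
  dup <- cbind(vals[, 1:5], vals[, 1:5])
  m_dup <- make_em(dup, genes = sprintf("g%03d", 1:200), unit = "CPM")
  res_dup <- compare_set_expression(m_dup, members, g, "A", "B")
  expect_equal(res_dup$p_value, 1)
  expect_identical(res_dup$direction, "equal")

  expect_error(compare_set_expression(m_shift, c("g001", "g002"), g, "A", "B"),
               ">= 3")
  expect_error(compare_set_expression(m_shift, members, g, "A", "Z"),
               "unknown group")
})
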