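# Pre-ranked gene-set enrichment with a permutation null, hypergeometric
# over-representation, and set-level Wilcoxon comparison of expression
# between groups.

#' Build a pre-ranked gene list from a DE table
#'
#' Sorts genes by descending ranking statistic (log2 fold change), ties
#' broken by ascending gene identifier. Genes with a non-finite statistic are
#' dropped and counted.
#'
#' @param de A `de_result` from [run_differential_expression()], or any data
#'   frame with `gene` and `log2_fold_change` columns.
#' @param statistic Ranking statistic; only `"log2FC"` is defined.
#' @return A `ranked_list`: data frame with columns `gene`, `stat`, sorted
#'   descending; attribute `n_dropped` counts non-finite statistics removed.
#' @export
make_ranked_list <- function(de, statistic = "log2FC") {
  statistic <- match.arg(statistic)
  if (!is.data.frame(de) || nrow(de) == 0L) {
    stop_data("make_ranked_list requires a non-empty DE table")
  }
  stat <- de$log2_fold_change
  genes <- de$gene
  keep <- is.finite(stat)
  n_dropped <- sum(!keep)
  stat <- stat[keep]; genes <- genes[keep]
  if (length(stat) == 0L) stop_data("no finite ranking statistics")
  ord <- order(-stat, genes, method = "radix")
  structure(
    data.frame(gene = genes[ord], stat = stat[ord], stringsAsFactors = FALSE),
    n_dropped = n_dropped,
    class = c("ranked_list", "data.frame")
  )
}

ranked_list_from_vector <- function(stats_named) {
  make_ranked_list(data.frame(gene = names(stats_named),
                              log2_fold_change = as.numeric(stats_named),
                              stringsAsFactors = FALSE))
}

# Core running-sum enrichment score for hit positions `pos` (sorted
# ascending) within a ranked statistic vector of length N. Hits increment by
# |stat|^weight normalized over hits; misses decrement by 1/(N - k). Only the
# candidate extrema (just before and just after each hit, plus the walk's
# endpoints) need inspecting, so this is O(k) after the sort.
es_from_positions <- function(stat, pos, weight) {
  n <- length(stat)
  k <- length(pos)
  w <- abs(stat[pos])^weight
  tot <- sum(w)
  w <- if (tot == 0) rep(1 / k, k) else w / tot  # all-zero stats: equal weights
  decr <- 1 / (n - k)
  cumw <- cumsum(w)
  # value just before hit i (after pos[i]-i misses), and just after hit i
  before <- c(0, cumw[-k]) - (pos - seq_len(k)) * decr
  after <- cumw - (pos - seq_len(k)) * decr
  hi <- max(after)
  lo <- min(before)
  # magnitude tie (to 1e-9, absorbing float jitter between equivalent
  # summation orders): score 0, so negating the statistics negates ES exactly
  es <- if (hi + lo > 1e-9) hi else if (hi + lo < -1e-9) lo else 0
  i_ext <- if (es >= 0) which.max(after)[1L] else which.min(before)[1L]
  list(es = es, i_ext = i_ext, pos = pos)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list: member genes increment the running sum by
#' `|stat|^weight` (normalized so member increments total 1), non-members
#' decrement by `1/(N - n_set)`. The enrichment score is the running-sum
#' value of maximal absolute deviation from zero (0 when the positive and
#' negative deviations tie exactly, preserving antisymmetry under statistic
#' negation). The leading edge is the members at or before the extremum for
#' positive ES, at or after it for negative ES.
#'
#' @param ranked A `ranked_list` from [make_ranked_list()].
#' @param set Character vector of member gene identifiers.
#' @param weight Nonnegative weight exponent (0 = classical unweighted KS
#'   statistic; default 1).
#' @return List with `es`, `running_sum` (length-N profile), `leading_edge`,
#'   `size` (members present in the list), `positions`.
#' @export
enrichment_score <- function(ranked, set, weight = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (weight < 0) stop_data("weight must be nonnegative")
  n <- nrow(ranked)
  hit <- ranked$gene %in% set
  k <- sum(hit)
  if (k == 0L) stop_data("gene set has no member in the ranked list")
  if (k == n) stop_data("gene set covers the whole ranked list; ES is undefined")
  pos <- which(hit)
  res <- es_from_positions(ranked$stat, pos, weight)
  w <- abs(ranked$stat[pos])^weight
  tot <- sum(w)
  w <- if (tot == 0) rep(1 / k, k) else w / tot
  step <- rep(-1 / (n - k), n)
  step[pos] <- w
  running <- cumsum(step)
  extremum_pos <- pos[res$i_ext]
  leading <- if (res$es >= 0) ranked$gene[pos[pos <= extremum_pos]]
             else ranked$gene[pos[pos >= extremum_pos]]
  list(es = res$es, running_sum = running, leading_edge = leading,
       size = k, positions = pos)
}

#' Pre-ranked GSEA with a gene-sampling permutation null
#'
#' For every set (after intersecting with the ranked list and filtering by
#' size bounds), computes the weighted enrichment score and compares it with
#' a null ensemble obtained by drawing `n_permutations` random position
#' assignments of the same size from the ranked list. Null ensembles are
#' shared between sets of equal size. The p-value conditions on the sign of
#' the observed score:
#' `p = (1 + #\{null of same sign with |ES_null| >= |ES|\}) / (1 + #\{null of same sign\})`,
#' so its resolution floor is `1/(n_permutations + 1)`.
#' `NES = ES / mean(|ES_null| of same sign)`; q-values are BH across all
#' tested sets in one family.
#'
#' @param ranked A `ranked_list`.
#' @param collection A [gene_set_collection()].
#' @param n_permutations Number of null draws (>= 100; default 1000).
#' @param weight Weight exponent of the running sum (default 1).
#' @param min_size,max_size Bounds on the intersected set size (default 5 and
#'   500, conventional GSEA practice).
#' @param seed Integer seed; identical seed and inputs give identical output.
#' @return A `gsea_result`: data frame with one row per tested set (`set`,
#'   `size`, `es`, `nes`, `p_value`, `q_value`, `leading_edge` as a
#'   comma-collapsed string), sorted by p then set name; attributes record
#'   the run parameters and the sets skipped by the size filter.
#' @export
preranked_gsea <- function(ranked, collection, n_permutations = 1000L,
                           weight = 1, min_size = 5L, max_size = 500L,
                           seed = 1L) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(collection, "gene_set_collection"))
  if (n_permutations < 100L) stop_data("n_permutations must be >= 100")
  n <- nrow(ranked)
  sizes <- vapply(collection, function(s) sum(ranked$gene %in% s), integer(1L))
  keep <- sizes >= min_size & sizes <= pmin(max_size, n - 1L)
  if (!any(keep)) {
    stop_data("all %d sets fall outside size bounds [%d, %d] after intersection",
              length(collection), min_size, max_size)
  }
  tested <- names(collection)[keep]
  obs <- lapply(tested, function(nm) enrichment_score(ranked, collection[[nm]], weight))
  es <- vapply(obs, `[[`, numeric(1L), "es")
  k_obs <- vapply(obs, `[[`, integer(1L), "size")

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  null_by_size <- list()
  for (k in sort(unique(k_obs))) {
    null_by_size[[as.character(k)]] <- vapply(seq_len(n_permutations), function(b) {
      es_from_positions(ranked$stat, sort(sample.int(n, k)), weight)$es
    }, numeric(1L))
  }
  p <- numeric(length(es))
  nes <- numeric(length(es))
  for (i in seq_along(es)) {
    null_es <- null_by_size[[as.character(k_obs[i])]]
    same <- null_es[sign(null_es) == sign(es[i]) | es[i] == 0]
    p[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
    nes[i] <- if (length(same)) es[i] / mean(abs(same)) else NA_real_
  }
  out <- data.frame(
    set = tested, size = k_obs, es = es, nes = nes,
    p_value = p, q_value = benjamini_hochberg(p),
    leading_edge = vapply(obs, function(o) paste(o$leading_edge, collapse = ","),
                          character(1L)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value, out$set, method = "radix"), ]
  rownames(out) <- NULL
  structure(out,
            n_permutations = n_permutations, weight = weight, seed = seed,
            min_size = min_size, max_size = max_size,
            n_skipped_size = sum(!keep),
            class = c("gsea_result", "data.frame"))
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("pre-ranked GSEA: %d sets tested (%d outside size bounds), %d permutations, seed %d\n",
              nrow(x), attr(x, "n_skipped_size"), attr(x, "n_permutations"),
              attr(x, "seed")))
  print(utils::head(as.data.frame(x)[, c("set", "size", "es", "nes", "p_value", "q_value")], 5L))
  invisible(x)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability of observing at least the overlap
#' between a query gene list and a set, within a gene universe. The set is
#' intersected with the universe before testing.
#'
#' @param query Character vector of query genes (must lie in the universe).
#' @param universe Character vector: the gene universe.
#' @param set Character vector: the gene set.
#' @return List with `overlap`, `expected` (`|query| * |set n universe| /
#'   |universe|`), `p_value` (`P(X >= overlap)`), and the sizes used.
#' @export
overrepresentation_test <- function(query, universe, set) {
  query <- unique(query); universe <- unique(universe); set <- unique(set)
  if (length(query) == 0L || length(universe) == 0L) {
    stop_data("query and universe must be non-empty")
  }
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop_data("query gene(s) outside the universe: %s",
              paste(utils::head(outside, 10L), collapse = ", "))
  }
  set_u <- intersect(set, universe)
  k <- length(intersect(query, set_u))
  m <- length(set_u)
  n_tot <- length(universe)
  n_q <- length(query)
  p <- stats::phyper(k - 1, m, n_tot - m, n_q, lower.tail = FALSE)
  list(overlap = k, expected = n_q * m / n_tot, p_value = p,
       set_size_in_universe = m, query_size = n_q, universe_size = n_tot)
}

#' Set-level expression comparison between two groups
#'
#' Reduces each member gene to its mean expression within each group, then
#' applies the unpaired Wilcoxon rank-sum test to the two per-gene mean
#' vectors — asking whether the genes of a biological process are, as a
#' population, expressed higher in one group than the other. Per-gene values
#' are returned plot-ready.
#'
#' @param matrix An [expression_matrix()] in a normalized unit.
#' @param set Character vector of member genes; at least 3 must be present in
#'   the matrix.
#' @param groups A [sample_groups()] object.
#' @param group_A,group_B Labels of the two groups.
#' @return A `set_comparison` list: `statistic`, `p_value`, `direction`
#'   (which group has the higher median per-gene mean, or `"equal"`),
#'   `values` (data frame `gene`, `mean_A`, `mean_B`), `n_genes`.
#' @export
compare_set_expression <- function(matrix, set, groups, group_A, group_B) {
  stopifnot(inherits(matrix, "expr_matrix"))
  s_a <- group_samples(groups, group_A)
  s_b <- group_samples(groups, group_B)
  missing <- setdiff(c(s_a, s_b), sample_ids(matrix))
  if (length(missing)) {
    stop_data("group sample(s) absent from matrix: %s", paste(missing, collapse = ", "))
  }
  members <- intersect(unique(set), gene_ids(matrix))
  if (length(members) < 3L) {
    stop_data("only %d member gene(s) found in the matrix; need >= 3", length(members))
  }
  mean_a <- rowMeans(em_values(matrix)[members, s_a, drop = FALSE])
  mean_b <- rowMeans(em_values(matrix)[members, s_b, drop = FALSE])
  test <- wilcoxon_rank_sum(mean_a, mean_b)
  med_a <- stats::median(mean_a); med_b <- stats::median(mean_b)
  direction <- if (med_a > med_b) group_A else if (med_b > med_a) group_B else "equal"
  structure(list(
    statistic = test$statistic, p_value = test$p_value, direction = direction,
    group_A = group_A, group_B = group_B, n_genes = length(members),
    values = data.frame(gene = members, mean_A = mean_a, mean_B = mean_b,
                        row.names = NULL, stringsAsFactors = FALSE)
  ), class = "set_comparison")
}

#' @export
print.set_comparison <- function(x, ...) {
  cat(sprintf("set comparison (%d genes): %s vs %s, W = %g, p = %.4g, higher in %s\n",
              x$n_genes, x$group_A, x$group_B, x$statistic, x$p_value,
              x$direction))
  invisible(x)
}
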