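# Independent oracles and small fixture builders shared across tests. Each
# oracle is a deliberately naive reference implementation, kept separate from
# the code paths it checks.

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(n_a + n_b, n_a) label assignments; two-sided rule is
# min(1, 2 * min(lower, upper)), matching the package's documented contract.
oracle_wilcoxon_enum <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  n_a <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ws <- apply(utils::combn(n, n_a), 2L, function(idx) {
    sum(r[idx]) - n_a * (n_a + 1) / 2
  })
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Brute-force running-sum enrichment score: full length-N profile, no
# shortcuts. `member` is a logical vector over the ranked statistics.
oracle_enrichment_score <- function(stat, member, weight) {
  n <- length(stat)
  k <- sum(member)
  w <- abs(stat)^weight
  tot <- sum(w[member])
  inc <- if (tot == 0) rep(1 / k, n) else w / tot
  step <- ifelse(member, inc, -1 / (n - k))
  rs <- cumsum(step)
  hi <- max(rs)
  lo <- min(rs)
  if (hi + lo > 1e-9) hi else if (hi + lo < -1e-9) lo else 0
}

# Closed-form upper-tail hypergeometric by direct summation of choose terms.
oracle_hypergeom_upper <- function(k, set_size, universe_size, query_size) {
  i <- seq(k, min(set_size, query_size))
  if (length(i) == 0L) return(if (k <= 0) 1 else 0)
  sum(choose(set_size, i) * choose(universe_size - set_size, query_size - i)) /
    choose(universe_size, query_size)
}

# Small expr_matrix builder with default identifiers.
make_em <- function(values, unit = "counts",
                    genes = sprintf("g%02d", seq_len(nrow(values))),
                    samples = sprintf("s%02d", seq_len(ncol(values)))) {
  m <- matrix(values, nrow = length(genes), ncol = length(samples))
  dimnames(m) <- list(genes, samples)
  expression_matrix(m, unit)
}

# Random Poisson-ish count matrix for property loops.
random_counts <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  make_em(matrix(rpois(n_genes * n_samples, lambda = 50) +
                   rpois(n_genes * n_samples, lambda = 5),
                 n_genes, n_samples))
}

random_lengths <- function(matrix, seed) {
  set.seed(seed)
  gene_length_table(stats::setNames(
    sample(200:5000, nrow(matrix), replace = TRUE), gene_ids(matrix)))
}

ranked_from_stats <- function(stats_named) {
  make_ranked_list(data.frame(gene = names(stats_named),
                              log2_fold_change = as.numeric(stats_named),
                              stringsAsFactors = FALSE))
}
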