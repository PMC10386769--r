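# Group-vs-group differential expression: log2 fold change, Welch's t,
# Wilcoxon rank-sum, Benjamini-Hochberg FDR, and the per-gene driver that
# assembles a volcano-ready table.

#' Log2 fold change of group means
#'
#' `log2((mean(values_A) + pseudocount) / (mean(values_B) + pseudocount))`.
#' The shared pseudocount stabilizes the ratio near zero expression.
#'
#' @param values_A,values_B Nonnegative expression values for each group.
#' @param pseudocount Positive offset (default 1).
#' @return A single real; positive when A is higher.
#' @export
log2_fold_change <- function(values_A, values_B, pseudocount = 1) {
  if (length(values_A) == 0L || length(values_B) == 0L) {
    stop_data("log2_fold_change requires non-empty groups")
  }
  if (pseudocount <= 0) stop_data("pseudocount must be positive")
  log2((mean(values_A) + pseudocount) / (mean(values_B) + pseudocount))
}

#' Welch's unequal-variance t-test
#'
#' `t = (mean_A - mean_B) / sqrt(s2_A/n_A + s2_B/n_B)` with sample variances
#' (n - 1 denominator) and Satterthwaite degrees of freedom; two-sided p from
#' the t distribution. Degenerate conventions: both variances zero with equal
#' means gives `t = 0, p = 1`; both variances zero with different means gives
#' `p = 0` with a warning.
#'
#' @param values_A,values_B Numeric vectors, each of length >= 2.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(values_A, values_B) {
  n_a <- length(values_A); n_b <- length(values_B)
  if (n_a < 2L || n_b < 2L) {
    stop_data("welch_t_test requires at least 2 values per group (got %d, %d)",
              n_a, n_b)
  }
  va <- stats::var(values_A) / n_a
  vb <- stats::var(values_B) / n_b
  delta <- mean(values_A) - mean(values_B)
  if (va + vb == 0) {
    if (delta == 0) return(list(statistic = 0, df = NA_real_, p_value = 1))
    warning("zero variance in both groups with unequal means; p = 0 by convention")
    return(list(statistic = sign(delta) * Inf, df = NA_real_, p_value = 0))
  }
  tstat <- delta / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1L) + vb^2 / (n_b - 1L))
  list(statistic = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Reports the Mann-Whitney statistic `W` for group A (rank sum of A minus its
#' minimum) and a two-sided p-value: exact via the null rank-sum distribution
#' when both groups have at most `exact_limit` values and the data are untied,
#' otherwise a normal approximation with mid-ranks, tie-corrected variance and
#' continuity correction. Two-sided p is `min(1, 2 * min(lower, upper))`.
#' All-tied data carry no evidence and return `p = 1`.
#'
#' @param values_A,values_B Numeric vectors, non-empty.
#' @param exact_limit Largest per-group size for the exact branch (default 25).
#' @return List with `statistic` (W for A), `p_value`, `exact` flag.
#' @export
wilcoxon_rank_sum <- function(values_A, values_B, exact_limit = 25L) {
  n_a <- length(values_A); n_b <- length(values_B)
  if (n_a == 0L || n_b == 0L) stop_data("wilcoxon_rank_sum requires non-empty groups")
  pooled <- c(values_A, values_B)
  r <- rank(pooled)
  w <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1L)
  if (!has_ties && n_a <= exact_limit && n_b <= exact_limit) {
    lower <- stats::pwilcox(w, n_a, n_b)
    upper <- stats::pwilcox(w - 1, n_a, n_b, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
    return(list(statistic = w, p_value = p, exact = TRUE))
  }
  mu <- n_a * n_b / 2
  n <- n_a + n_b
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(list(statistic = w, p_value = 1, exact = FALSE))  # all values tied
  }
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  list(statistic = w, p_value = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Thin validating wrapper over `stats::p.adjust(method = "BH")`; input order
#' is preserved.
#'
#' @param p_values Numeric vector with all values in \[0, 1\].
#' @return q-values in the original order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0L))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop_data("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-gene differential expression between two groups
#'
#' For every gene, compares per-sample normalized expression between the two
#' named groups with the chosen test, computes the log2 fold change of group
#' means, and adjusts p-values by Benjamini-Hochberg across all genes tested.
#' Genes with zero expression in every sample of both groups are dropped and
#' counted (`n_dropped` attribute). Count matrices are refused: normalize
#' first. For `log2`-unit input the fold change is the difference of group
#' means (already a log2 ratio); for linear units it is
#' [log2_fold_change()] with the shared pseudocount.
#'
#' @param matrix An [expression_matrix()] in a normalized or log2 unit.
#' @param groups A [sample_groups()] object resolvable in the matrix.
#' @param group_A,group_B Group labels to compare (A vs B).
#' @param test `"welch"` or `"wilcoxon"`.
#' @param pseudocount Positive pseudocount for the fold change (default 1).
#' @return A `de_result`: data frame with columns `gene`, `mean_A`, `mean_B`,
#'   `log2_fold_change`, `statistic`, `p_value`, `q_value`, ordered as the
#'   input genes; attributes record the comparison metadata and volcano
#'   defaults (`lfc_threshold = 1`, `q_threshold = 0.05`, informational only).
#' @export
run_differential_expression <- function(matrix, groups, group_A, group_B,
                                        test = c("wilcoxon", "welch"),
                                        pseudocount = 1) {
  test <- match.arg(test)
  stopifnot(inherits(matrix, "expr_matrix"))
  if (em_unit(matrix) == "counts") {
    stop_data("differential expression requires normalized input (got raw counts); run cpm/rpkm/tpm first")
  }
  if (identical(group_A, group_B)) {
    stop_data("group_A and group_B must differ (both '%s')", group_A)
  }
  s_a <- group_samples(groups, group_A)
  s_b <- group_samples(groups, group_B)
  missing <- setdiff(c(s_a, s_b), sample_ids(matrix))
  if (length(missing)) {
    stop_data("group sample(s) absent from matrix: %s",
              paste(missing, collapse = ", "))
  }
  if (test == "welch" && (length(s_a) < 2L || length(s_b) < 2L)) {
    stop_data("welch test requires >= 2 samples per group")
  }
  va <- em_values(matrix)[, s_a, drop = FALSE]
  vb <- em_values(matrix)[, s_b, drop = FALSE]
  nonzero <- rowSums(va != 0) + rowSums(vb != 0) > 0
  n_dropped <- sum(!nonzero)
  if (!any(nonzero)) stop_data("all genes have zero expression in both groups")
  va <- va[nonzero, , drop = FALSE]
  vb <- vb[nonzero, , drop = FALSE]
  genes <- rownames(va)
  mean_a <- rowMeans(va)
  mean_b <- rowMeans(vb)
  lfc <- if (em_unit(matrix) == "log2") {
    mean_a - mean_b
  } else {
    log2((mean_a + pseudocount) / (mean_b + pseudocount))
  }
  res <- vapply(seq_along(genes), function(i) {
    if (test == "welch") {
      r <- welch_t_test(va[i, ], vb[i, ])
    } else {
      r <- wilcoxon_rank_sum(va[i, ], vb[i, ])
    }
    c(r$statistic, r$p_value)
  }, numeric(2L))
  out <- data.frame(
    gene = genes,
    mean_A = mean_a,
    mean_B = mean_b,
    log2_fold_change = lfc,
    statistic = res[1L, ],
    p_value = res[2L, ],
    q_value = benjamini_hochberg(res[2L, ]),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(out,
            test = test, group_A = group_A, group_B = group_B,
            n_A = length(s_a), n_B = length(s_b),
            pseudocount = pseudocount, n_dropped = n_dropped,
            lfc_threshold = 1, q_threshold = 0.05,
            class = c("de_result", "data.frame"))
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("differential expression: %s vs %s (%s test), %d genes, %d dropped all-zero\n",
              attr(x, "group_A"), attr(x, "group_B"), attr(x, "test"),
              nrow(x), attr(x, "n_dropped")))
  top <- x[order(x$q_value, x$p_value), ]
  print(utils::head(as.data.frame(top), 5L))
  invisible(x)
}
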