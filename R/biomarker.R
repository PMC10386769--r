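# Marker-gene discovery: rank genes that separate one group from the rest by
# maximized fold change and minimized coefficient of variation, optionally by
# Welch/Wilcoxon p-value or an additive rank combination.
#
# The score is an additive rank combination: rank of descending log2FC
# (target vs rest) plus rank of ascending max within-group CV, with
# lexicographic gene-id tie-breaking — a scale-free formalization of
# "maximized fold change and minimized coefficients of variation". A marker
# must be stable in EVERY group (target included), so the CV entering the
# rank is the max over all within-group CVs.

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean. For
#' all-zero input (the only way nonnegative values have mean zero) the CV is
#' 0 by convention.
#'
#' @param values Nonnegative numeric vector of length >= 2.
#' @return Nonnegative real.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) {
    stop_data("coefficient_of_variation requires at least 2 values")
  }
  m <- mean(values)
  if (m == 0) return(0)
  stats::sd(values) / m
}

# rank with deterministic lexicographic tie-breaking on gene id
rank_by <- function(key, ids, decreasing = FALSE) {
  ord <- order(if (decreasing) -key else key, ids, method = "radix")
  r <- integer(length(key))
  r[ord] <- seq_along(key)
  r
}

#' Discover candidate marker genes for one group
#'
#' Ranks every gene for its ability to mark the target group against the
#' union of all other groups ("rest"). Components per gene: `log2FC` (target
#' vs rest group means, shared pseudocount), `cv_target` (within-target CV),
#' `cv_rest_max` (max within-group CV over the non-target groups) and, for
#' test-based methods, a Welch or Wilcoxon p-value (target samples vs rest
#' samples) with BH q across genes.
#'
#' Orderings by method:
#' * `cv_fc`: ascending `combined_rank = rank_fc + rank_cv`, where `rank_fc`
#'   is 1 for the largest (most positive toward the target) log2FC and
#'   `rank_cv` is 1 for the smallest `max(cv_target, cv_rest_max)`.
#' * `welch` / `wilcoxon`: ascending p, then descending |log2FC|.
#' * `combined`: ascending `rank_fc + rank_cv + rank_p`.
#'
#' All rank ties are broken by ascending gene identifier, so the output is a
#' deterministic function of the inputs. Only genes with `log2FC > 0` toward
#' the target are eligible markers; ineligible genes are retained in the
#' table, flagged, and sorted after all eligible ones.
#'
#' @param matrix An [expression_matrix()] in a normalized (non-count) unit;
#'   CV is computed on the linear scale, so non-log units are recommended.
#' @param groups A [sample_groups()] object; every group needs >= 2 samples
#'   for CV-based methods.
#' @param target Label of the group to find markers for.
#' @param method One of `"cv_fc"`, `"welch"`, `"wilcoxon"`, `"combined"`.
#' @param pseudocount Positive pseudocount for the fold change.
#' @param top_k Number of top eligible genes flagged as the marker panel
#'   (`NULL` = all eligible).
#' @return A `biomarker_result`: data frame ordered by the method's ranking
#'   with columns `gene`, `log2FC`, `cv_target`, `cv_rest_max`, `rank_fc`,
#'   `rank_cv`, (`p_value`, `q_value`, `rank_p` for test methods),
#'   `combined_rank`, `eligible`, `selected`.
#' @export
discover_biomarkers <- function(matrix, groups, target,
                                method = c("cv_fc", "welch", "wilcoxon", "combined"),
                                pseudocount = 1, top_k = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "expr_matrix"))
  if (em_unit(matrix) == "counts") {
    stop_data("biomarker discovery requires normalized input; run cpm/rpkm/tpm first")
  }
  s_target <- group_samples(groups, target)
  rest_groups <- setdiff(names(groups), target)
  if (length(rest_groups) == 0L) stop_data("no non-target group exists")
  missing <- setdiff(unlist(groups, use.names = FALSE), sample_ids(matrix))
  if (length(missing)) {
    stop_data("group sample(s) absent from matrix: %s", paste(missing, collapse = ", "))
  }
  needs_cv <- method %in% c("cv_fc", "combined")
  if (needs_cv && any(lengths(unclass(groups)) < 2L)) {
    stop_data("CV-based ranking requires >= 2 samples in every group")
  }
  needs_test <- method %in% c("welch", "wilcoxon", "combined")
  vals <- em_values(matrix)
  genes <- rownames(vals)
  v_target <- vals[, s_target, drop = FALSE]
  s_rest <- unlist(unclass(groups)[rest_groups], use.names = FALSE)
  v_rest <- vals[, s_rest, drop = FALSE]

  lfc <- log2((rowMeans(v_target) + pseudocount) / (rowMeans(v_rest) + pseudocount))
  cv_row <- function(m) {
    if (ncol(m) < 2L) return(rep(NA_real_, nrow(m)))
    mu <- rowMeans(m)
    sdv <- apply(m, 1L, stats::sd)
    ifelse(mu == 0, 0, sdv / mu)
  }
  cv_target <- cv_row(v_target)
  cv_by_group <- vapply(rest_groups, function(g) {
    cv_row(vals[, group_samples(groups, g), drop = FALSE])
  }, numeric(length(genes)))
  cv_by_group <- matrix(cv_by_group, nrow = length(genes))
  cv_rest_max <- apply(cv_by_group, 1L, max)
  cv_max <- pmax(cv_target, cv_rest_max)

  rank_fc <- rank_by(lfc, genes, decreasing = TRUE)
  rank_cv <- if (needs_cv) rank_by(cv_max, genes) else rep(NA_integer_, length(genes))

  out <- data.frame(gene = genes, log2FC = lfc,
                    cv_target = cv_target, cv_rest_max = cv_rest_max,
                    rank_fc = rank_fc, rank_cv = rank_cv,
                    row.names = NULL, stringsAsFactors = FALSE)

  if (needs_test) {
    test_fun <- if (method == "welch" ||
                    (method == "combined" && length(s_target) >= 2L && length(s_rest) >= 2L)) {
      # combined uses Welch when sizes allow, else falls back to rank-sum
      if (method == "welch" && (length(s_target) < 2L || length(s_rest) < 2L)) {
        stop_data("welch method requires >= 2 samples on each side")
      }
      function(a, b) welch_t_test(a, b)$p_value
    } else {
      function(a, b) wilcoxon_rank_sum(a, b)$p_value
    }
    p <- vapply(seq_along(genes), function(i) test_fun(v_target[i, ], v_rest[i, ]),
                numeric(1L))
    out$p_value <- p
    out$q_value <- benjamini_hochberg(p)
    out$rank_p <- rank_by(p, genes)
  }

  key <- switch(method,
    cv_fc = {
      out$combined_rank <- out$rank_fc + out$rank_cv
      out$combined_rank
    },
    combined = {
      out$combined_rank <- out$rank_fc + out$rank_cv + out$rank_p
      out$combined_rank
    },
    welch = ,
    wilcoxon = NULL
  )
  out$eligible <- out$log2FC > 0
  ord <- if (is.null(key)) {
    order(!out$eligible, out$p_value, -abs(out$log2FC), out$gene, method = "radix")
  } else {
    order(!out$eligible, key, out$gene, method = "radix")
  }
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  n_eligible <- sum(out$eligible)
  k <- if (is.null(top_k)) n_eligible else min(top_k, n_eligible)
  out$selected <- seq_len(nrow(out)) <= k
  structure(out,
            target = target, method = method, pseudocount = pseudocount,
            top_k = top_k,
            low_separation = n_eligible == 0L || max(out$log2FC) < 1,
            class = c("biomarker_result", "data.frame"))
}

#' @export
print.biomarker_result <- function(x, ...) {
  cat(sprintf("biomarkers for group '%s' (method %s): %d selected of %d eligible genes%s\n",
              attr(x, "target"), attr(x, "method"), sum(x$selected),
              sum(x$eligible),
              if (isTRUE(attr(x, "low_separation"))) " [low separation]" else ""))
  print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' One-vs-rest marker panels for every group
#'
#' Runs [discover_biomarkers()] once per group and assembles the union panel
#' (deduplicated; each gene keeps the group where it ranked best) for
#' downstream heatmap or embedding use.
#'
#' @inheritParams discover_biomarkers
#' @return List with `results` (named list of `biomarker_result`) and `panel`
#'   (data frame `gene`, `group`, `position`: best selected rank per gene).
#' @export
one_vs_rest_panel <- function(matrix, groups,
                              method = c("cv_fc", "welch", "wilcoxon", "combined"),
                              pseudocount = 1, top_k = NULL) {
  method <- match.arg(method)
  if (length(groups) < 2L) stop_data("one_vs_rest_panel requires >= 2 groups")
  results <- lapply(names(groups), function(g) {
    discover_biomarkers(matrix, groups, g, method = method,
                        pseudocount = pseudocount, top_k = top_k)
  })
  names(results) <- names(groups)
  panel <- do.call(rbind, lapply(names(results), function(g) {
    r <- results[[g]]
    sel <- which(r$selected)
    if (!length(sel)) return(NULL)
    data.frame(gene = r$gene[sel], group = g, position = sel,
               stringsAsFactors = FALSE)
  }))
  if (is.null(panel)) {
    panel <- data.frame(gene = character(), group = character(),
                        position = integer(), stringsAsFactors = FALSE)
  } else {
    panel <- panel[order(panel$position, panel$gene, method = "radix"), ]
    panel <- panel[!duplicated(panel$gene), , drop = FALSE]
    rownames(panel) <- NULL
  }
  list(results = results, panel = panel)
}
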