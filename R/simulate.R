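# Deterministic synthetic-data generator: grouped negative-binomial count
# matrices with planted one-vs-rest markers, pairwise DE genes and enriched
# gene sets, plus the truth tables every downstream test consumes. This is
# the study substrate standing in for public expression archives: grouped
# immune-cell-like libraries at bulk sequencing depth.

#' Specification of a synthetic grouped RNA-seq dataset
#'
#' Defaults describe the conditions used throughout the package's
#' simulations: a 500-gene matrix over three groups of four libraries,
#' log-normal baseline means around a few hundred counts, a shared
#' negative-binomial dispersion giving biological CV about 0.5, ten planted
#' markers per group at 8-fold enrichment with within-group CV capped at 0.2,
#' fifty planted DE genes at |log2 effect| 2 between the first two groups,
#' and ten planted gene sets of size 20 drawing 80% of members from the
#' up-regulated DE genes (plus as many random background sets).
#'
#' @param n_genes Total genes.
#' @param groups Named integer vector: samples per group.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-gene
#'   baseline mean counts.
#' @param dispersion Negative-binomial size parameter shared by all genes
#'   (biological CV at high depth is about `1/sqrt(dispersion)`).
#' @param length_range Integer range of gene lengths in bp.
#' @param markers_per_group,marker_fold,marker_cv_cap Planted one-vs-rest
#'   markers: count per group, fold enrichment in the target group, and the
#'   within-group CV cap enforced (in every group) by rejection resampling.
#' @param n_de,de_lfc Planted DE genes between the first two groups: count
#'   and absolute log2 effect (half up, half down in the second group).
#' @param n_sets,set_size,set_de_fraction Planted enriched sets: count, size,
#'   and the fraction of members drawn from up-regulated DE genes.
#' @param n_null_sets Random background sets of the same size.
#' @param seed Integer seed; the bundle is a pure function of the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 500L,
                           groups = c(A = 4L, B = 4L, C = 4L),
                           baseline_meanlog = log(200), baseline_sdlog = 1,
                           dispersion = 4,
                           length_range = c(200L, 10000L),
                           markers_per_group = 10L, marker_fold = 8,
                           marker_cv_cap = 0.2,
                           n_de = 50L, de_lfc = 2,
                           n_sets = 10L, set_size = 20L,
                           set_de_fraction = 0.8,
                           n_null_sets = 10L,
                           seed = 1L) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop_data("groups must be a named vector of sample counts")
  }
  if (any(groups < 1L)) stop_data("every group needs at least one sample")
  if (markers_per_group < 0L || n_de < 0L || n_sets < 0L) {
    stop_data("planted counts must be nonnegative")
  }
  n_planted <- markers_per_group * length(groups) + n_de
  if (n_planted > n_genes) {
    stop_data("planted genes (%d) exceed n_genes (%d)", n_planted, n_genes)
  }
  if (markers_per_group > 0L && marker_fold <= 1) {
    stop_data("marker_fold must exceed 1")
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

# NB draws for one gene in one group, rejection-resampled until the sample CV
# is within the cap; after max_retries keep the lowest-CV draw seen.
rnbinom_capped <- function(n, mu, size, cv_cap, max_retries = 500L) {
  best <- NULL
  best_cv <- Inf
  for (i in seq_len(max_retries)) {
    draw <- stats::rnbinom(n, mu = mu, size = size)
    m <- mean(draw)
    cv <- if (m == 0) Inf else stats::sd(draw) / m
    if (cv <= cv_cap) return(list(counts = draw, ok = TRUE))
    if (cv < best_cv) { best <- draw; best_cv <- cv }
  }
  list(counts = best, ok = FALSE)
}

#' Generate a synthetic dataset bundle
#'
#' Draws counts per gene and sample from a negative binomial with the
#' group-adjusted mean: planted markers carry `baseline * marker_fold` in
#' their target group, planted DE genes carry `baseline * 2^(+-de_lfc)` in
#' the second group of the DE pair. Marker genes are rejection-resampled in
#' every group until their within-group CV is at or below the cap (bounded
#' retries, then a warning). Fully reproducible from the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A `dataset_bundle` list: `matrix` (counts [expression_matrix()]),
#'   `groups` ([sample_groups()]), `lengths` ([gene_length_table()]), `sets`
#'   ([gene_set_collection()]), and `truth` (markers per group, DE table with
#'   signs, enriched set names).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  group_names <- names(spec$groups)
  samples_by_group <- lapply(group_names, function(g) {
    sprintf("%s_%d", g, seq_len(spec$groups[[g]]))
  })
  names(samples_by_group) <- group_names
  groups <- sample_groups(samples_by_group)
  samples <- unlist(samples_by_group, use.names = FALSE)

  baseline <- stats::rlnorm(spec$n_genes, spec$baseline_meanlog, spec$baseline_sdlog)
  lengths <- gene_length_table(stats::setNames(
    sample(seq(spec$length_range[1L], spec$length_range[2L]), spec$n_genes,
           replace = TRUE), genes))

  # assign planted roles over disjoint gene indices
  n_marker_total <- spec$markers_per_group * length(group_names)
  planted_idx <- sample.int(spec$n_genes, n_marker_total + spec$n_de)
  marker_idx <- planted_idx[seq_len(n_marker_total)]
  de_idx <- planted_idx[n_marker_total + seq_len(spec$n_de)]
  markers_by_group <- split(marker_idx,
                            rep(group_names, each = spec$markers_per_group))[group_names]
  if (spec$markers_per_group == 0L) {
    markers_by_group <- stats::setNames(rep(list(integer(0L)), length(group_names)),
                                        group_names)
  }
  de_sign <- if (spec$n_de > 0L) {
    rep_len(c(1, -1), spec$n_de)  # up/down in the second group of the pair
  } else numeric(0L)

  # per-gene per-group mean matrix
  mu <- matrix(baseline, spec$n_genes, length(group_names),
               dimnames = list(genes, group_names))
  for (g in group_names) {
    mu[markers_by_group[[g]], g] <- baseline[markers_by_group[[g]]] * spec$marker_fold
  }
  if (spec$n_de > 0L && length(group_names) >= 2L) {
    g2 <- group_names[2L]
    mu[de_idx, g2] <- baseline[de_idx] * 2^(spec$de_lfc * de_sign)
  }

  counts <- matrix(0, spec$n_genes, length(samples),
                   dimnames = list(genes, samples))
  is_marker <- seq_len(spec$n_genes) %in% marker_idx
  n_cap_failures <- 0L
  for (g in group_names) {
    cols <- samples_by_group[[g]]
    n_s <- length(cols)
    plain <- !is_marker
    counts[plain, cols] <- stats::rnbinom(sum(plain) * n_s,
                                          mu = rep(mu[plain, g], n_s),
                                          size = spec$dispersion)
    for (i in which(is_marker)) {
      r <- rnbinom_capped(n_s, mu[i, g], spec$dispersion, spec$marker_cv_cap)
      counts[i, cols] <- r$counts
      if (!r$ok) n_cap_failures <- n_cap_failures + 1L
    }
  }
  if (n_cap_failures > 0L) {
    warning(sprintf("CV cap not reached for %d marker gene-group draws; kept lowest-CV attempt",
                    n_cap_failures))
  }

  # planted enriched sets from up-regulated DE genes, plus random background
  sets <- list()
  enriched_names <- character(0L)
  if (spec$n_sets > 0L && spec$n_de > 0L) {
    up_genes <- genes[de_idx[de_sign > 0]]
    other_genes <- setdiff(genes, up_genes)
    n_from_de <- min(round(spec$set_size * spec$set_de_fraction), length(up_genes))
    for (j in seq_len(spec$n_sets)) {
      nm <- sprintf("PLANTED_SET_%02d", j)
      members <- c(sample(up_genes, n_from_de),
                   sample(other_genes, spec$set_size - n_from_de))
      sets[[nm]] <- members
      enriched_names <- c(enriched_names, nm)
    }
  }
  if (spec$n_null_sets > 0L) {
    for (j in seq_len(spec$n_null_sets)) {
      sets[[sprintf("NULL_SET_%02d", j)]] <- sample(genes, spec$set_size)
    }
  }
  collection <- if (length(sets)) {
    gene_set_collection(sets, descriptions = rep("synthetic", length(sets)))
  } else NULL

  truth <- list(
    markers = lapply(markers_by_group, function(i) genes[i]),
    de = data.frame(gene = genes[de_idx], sign = de_sign,
                    stringsAsFactors = FALSE),
    enriched_sets = enriched_names
  )
  structure(list(
    matrix = expression_matrix(counts, "counts"),
    groups = groups, lengths = lengths, sets = collection, truth = truth,
    spec = spec
  ), class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf("synthetic dataset: %d genes x %d samples in %d groups (seed %d)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$groups), x$spec$seed))
  cat(sprintf("planted: %d markers/group, %d DE genes, %d enriched sets\n",
              x$spec$markers_per_group, x$spec$n_de,
              length(x$truth$enriched_sets)))
  invisible(x)
}
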