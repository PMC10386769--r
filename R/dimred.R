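# Sample-space dimensionality reduction (PCA, classical MDS, delegated
# t-SNE/UMAP) and hierarchical row/column ordering for heatmaps. Samples
# (libraries) are the observations; genes are the features. log2-transformed
# input is recommended for embeddings and warned-if-absent, never forced.

warn_if_not_log <- function(matrix, what) {
  if (em_unit(matrix) != "log2") {
    warning(sprintf("%s on unit '%s'; log2-transformed input is recommended",
                    what, em_unit(matrix)))
  }
}

#' Principal component analysis of samples
#'
#' Centers (and optionally unit-scales) gene features across samples, drops
#' constant features, and decomposes via singular values (`stats::prcomp`).
#' Component signs follow a fixed convention — the largest-magnitude loading
#' of each component is positive — so coordinates are stable across
#' platforms.
#'
#' @param matrix An [expression_matrix()] with >= 2 samples.
#' @param k Number of components, `1 <= k <= min(n_samples, n_genes)`.
#' @param scale_features If `TRUE`, scale features to unit variance.
#' @param transpose If `TRUE`, embed genes instead of samples.
#' @return An `embedding_result`: list with `coordinates` (items x k, row
#'   names = identifiers), `explained_variance` (fraction per component,
#'   nonincreasing), `loadings`, `method = "pca"`, `n_dropped_features`.
#' @export
pca <- function(matrix, k = 2L, scale_features = FALSE, transpose = FALSE) {
  stopifnot(inherits(matrix, "expr_matrix"))
  x <- em_values(matrix)
  x <- if (transpose) x else t(x)  # observations in rows
  if (nrow(x) < 2L) stop_data("pca requires at least 2 observations")
  if (k < 1L || k > min(dim(x))) {
    stop_data("k = %d out of range 1..%d", k, min(dim(x)))
  }
  const <- apply(x, 2L, function(col) max(col) == min(col))
  n_dropped <- sum(const)
  x <- x[, !const, drop = FALSE]
  if (ncol(x) == 0L) stop_data("all features are constant")
  fit <- stats::prcomp(x, center = TRUE, scale. = scale_features)
  ev <- fit$sdev^2
  k_eff <- min(k, ncol(fit$rotation))
  rot <- fit$rotation[, seq_len(k_eff), drop = FALSE]
  coords <- fit$x[, seq_len(k_eff), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(k_eff)) {
    i_max <- which.max(abs(rot[, j]))[1L]
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  if (k_eff < k) {  # rank-deficient input: pad zero-variance components
    coords <- cbind(coords, matrix(0, nrow(coords), k - k_eff))
  }
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(
    coordinates = coords,
    explained_variance = (ev / sum(ev))[seq_len(k_eff)],
    loadings = rot, method = "pca", k = k,
    n_dropped_features = n_dropped
  ), class = "embedding_result")
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centers the squared distance matrix and takes the top-k
#' nonnegative eigenpairs (`stats::cmdscale`). The mass of negative
#' eigenvalues — non-Euclidean distortion — is reported as a fraction.
#'
#' @param distances Square symmetric nonnegative matrix with zero diagonal
#'   (or a `dist` object).
#' @param k Number of dimensions.
#' @return An `embedding_result` with `coordinates`, `eigenvalues`,
#'   `negative_mass` (fraction of |eigenvalue| mass that is negative),
#'   `method = "mds"`.
#' @export
classical_mds <- function(distances, k = 2L) {
  if (inherits(distances, "dist")) distances <- as.matrix(distances)
  if (!is.matrix(distances) || nrow(distances) != ncol(distances)) {
    stop_data("distances must be a square matrix")
  }
  if (max(abs(distances - t(distances))) > 1e-8) {
    stop_data("distance matrix is not symmetric (tolerance 1e-8)")
  }
  if (any(abs(diag(distances)) > 1e-12)) {
    stop_data("distance matrix must have a zero diagonal")
  }
  if (any(distances < 0)) stop_data("distances must be nonnegative")
  n <- nrow(distances)
  if (k < 1L || k > n - 1L) stop_data("k = %d out of range 1..%d", k, n - 1L)
  # degenerate geometries (fewer positive eigenvalues than k) are padded with
  # zero coordinates below; cmdscale's own warning about them is redundant
  fit <- suppressWarnings(stats::cmdscale(distances, k = k, eig = TRUE))
  eig <- fit$eig
  neg_mass <- if (sum(abs(eig)) > 0) sum(abs(pmin(eig, 0))) / sum(abs(eig)) else 0
  if (neg_mass > 1e-8) {
    warning(sprintf("non-Euclidean distances: %.3g of eigenvalue mass is negative",
                    neg_mass))
  }
  coords <- fit$points
  if (is.null(coords) || ncol(coords) < k) {  # degenerate geometry: pad zeros
    pad <- matrix(0, n, k - if (is.null(coords)) 0L else ncol(coords))
    coords <- cbind(coords, pad)
  }
  rownames(coords) <- rownames(distances)
  colnames(coords) <- paste0("MDS", seq_len(k))
  structure(list(coordinates = coords, eigenvalues = eig,
                 negative_mass = neg_mass, method = "mds", k = k),
            class = "embedding_result")
}

#' Nonlinear embedding of samples by t-SNE or UMAP
#'
#' Delegates to the established implementations (Rtsne, uwot) with
#' single-threaded, seeded execution so that identical seed and inputs give
#' identical coordinates. The contract here is shape, determinism and cluster
#' preservation, not the optimizer internals.
#'
#' @param matrix An [expression_matrix()] (log2 recommended).
#' @param method `"tsne"` or `"umap"`.
#' @param k Output dimensions, 2 or 3.
#' @param seed Integer seed.
#' @param neighborhood t-SNE perplexity (default 30, lowered automatically is
#'   an error instead: must satisfy `3 * perplexity < n - 1`) or UMAP
#'   n_neighbors (default 15; must be `< n`).
#' @param transpose If `TRUE`, embed genes instead of samples.
#' @return An `embedding_result` with `coordinates`, `method`, `seed`,
#'   `neighborhood`.
#' @export
embed_nonlinear <- function(matrix, method = c("tsne", "umap"), k = 2L,
                            seed = 1L, neighborhood = NULL, transpose = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "expr_matrix"))
  if (!k %in% c(2L, 3L)) stop_data("k must be 2 or 3 for nonlinear embeddings")
  warn_if_not_log(matrix, "nonlinear embedding")
  x <- em_values(matrix)
  x <- if (transpose) x else t(x)
  n <- nrow(x)
  ids <- rownames(x)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  if (method == "tsne") {
    perplexity <- if (is.null(neighborhood)) 30 else neighborhood
    if (3 * perplexity >= n - 1) {
      stop_data("perplexity %g too large for %d observations; need 3*perplexity < n - 1 (try <= %g)",
                perplexity, n, (n - 2) / 3)
    }
    fit <- Rtsne::Rtsne(x, dims = k, perplexity = perplexity,
                        check_duplicates = FALSE, pca = TRUE,
                        num_threads = 1L, verbose = FALSE)
    coords <- fit$Y
  } else {
    n_neighbors <- if (is.null(neighborhood)) 15 else neighborhood
    if (n_neighbors >= n) {
      stop_data("n_neighbors %g must be below the number of observations (%d)",
                n_neighbors, n)
    }
    coords <- uwot::umap(x, n_components = k, n_neighbors = n_neighbors,
                         n_threads = 1L, n_sgd_threads = 1L, verbose = FALSE)
  }
  rownames(coords) <- ids
  colnames(coords) <- paste0(toupper(method), seq_len(k))
  structure(list(coordinates = coords, method = method, k = k, seed = seed,
                 neighborhood = if (method == "tsne") {
                   if (is.null(neighborhood)) 30 else neighborhood
                 } else {
                   if (is.null(neighborhood)) 15 else neighborhood
                 }),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("%s embedding: %d items x %d dims\n", x$method,
              nrow(x$coordinates), ncol(x$coordinates)))
  if (!is.null(x$explained_variance)) {
    cat("explained variance:",
        paste(sprintf("%.3f", x$explained_variance), collapse = " "), "\n")
  }
  print(utils::head(x$coordinates, 4L))
  invisible(x)
}

#' Hierarchical leaf order for heatmaps
#'
#' Agglomerative clustering along one axis; returns the dendrogram leaf
#' order. Correlation distance is `1 - Pearson r`; rows constant along the
#' other axis get distance 1 to everything (their correlation is undefined).
#'
#' @param matrix An [expression_matrix()].
#' @param axis `"genes"` or `"samples"`.
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @return Character vector: identifiers in leaf order (a permutation of the
#'   axis identifiers). A single item returns the identity order.
#' @export
hierarchical_order <- function(matrix, axis = c("genes", "samples"),
                               distance = c("correlation", "euclidean"),
                               linkage = c("average", "complete")) {
  axis <- match.arg(axis); distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  stopifnot(inherits(matrix, "expr_matrix"))
  x <- em_values(matrix)
  if (axis == "samples") x <- t(x)
  ids <- rownames(x)
  if (nrow(x) == 1L) return(ids)
  if (distance == "euclidean") {
    d <- stats::dist(x, method = "euclidean")
  } else {
    cm <- suppressWarnings(stats::cor(t(x)))
    cm[is.na(cm)] <- 0              # constant rows: distance 1 to everything
    dmat <- 1 - cm
    diag(dmat) <- 0
    d <- stats::as.dist(dmat)
  }
  fit <- stats::hclust(d, method = linkage)
  ids[fit$order]
}
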