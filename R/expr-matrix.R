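#' @keywords internal
"_PACKAGE"

# Condition helpers: data errors exit 1 from the CLI, usage errors exit 2.
stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("exprkit_data_error", "error")))
}

stop_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("exprkit_usage_error", "error")))
}

#' Units an expression matrix may declare
#'
#' @return Character vector of recognised unit tags.
#' @export
expression_units <- function() {
  c("counts", "CPM", "RPKM", "FPKM", "TPM", "log2")
}

#' Construct an expression matrix with a declared unit
#'
#' The central container of the package: a numeric gene x sample grid with
#' unique gene identifiers as row names, unique sample identifiers as column
#' names, and a unit tag recording what the values mean. All values must be
#' finite, and nonnegative unless the unit is `log2`.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   complete row and column names.
#' @param unit One of [expression_units()].
#' @return An object of class `expr_matrix` (a classed numeric matrix with a
#'   `unit` attribute).
#' @examples
#' m <- expression_matrix(matrix(1:4, 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))), unit = "counts")
#' em_unit(m)
#' @export
expression_matrix <- function(values, unit) {
  unit <- match.arg(unit, expression_units())
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_data("expression values must be a numeric matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop_data("expression matrix must have at least one gene and one sample")
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || anyNA(gid) || any(gid == "")) {
    stop_data("expression matrix requires gene identifiers as row names")
  }
  if (is.null(sid) || anyNA(sid) || any(sid == "")) {
    stop_data("expression matrix requires sample identifiers as column names")
  }
  if (anyDuplicated(gid)) {
    stop_data("duplicate gene identifier: %s",
              paste(unique(gid[duplicated(gid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    stop_data("duplicate sample identifier: %s",
              paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop_data("non-finite value at gene '%s', sample '%s'",
              gid[bad[1L]], sid[bad[2L]])
  }
  if (unit != "log2" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop_data("negative value %g at gene '%s', sample '%s' (unit '%s' requires values >= 0)",
              values[bad[1L], bad[2L]], gid[bad[1L]], sid[bad[2L]], unit)
  }
  structure(values, unit = unit, class = c("expr_matrix", class(values)))
}

#' @rdname expression_matrix
#' @param x An `expr_matrix`.
#' @export
em_unit <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  attr(x, "unit")
}

#' @rdname expression_matrix
#' @export
em_values <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  y <- unclass(x)
  attr(y, "unit") <- NULL
  y
}

#' @rdname expression_matrix
#' @export
gene_ids <- function(x) rownames(x)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x)

# Subsetting keeps the class and unit as long as the result is still a matrix.
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    out <- structure(out, unit = attr(x, "unit"),
                     class = c("expr_matrix", class(out)))
  }
  out
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples [unit: %s]\n",
              nrow(x), ncol(x), em_unit(x)))
  n <- min(5L, nrow(x))
  m <- min(5L, ncol(x))
  print(em_values(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) {
    cat(sprintf("... (%d more genes, %d more samples)\n",
                nrow(x) - n, ncol(x) - m))
  }
  invisible(x)
}

#' Group assignment of samples
#'
#' A labelled, pairwise-disjoint partition of sample identifiers into
#' comparison groups, stored as a named list of character vectors.
#'
#' @param groups Named list, one character vector of sample identifiers per
#'   group label.
#' @return Object of class `sample_groups`.
#' @export
sample_groups <- function(groups) {
  if (!is.list(groups) || is.null(names(groups)) ||
      any(names(groups) == "") || anyDuplicated(names(groups))) {
    stop_data("groups must be a named list with unique non-empty labels")
  }
  groups <- lapply(groups, as.character)
  if (any(lengths(groups) == 0L)) {
    stop_data("empty group: %s",
              paste(names(groups)[lengths(groups) == 0L], collapse = ", "))
  }
  all_samples <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_samples)) {
    dup <- unique(all_samples[duplicated(all_samples)])
    stop_data("sample assigned to more than one group: %s",
              paste(dup, collapse = ", "))
  }
  structure(groups, class = "sample_groups")
}

#' @export
print.sample_groups <- function(x, ...) {
  cat(sprintf("sample groups: %d groups, %d samples\n",
              length(x), sum(lengths(x))))
  for (g in names(x)) {
    cat(sprintf("  %s (%d): %s\n", g, length(x[[g]]),
                paste(utils::head(x[[g]], 6L), collapse = ", ")))
  }
  invisible(x)
}

#' Samples belonging to one group
#'
#' @param groups A [sample_groups()] object.
#' @param label Group label; unknown labels raise an error naming the known
#'   ones.
#' @return Character vector of sample identifiers.
#' @export
group_samples <- function(groups, label) {
  stopifnot(inherits(groups, "sample_groups"))
  if (!label %in% names(groups)) {
    stop_data("unknown group label '%s' (known: %s)", label,
              paste(names(groups), collapse = ", "))
  }
  unclass(groups)[[label]]
}

#' Named collection of gene sets
#'
#' @param sets Named list; each element is a character vector of member gene
#'   identifiers (deduplicated, order preserved).
#' @param descriptions Optional character vector of per-set descriptions.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop_data("gene sets must be a named list")
  }
  if (anyDuplicated(names(sets))) {
    dup <- unique(names(sets)[duplicated(names(sets))])
    stop_data("duplicate gene set name: %s", paste(dup, collapse = ", "))
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) {
    stop_data("empty gene set: %s",
              paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x)
  cat(sprintf("gene set collection: %d sets (sizes %d-%d, median %g)\n",
              length(x), min(sz), max(sz), stats::median(sz)))
  invisible(x)
}

#' Gene length table
#'
#' Maps gene identifiers to transcript/gene lengths in base pairs; required to
#' compute RPKM and TPM from raw counts.
#'
#' @param lengths Named numeric vector of lengths in bp (all >= 1).
#' @return Object of class `gene_length_table` (a named numeric vector).
#' @export
gene_length_table <- function(lengths) {
  nm <- names(lengths)
  if (is.null(nm) || any(nm == "") || anyNA(nm)) {
    stop_data("gene lengths must be a named vector")
  }
  if (anyDuplicated(nm)) {
    stop_data("duplicate gene identifier in lengths: %s",
              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  lengths <- as.numeric(lengths)
  names(lengths) <- nm
  if (any(!is.finite(lengths)) || any(lengths < 1)) {
    stop_data("gene lengths must be finite and >= 1 bp")
  }
  structure(lengths, class = "gene_length_table")
}
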