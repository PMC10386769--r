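# Delimited-text I/O for expression tables, gene lengths, group maps and GMT
# gene sets. All parsing is strict: ragged rows, duplicate identifiers and
# non-numeric cells are hard errors that name the offending entry. Lines
# starting with '#' are treated as comments (the CLI writes provenance
# headers in that form).

read_text_lines <- function(path) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines[!startsWith(lines, "#")]
}

#' Read a gene x sample expression table
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; every body cell must be numeric. The header may or may not
#' carry a corner label above the gene-id column. Lines starting with `#` are
#' skipped.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field delimiter (default tab; never auto-detected).
#' @param unit Declared unit of the values, one of [expression_units()].
#' @param strict_integer If `TRUE`, refuse non-integral values (counts from
#'   expectation-based quantifiers are fractional, so the default is lenient).
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, delimiter = "\t", unit = "counts",
                                  strict_integer = FALSE) {
  unit <- match.arg(unit, expression_units())
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop_data("expression table '%s' has no data rows", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]
  widths <- lengths(body)
  if (length(unique(widths)) != 1L) {
    stop_data("ragged rows in '%s': widths %s", path,
              paste(unique(widths), collapse = ", "))
  }
  ncol_body <- widths[1L] - 1L
  if (ncol_body < 1L) stop_data("expression table '%s' has no sample columns", path)
  # header either matches the body width (corner label present) or is one short
  if (length(header) == ncol_body + 1L) {
    samples <- header[-1L]
  } else if (length(header) == ncol_body) {
    samples <- header
  } else {
    stop_data("header of '%s' has %d fields but rows have %d",
              path, length(header), ncol_body + 1L)
  }
  genes <- vapply(body, `[`, character(1L), 1L)
  if (anyDuplicated(genes)) {
    stop_data("duplicate gene identifier in '%s': %s", path,
              paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  cells <- vapply(body, function(f) f[-1L], character(ncol_body))
  cells <- if (ncol_body == 1L) matrix(cells, nrow = 1L) else cells
  vals <- suppressWarnings(as.numeric(cells))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    # cells is samples x genes (vapply stacks per row); recover coordinates
    s_i <- (bad - 1L) %% ncol_body + 1L
    g_i <- (bad - 1L) %/% ncol_body + 1L
    stop_data("non-numeric cell '%s' at gene '%s', sample '%s' in '%s'",
              cells[bad], genes[g_i], samples[s_i], path)
  }
  m <- matrix(vals, nrow = ncol_body)  # samples x genes
  m <- t(m)
  if (unit != "log2" && any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop_data("negative value %g at gene '%s', sample '%s' in '%s'",
              m[bad[1L], bad[2L]], genes[bad[1L]], samples[bad[2L]], path)
  }
  if (strict_integer && any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)[1L, ]
    stop_data("non-integer value %g at gene '%s', sample '%s' with strict_integer",
              m[bad[1L], bad[2L]], genes[bad[1L]], samples[bad[2L]])
  }
  dimnames(m) <- list(genes, samples)
  expression_matrix(m, unit)
}

#' Write an expression table
#'
#' Serializes with full double precision so that
#' `read_expression_table(write_expression_table(x))` reproduces `x` exactly.
#'
#' @param matrix An [expression_matrix()].
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @param header_comments Optional character vector written as leading
#'   `#`-prefixed comment lines (used by the CLI for provenance).
#' @export
write_expression_table <- function(matrix, path, delimiter = "\t",
                                   header_comments = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"))
  vals <- em_values(matrix)
  body <- apply(vals, 1L, function(row) {
    paste(sprintf("%.17g", row), collapse = delimiter)
  })
  lines <- c(
    if (length(header_comments)) paste0("# ", header_comments),
    paste(c("gene_id", colnames(vals)), collapse = delimiter),
    paste(rownames(vals), body, sep = delimiter)
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_data("cannot write expression table to '%s'", path)
  invisible(NULL)
}

#' Read gene sets in GMT format
#'
#' One set per line, tab-separated: name, description, then member genes.
#' Duplicate members within a line are dropped; lines with no members are
#' skipped and counted in the `n_skipped` attribute (with a warning).
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()] with attribute `n_skipped`.
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_data("GMT file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[`, character(1L), 1L)
  if (anyDuplicated(nm)) {
    stop_data("duplicate gene set name in '%s': %s", path,
              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  desc <- vapply(fields, function(f) if (length(f) >= 2L) f[2L] else "", character(1L))
  members <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  keep <- lengths(members) > 0L
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    warning(sprintf("%d gene set(s) with no members skipped: %s", n_skipped,
                    paste(utils::head(nm[!keep], 5L), collapse = ", ")))
  }
  if (!any(keep)) stop_data("no non-empty gene sets in '%s'", path)
  out <- gene_set_collection(stats::setNames(members[keep], nm[keep]),
                             descriptions = desc[keep])
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write gene sets in GMT format
#'
#' @param sets A [gene_set_collection()].
#' @param path Output path.
#' @export
write_gene_sets_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(NULL)
}

#' Read a sample-to-group assignment table
#'
#' Two-column delimited text: sample identifier, group label. Order within
#' each group follows file order.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field delimiter (default tab).
#' @param header If `TRUE`, the first non-comment line is discarded.
#' @return A [sample_groups()] object.
#' @export
read_sample_groups <- function(path, delimiter = "\t", header = FALSE) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (header && length(lines)) lines <- lines[-1L]
  if (length(lines) == 0L) stop_data("group file '%s' has no assignments", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop_data("group file '%s' must have two columns (sample, group)", path)
  }
  smp <- vapply(fields, `[`, character(1L), 1L)
  grp <- vapply(fields, `[`, character(1L), 2L)
  if (anyDuplicated(smp)) {
    dup <- unique(smp[duplicated(smp)])
    stop_data("sample assigned to more than one group: %s",
              paste(dup, collapse = ", "))
  }
  sample_groups(split(smp, factor(grp, levels = unique(grp))))
}

#' Read a two-column gene length table
#'
#' @param path Path to delimited text: gene identifier, length in bp.
#' @param delimiter Field delimiter (default tab).
#' @param header If `TRUE`, the first non-comment line is discarded.
#' @return A [gene_length_table()].
#' @export
read_gene_lengths <- function(path, delimiter = "\t", header = FALSE) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (header && length(lines)) lines <- lines[-1L]
  if (length(lines) == 0L) stop_data("length file '%s' is empty", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop_data("length file '%s' must have two columns (gene, length)", path)
  }
  genes <- vapply(fields, `[`, character(1L), 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1L), 2L)))
  if (anyNA(len)) {
    stop_data("non-numeric length for gene '%s' in '%s'",
              genes[which(is.na(len))[1L]], path)
  }
  gene_length_table(stats::setNames(len, genes))
}

#' Cross-validate inputs against an expression matrix
#'
#' Checks that group samples resolve in the matrix (hard error otherwise,
#' since comparisons cannot proceed), and reports gene-set members and length
#' entries that do not match a matrix gene. Identifier matching is exact and
#' case-sensitive.
#'
#' @param matrix An [expression_matrix()].
#' @param groups A [sample_groups()] object.
#' @param sets Optional [gene_set_collection()].
#' @param lengths Optional [gene_length_table()].
#' @return A `validation_report`: list with `n_genes_matched`,
#'   `n_genes_unmatched`, `unmatched_examples` (at most 20), `warnings`.
#' @export
validate_against <- function(matrix, groups, sets = NULL, lengths = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(groups, "sample_groups"))
  missing_samples <- setdiff(unlist(groups, use.names = FALSE), sample_ids(matrix))
  if (length(missing_samples)) {
    stop_data("group sample(s) absent from matrix: %s",
              paste(utils::head(missing_samples, 10L), collapse = ", "))
  }
  queried <- character(0L)
  warnings <- character(0L)
  if (!is.null(sets)) {
    stopifnot(inherits(sets, "gene_set_collection"))
    queried <- c(queried, unlist(unclass(sets), use.names = FALSE))
  }
  if (!is.null(lengths)) {
    stopifnot(inherits(lengths, "gene_length_table"))
    queried <- c(queried, names(lengths))
    no_len <- setdiff(gene_ids(matrix), names(lengths))
    if (length(no_len)) {
      warnings <- c(warnings, sprintf(
        "%d matrix gene(s) without a length entry: %s", length(no_len),
        paste(utils::head(no_len, 20L), collapse = ", ")))
    }
  }
  queried <- unique(queried)
  matched <- intersect(queried, gene_ids(matrix))
  unmatched <- setdiff(queried, gene_ids(matrix))
  if (length(unmatched)) {
    warnings <- c(warnings, sprintf(
      "%d queried gene identifier(s) not in matrix", length(unmatched)))
  }
  structure(list(
    n_genes_matched = length(matched),
    n_genes_unmatched = length(unmatched),
    unmatched_examples = utils::head(unmatched, 20L),
    warnings = warnings
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation: %d gene ids matched, %d unmatched\n",
              x$n_genes_matched, x$n_genes_unmatched))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
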