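# Count normalization: CPM, RPKM/FPKM, TPM and the log2 transform.
#
# Library size is always the column sum of the supplied count matrix; the
# operations refuse non-count input so already-normalized values are never
# silently renormalized.

check_counts_input <- function(matrix, op) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (em_unit(matrix) != "counts") {
    stop_data("%s expects unit 'counts', got '%s' (refusing to renormalize)",
              op, em_unit(matrix))
  }
  libsize <- colSums(em_values(matrix))
  zero <- libsize == 0
  if (any(zero)) {
    stop_data("zero library size in sample(s): %s",
              paste(sample_ids(matrix)[zero], collapse = ", "))
  }
  libsize
}

match_lengths <- function(matrix, lengths) {
  stopifnot(inherits(lengths, "gene_length_table"))
  missing <- setdiff(gene_ids(matrix), names(lengths))
  if (length(missing)) {
    stop_data("no length for gene(s): %s%s",
              paste(utils::head(missing, 10L), collapse = ", "),
              if (length(missing) > 10L) sprintf(" (+%d more)", length(missing) - 10L) else "")
  }
  as.numeric(lengths[gene_ids(matrix)])
}

#' Counts per million
#'
#' `CPM(g, s) = counts(g, s) * 1e6 / libsize(s)` with library size the column
#' sum of the count matrix.
#'
#' @param matrix An [expression_matrix()] with unit `counts`.
#' @return An `expr_matrix` with unit `CPM`.
#' @export
cpm <- function(matrix) {
  libsize <- check_counts_input(matrix, "cpm")
  vals <- sweep(em_values(matrix), 2L, libsize, "/") * 1e6
  expression_matrix(vals, "CPM")
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM(g, s) = counts(g, s) * 1e9 / (libsize(s) * length(g))`. FPKM is the
#' same quantity under a fragment-based name; outputs are labelled RPKM.
#'
#' @param matrix An [expression_matrix()] with unit `counts`.
#' @param lengths A [gene_length_table()] covering every matrix gene.
#' @return An `expr_matrix` with unit `RPKM`.
#' @export
rpkm <- function(matrix, lengths) {
  libsize <- check_counts_input(matrix, "rpkm")
  len <- match_lengths(matrix, lengths)
  vals <- sweep(em_values(matrix) / len, 2L, libsize, "/") * 1e9
  expression_matrix(vals, "RPKM")
}

#' Transcripts per million
#'
#' Per-length read rates `counts(g, s) / length(g)` rescaled so every column
#' sums to 1e6. Equivalently, column-rescaled RPKM.
#'
#' @inheritParams rpkm
#' @return An `expr_matrix` with unit `TPM`.
#' @export
tpm <- function(matrix, lengths) {
  check_counts_input(matrix, "tpm")
  len <- match_lengths(matrix, lengths)
  rate <- em_values(matrix) / len
  denom <- colSums(rate)
  if (any(denom == 0)) {
    stop_data("all-zero counts in sample(s): %s",
              paste(sample_ids(matrix)[denom == 0], collapse = ", "))
  }
  vals <- sweep(rate, 2L, denom, "/") * 1e6
  expression_matrix(vals, "TPM")
}

#' Log2 transform with pseudocount
#'
#' `value <- log2(value + pseudocount)`; the resulting unit is `log2`.
#'
#' @param matrix An [expression_matrix()] in any non-log unit.
#' @param pseudocount Positive offset added before taking logs (default 1).
#' @return An `expr_matrix` with unit `log2`.
#' @export
log_transform <- function(matrix, pseudocount = 1) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (em_unit(matrix) == "log2") {
    stop_data("matrix is already log2-transformed")
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0) {
    stop_data("pseudocount must be a single positive number")
  }
  expression_matrix(log2(em_values(matrix) + pseudocount), "log2")
}
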