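#' Gene-by-array M-value matrix with design metadata
#'
#' Container for two-channel common-reference expression data: a matrix of
#' M-values (log2 of sample over common reference) with one column per
#' array, an optional matrix of A-values (average log2 intensity), and a
#' design table assigning each array to a time-point (in days) and a
#' replicate.
#'
#' @param M numeric matrix, genes in rows (rownames are gene ids), arrays
#'   in columns (colnames are array ids).
#' @param design data.frame with columns `array`, `time_point` (days,
#'   numeric) and `replicate`; one row per array.
#' @param A optional numeric matrix of A-values, same dimensions as `M`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `M`, `A` and `design`.
#' @export
expression_matrix <- function(M, design, A = NULL) {
  .assert(is.matrix(M) && is.numeric(M), "M must be a numeric matrix")
  .assert(!is.null(rownames(M)), "M must have gene ids as rownames")
  .assert(!anyDuplicated(rownames(M)), "duplicate gene ids in M")
  .assert(!is.null(colnames(M)), "M must have array ids as colnames")
  .assert(is.data.frame(design), "design must be a data.frame")
  .assert(all(c("array", "time_point", "replicate") %in% names(design)),
          "design needs columns array, time_point, replicate")
  .assert(all(colnames(M) %in% design$array),
          "every array id in M must be present in design")
  design <- design[match(colnames(M), design$array), , drop = FALSE]
  rownames(design) <- NULL
  if (!is.null(A)) {
    .assert(is.matrix(A) && all(dim(A) == dim(M)),
            "A must be a matrix with the same dimensions as M")
    dimnames(A) <- dimnames(M)
  }
  structure(list(M = M, A = A, design = design), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d arrays\n",
              nrow(x$M), ncol(x$M)))
  tp <- sort(unique(x$design$time_point))
  cat(sprintf("  time-points (d): %s\n", paste(tp, collapse = ", ")))
  cat(sprintf("  replicates: %d%s\n",
              length(unique(x$design$replicate)),
              if (is.null(x$A)) "  (no A-values)" else ""))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$M)

#' Subset an ExpressionMatrix by genes and/or arrays
#' @param x ExpressionMatrix.
#' @param genes character vector of gene ids (default all).
#' @param arrays character vector of array ids (default all).
#' @return ExpressionMatrix restricted to the requested rows/columns.
#' @export
subset_expression <- function(x, genes = rownames(x$M),
                              arrays = colnames(x$M)) {
  .assert(all(genes %in% rownames(x$M)), "unknown gene ids in subset")
  .assert(all(arrays %in% colnames(x$M)), "unknown array ids in subset")
  expression_matrix(x$M[genes, arrays, drop = FALSE], x$design,
                    A = if (is.null(x$A)) NULL
                        else x$A[genes, arrays, drop = FALSE])
}
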