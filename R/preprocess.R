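#' Background-correct a raw two-channel array set
#'
#' Subtracts the per-probe background estimate from the foreground in
#' each channel ("subtract" method).  Corrected values that are not
#' strictly positive cannot be log-transformed and are set to missing
#' for that probe/array rather than floored.
#'
#' @param raw a `RawArray` (see [generate_raw_two_channel()] for the
#'   structure).
#' @return the `RawArray` with elements `R` and `G` added: background-
#'   corrected intensities with non-positive values as `NA`.
#' @export
background_subtract <- function(raw) {
  .assert(inherits(raw, "RawArray"), "raw must be a RawArray")
  .assert(!is.null(raw$R_bg) && !is.null(raw$G_bg),
          "background intensities are missing")
  R <- raw$R_fg - raw$R_bg
  G <- raw$G_fg - raw$G_bg
  R[R <= 0] <- NA_real_
  G[G <= 0] <- NA_real_
  raw$R <- R
  raw$G <- G
  raw
}

#' Compute M and A values from corrected intensities
#'
#' `M = log2(R/G)`, `A = (log2(R) + log2(G)) / 2`; missing if either
#' channel is missing.
#'
#' @param raw background-corrected `RawArray` (after
#'   [background_subtract()]).
#' @return the `RawArray` with probe-by-array matrices `M` and `A`.
#' @export
compute_ma <- function(raw) {
  .assert(!is.null(raw$R) && !is.null(raw$G),
          "run background_subtract() first")
  raw$M <- log2(raw$R) - log2(raw$G)
  raw$A <- (log2(raw$R) + log2(raw$G)) / 2
  raw
}

#' Within-array loess normalization of M on A
#'
#' Removes intensity-dependent dye bias from one array by fitting a
#' locally weighted polynomial regression (tricube weights, robustifying
#' iterations) of M on A and returning the residuals.
#'
#' @param M numeric vector of M-values for one array.
#' @param A numeric vector of A-values, same length.
#' @param span loess span as a fraction of the data (default 0.3).
#' @param iterations robustifying iterations (default 4).
#' @return numeric vector `M - g(A)` where `g` is the loess fit;
#'   entries with missing M or A stay missing.
#' @export
normalize_within_loess <- function(M, A, span = 0.3, iterations = 4) {
  .assert(length(M) == length(A), "M and A must have equal length")
  ok <- is.finite(M) & is.finite(A)
  .assert(sum(ok) >= 50,
          "need at least 50 finite (M, A) pairs, got %d", sum(ok))
  fit <- limma::loessFit(M, A, span = span, iterations = iterations)
  M - fit$fitted
}

#' Between-array A-quantile normalization
#'
#' Quantile-normalizes the A-values across arrays (each quantile
#' replaced by the cross-array mean of that quantile, tied ranks
#' averaged); M-values are left untouched, which preserves within-array
#' log-ratios while making intensity distributions comparable.
#'
#' @param M probe-by-array matrix of M-values.
#' @param A probe-by-array matrix of A-values (same dimensions).
#' @return list `(M, A)` with normalized `A`.
#' @export
normalize_between_aquantile <- function(M, A) {
  .assert(is.matrix(A) && ncol(A) >= 2, "need at least 2 arrays")
  .assert(all(dim(M) == dim(A)),
          "M and A must cover the same probes and arrays")
  Aq <- limma::normalizeQuantiles(A, ties = TRUE)
  dimnames(Aq) <- dimnames(A)
  list(M = M, A = Aq)
}

#' Average probe-level values to gene level
#'
#' @param M probe-by-array matrix.
#' @param A probe-by-array matrix or NULL.
#' @param probe_gene character vector mapping each probe (row) to a
#'   gene id; `NA` rows (controls) are dropped.
#' @param design design data.frame (array, time_point, replicate).
#' @return [expression_matrix()] at gene level; a gene is missing on an
#'   array iff all of its probes are missing there.
#' @export
summarize_probes_to_genes <- function(M, A = NULL, probe_gene, design) {
  .assert(length(probe_gene) == nrow(M),
          "probe_gene must map every row of M")
  keep <- !is.na(probe_gene)
  .assert(any(keep), "no probes map to genes")
  gmean <- function(X) {
    X <- X[keep, , drop = FALSE]
    g <- probe_gene[keep]
    cnt <- rowsum((!is.na(X)) * 1, g)
    X0 <- X
    X0[is.na(X0)] <- 0
    out <- rowsum(X0, g) / cnt
    out[cnt == 0] <- NA_real_
    out
  }
  Mg <- gmean(M)
  Ag <- if (is.null(A)) NULL else gmean(A)
  expression_matrix(Mg, design, A = Ag)
}

#' Filter genes below the negative-control background
#'
#' Per array, the expression threshold is the median A-value of the
#' negative-control probes; a gene is retained iff its A-value exceeds
#' that threshold on at least `min_arrays` arrays.
#'
#' @param em [expression_matrix()] with A-values.
#' @param negctl_A matrix of negative-control A-values
#'   (control-probe rows x the same arrays as `em`).
#' @param min_arrays minimum number of arrays on which a gene must
#'   exceed background (default 1).
#' @return the filtered `ExpressionMatrix`; removed gene ids are
#'   attached as `attr(, "removed")`.
#' @export
filter_low_expression <- function(em, negctl_A, min_arrays = 1) {
  .assert(inherits(em, "ExpressionMatrix"), "em must be an ExpressionMatrix")
  .assert(!is.null(em$A), "em must carry A-values")
  .assert(is.matrix(negctl_A) && nrow(negctl_A) > 0,
          "no negative-control intensities supplied")
  .assert(ncol(negctl_A) == ncol(em$A),
          "negative controls must cover the same arrays")
  thr <- apply(negctl_A, 2, stats::median, na.rm = TRUE)
  above <- sweep(em$A, 2, thr, ">")
  above[is.na(above)] <- FALSE
  keep <- rowSums(above) >= min_arrays
  out <- subset_expression(em, genes = rownames(em$M)[keep])
  attr(out, "removed") <- rownames(em$M)[!keep]
  out
}

#' Full preprocessing pipeline for raw two-channel arrays
#'
#' Applies, in order: background subtraction (subtract method), M/A
#' computation, within-array loess normalization, between-array
#' A-quantile normalization, probe-to-gene averaging, and the
#' negative-control expression filter.
#'
#' @param raw a `RawArray`.
#' @param span loess span (default 0.3).
#' @param iterations loess robustifying iterations (default 4).
#' @param min_arrays quorum for the low-expression filter (default 1).
#' @return filtered gene-level [expression_matrix()] with M and A;
#'   removed genes in `attr(, "removed")`.
#' @export
preprocess_raw <- function(raw, span = 0.3, iterations = 4,
                           min_arrays = 1) {
  raw <- compute_ma(background_subtract(raw))
  for (j in seq_len(ncol(raw$M)))
    raw$M[, j] <- normalize_within_loess(raw$M[, j], raw$A[, j],
                                         span = span,
                                         iterations = iterations)
  nb <- normalize_between_aquantile(raw$M, raw$A)
  ctl <- raw$is_control
  em <- summarize_probes_to_genes(nb$M[!ctl, , drop = FALSE],
                                  nb$A[!ctl, , drop = FALSE],
                                  raw$gene[!ctl], raw$design)
  filter_low_expression(em, nb$A[ctl, , drop = FALSE],
                        min_arrays = min_arrays)
}
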