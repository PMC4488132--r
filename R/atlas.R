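#' Average atlas samples into tissue groups
#'
#' @param atlas gene x sample numeric matrix.
#' @param sample_groups named character vector mapping every sample
#'   (column) to a tissue-group label.
#' @param reducer summary function applied within a group (default
#'   `mean`).
#' @return gene x tissue-group matrix.
#' @export
group_atlas_samples <- function(atlas, sample_groups, reducer = mean) {
  .assert(is.matrix(atlas), "atlas must be a matrix")
  unmapped <- setdiff(colnames(atlas), names(sample_groups))
  .assert(length(unmapped) == 0, "unmapped atlas samples: %s",
          paste(utils::head(unmapped, 5), collapse = ", "))
  groups <- sample_groups[colnames(atlas)]
  out <- sapply(unique(groups), function(g)
    apply(atlas[, groups == g, drop = FALSE], 1, reducer))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(atlas),
                                     dimnames = list(rownames(atlas),
                                                     unique(groups)))
  out
}

#' Where each cluster's genes reach their expression extremes
#'
#' For each gene covered by the atlas, finds the tissue group with the
#' highest and the lowest expression, then reports per cluster the
#' percentage of its covered genes peaking (and bottoming) in each
#' tissue.  Genes absent from the atlas, and genes whose extreme value
#' is tied across tissues, are tallied separately and excluded from the
#' percentages.
#'
#' @param clusters a `ClusterAssignment` (or named integer vector
#'   gene -> cluster id).
#' @param atlas gene x tissue-group matrix.
#' @return object of class `TissueExtremeTable`: data.frame with one
#'   row per cluster x tissue (`cluster`, `tissue`, `pct_max`,
#'   `pct_min`), plus per-cluster tallies in `attr(, "counts")`
#'   (`n_genes`, `n_covered`, `n_absent`, `n_tied_max`, `n_tied_min`).
#' @export
map_extreme_tissue <- function(clusters, atlas) {
  cl <- if (inherits(clusters, "ClusterAssignment")) clusters$cluster
        else clusters
  .assert(!is.null(names(cl)), "clusters must be a named vector")
  .assert(is.matrix(atlas) && ncol(atlas) >= 2,
          "atlas needs at least two tissue groups")
  tissues <- colnames(atlas)
  cids <- sort(unique(cl))

  rows <- list()
  counts <- list()
  for (cc in cids) {
    genes <- names(cl)[cl == cc]
    covered <- intersect(genes, rownames(atlas))
    if (length(covered) == 0) {
      warning(sprintf("cluster %s has no atlas coverage", cc))
      counts[[as.character(cc)]] <-
        data.frame(cluster = cc, n_genes = length(genes), n_covered = 0,
                   n_absent = length(genes), n_tied_max = 0,
                   n_tied_min = 0)
      rows[[as.character(cc)]] <-
        data.frame(cluster = cc, tissue = tissues, pct_max = NA_real_,
                   pct_min = NA_real_)
      next
    }
    sub <- atlas[covered, , drop = FALSE]
    hi <- apply(sub, 1, function(v) {
      w <- which(v == max(v))
      if (length(w) > 1) NA_integer_ else w
    })
    lo <- apply(sub, 1, function(v) {
      w <- which(v == min(v))
      if (length(w) > 1) NA_integer_ else w
    })
    n_hi <- sum(!is.na(hi)); n_lo <- sum(!is.na(lo))
    pct_max <- if (n_hi > 0)
      100 * tabulate(hi[!is.na(hi)], ncol(atlas)) / n_hi else
        rep(NA_real_, ncol(atlas))
    pct_min <- if (n_lo > 0)
      100 * tabulate(lo[!is.na(lo)], ncol(atlas)) / n_lo else
        rep(NA_real_, ncol(atlas))
    rows[[as.character(cc)]] <-
      data.frame(cluster = cc, tissue = tissues, pct_max = pct_max,
                 pct_min = pct_min)
    counts[[as.character(cc)]] <-
      data.frame(cluster = cc, n_genes = length(genes),
                 n_covered = length(covered),
                 n_absent = length(genes) - length(covered),
                 n_tied_max = sum(is.na(hi)), n_tied_min = sum(is.na(lo)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "counts") <- do.call(rbind, counts)
  class(out) <- c("TissueExtremeTable", "data.frame")
  out
}
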