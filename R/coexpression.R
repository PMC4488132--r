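#' Z-scored mean expression profiles
#'
#' Averages M-values across replicates per time-point, then centres and
#' scales each gene's profile to mean 0 and SD 1 across time-points.
#' Genes with a constant profile (zero SD) cannot be scaled and are
#' dropped with a warning.
#'
#' @param em an [expression_matrix()].
#' @param genes character vector of gene ids to profile (typically the
#'   DEG list).
#' @return gene x time-point matrix of z-scores (class
#'   `ScaledProfileMatrix`); dropped constant-profile genes are listed
#'   in `attr(, "dropped")`.
#' @export
zscore_profiles <- function(em, genes) {
  .assert(inherits(em, "ExpressionMatrix"), "em must be an ExpressionMatrix")
  .assert(length(genes) > 0, "empty gene list")
  .assert(all(genes %in% rownames(em$M)),
          "genes missing from the expression matrix: %s",
          paste(utils::head(setdiff(genes, rownames(em$M)), 5),
                collapse = ", "))
  tp <- sort(unique(em$design$time_point))
  grp <- factor(em$design$time_point, levels = tp)
  M <- em$M[genes, , drop = FALSE]
  cnt <- t(rowsum(t((!is.na(M)) * 1), grp))
  M0 <- M
  M0[is.na(M0)] <- 0
  avg <- t(rowsum(t(M0), grp)) / cnt
  mu <- rowMeans(avg)
  sdv <- apply(avg, 1, stats::sd)
  keep <- is.finite(sdv) & sdv > 0
  if (any(!keep))
    warning(sprintf("%d constant-profile gene(s) dropped: %s",
                    sum(!keep),
                    paste(utils::head(genes[!keep], 5), collapse = ", ")))
  z <- (avg[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  dimnames(z) <- list(genes[keep], as.character(tp))
  attr(z, "dropped") <- genes[!keep]
  class(z) <- c("ScaledProfileMatrix", class(z))
  z
}

# k-means++ style seeding: first centre uniform, then each next centre
# with probability proportional to squared distance to the nearest
# chosen centre
.kmpp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k > 1L) {
    d2 <- rowSums((x - rep(centers[1L, ], each = n))^2)
    for (c in 2:k) {
      prob <- d2 / sum(d2)
      idx <- sample.int(n, 1L, prob = prob)
      centers[c, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums((x - rep(centers[c, ], each = n))^2))
    }
  }
  centers
}

#' K-means clustering of scaled profiles
#'
#' Euclidean k-means with k-means++ style seeding, keeping the best of
#' `n_init` restarts by total within-cluster sum of squares.  Cluster
#' labels are arbitrary; they are relabelled 1..k by descending cluster
#' size so output is stable for a fixed seed.
#'
#' @param scaled a `ScaledProfileMatrix` (or any numeric matrix of
#'   gene profiles).
#' @param k number of clusters (default 15).
#' @param seed RNG seed for the restarts.
#' @param n_init number of restarts (default 25).
#' @param iter_max maximum Lloyd/Hartigan-Wong iterations per restart.
#' @return object of class `ClusterAssignment`: list with `cluster`
#'   (named integer vector gene -> 1..k), `centers` (k x time-points),
#'   `k`, `bss_tss`, `tot_withinss`, `seed`, `n_init`.
#' @export
kmeans_cluster <- function(scaled, k = 15, seed = 1L, n_init = 25,
                           iter_max = 50) {
  x <- unclass(scaled)
  attr(x, "dropped") <- NULL
  .assert(is.matrix(x) && is.numeric(x), "scaled must be a numeric matrix")
  .assert(.is_count(k), "k must be a positive count")
  .assert(k <= nrow(x), "k (%d) exceeds the number of genes (%d)",
          k, nrow(x))
  best <- NULL
  .with_seed(seed, {
    for (r in seq_len(n_init)) {
      fit <- suppressWarnings(
        stats::kmeans(x, centers = .kmpp_centers(x, k),
                      iter.max = iter_max))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss)
        best <- fit
    }
  })
  # relabel by descending size (ties broken by old label)
  ord <- order(-tabulate(best$cluster, k), seq_len(k))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  cl <- relabel[best$cluster]
  names(cl) <- rownames(x)
  centers <- best$centers[ord, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  structure(list(cluster = cl, centers = centers, k = k,
                 bss_tss = best$betweenss / best$totss,
                 tot_withinss = best$tot.withinss,
                 seed = seed, n_init = n_init),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d genes in %d clusters (BSS/TSS = %.3f)\n",
              length(x$cluster), x$k, x$bss_tss))
  sz <- table(x$cluster)
  cat("  sizes:", paste(sz, collapse = ", "), "\n")
  invisible(x)
}

#' Elbow curve for choosing the number of clusters
#'
#' Computes the ratio of between-cluster to total sum of squares for
#' each k in `k_range` (best of `n_init` restarts each) and suggests
#' the k whose point on the curve is farthest (perpendicular distance)
#' from the chord joining the curve's endpoints.  The suggestion is
#' advisory; the choice of k remains with the analyst.
#'
#' @param scaled a `ScaledProfileMatrix`.
#' @param k_range integer vector of candidate k (default `2:20`).
#' @param seed RNG seed.
#' @param n_init restarts per k (default 10).
#' @return object of class `ElbowCurve`: data.frame `k`, `bss_tss`,
#'   with the suggested k in `attr(, "suggested_k")`.
#' @export
elbow_curve <- function(scaled, k_range = 2:20, seed = 1L, n_init = 10) {
  .assert(all(k_range >= 1) && all(k_range <= nrow(scaled)),
          "k_range must lie within [1, n genes]")
  k_range <- sort(unique(as.integer(k_range)))
  ratio <- vapply(k_range, function(k)
    kmeans_cluster(scaled, k, seed = seed + k, n_init = n_init)$bss_tss,
    0)
  # perpendicular distance from each point to the endpoint chord
  x1 <- k_range[1]; y1 <- ratio[1]
  x2 <- k_range[length(k_range)]; y2 <- ratio[length(ratio)]
  num <- abs((y2 - y1) * k_range - (x2 - x1) * ratio +
               x2 * y1 - y2 * x1)
  dist <- num / sqrt((y2 - y1)^2 + (x2 - x1)^2)
  out <- data.frame(k = k_range, bss_tss = ratio)
  attr(out, "suggested_k") <- k_range[which.max(dist)]
  class(out) <- c("ElbowCurve", "data.frame")
  out
}

#' @export
print.ElbowCurve <- function(x, ...) {
  cat(sprintf("ElbowCurve over k = %d..%d; suggested k = %d (advisory)\n",
              min(x$k), max(x$k), attr(x, "suggested_k")))
  invisible(as.data.frame(x))
}

#' Adjusted Rand index between two partitions
#'
#' Label-invariant agreement between a clustering and a reference
#' partition; 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b integer/factor vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  .assert(length(a) == length(b), "partitions must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
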