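#' Enumerate time-point pairs within a day window
#'
#' @param time_points sorted numeric time grid (days).
#' @param window_days maximum separation in days (inclusive).
#' @return data.frame `i`, `j` (indices into `time_points`, `i < j`),
#'   `time_i`, `time_j`.
#' @export
window_pairs <- function(time_points, window_days = 2.0) {
  .assert(window_days > 0, "window must be > 0 days")
  .assert(all(diff(time_points) > 0), "time grid must be increasing")
  idx <- which(outer(time_points, time_points,
                     function(a, b) b > a & b - a <= window_days),
               arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(i = integer(0), j = integer(0),
                      time_i = numeric(0), time_j = numeric(0)))
  ord <- order(idx[, 1], idx[, 2])
  data.frame(i = idx[ord, 1], j = idx[ord, 2],
             time_i = time_points[idx[ord, 1]],
             time_j = time_points[idx[ord, 2]])
}

#' All windowed contrasts between near-by time-points
#'
#' Tests, for every gene, every ordered pair of time-points separated
#' by at most `window_days` (default 2 days, inclusive), using the
#' moderated t-statistic
#' `t = (coef_j - coef_i) / (s~_g sqrt(1/n_i + 1/n_j))` with
#' `d_g + d0` degrees of freedom.  By default all gene-by-contrast
#' p-values are pooled into a single Benjamini-Hochberg adjustment
#' across the experiment; `pool = "per_contrast"` adjusts each contrast
#' separately instead.
#'
#' @param mfit a `ModeratedFit`.
#' @param window_days contrast window in days (default 2).
#' @param pool `"global"` (default) or `"per_contrast"` FDR pooling.
#' @return object of class `ContrastTable`: data.frame with columns
#'   `gene`, `time_i`, `time_j`, `log2fc` (`coef_j - coef_i`), `t`,
#'   `p`, `p_adj`.
#' @export
windowed_contrasts <- function(mfit, window_days = 2.0,
                               pool = c("global", "per_contrast")) {
  .assert(inherits(mfit, "ModeratedFit"), "mfit must be a ModeratedFit")
  pool <- match.arg(pool)
  pairs <- window_pairs(mfit$time_points, window_days)
  ok <- mfit$testable & is.finite(mfit$s2_post) & mfit$s2_post > 0
  genes <- rownames(mfit$coef)[ok]
  coef <- mfit$coef[ok, , drop = FALSE]
  nrep <- mfit$n_obs[ok, , drop = FALSE]
  s_post <- sqrt(mfit$s2_post[ok])
  df <- mfit$df[ok] + mfit$d0

  out <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    lfc <- coef[, j] - coef[, i]
    se <- s_post * sqrt(1 / nrep[, i] + 1 / nrep[, j])
    tstat <- lfc / se
    p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
    out[[r]] <- data.frame(gene = genes,
                           time_i = pairs$time_i[r],
                           time_j = pairs$time_j[r],
                           log2fc = lfc, t = tstat, p = p,
                           row.names = NULL)
  }
  ct <- do.call(rbind, out)
  if (is.null(ct)) {
    ct <- data.frame(gene = character(0), time_i = numeric(0),
                     time_j = numeric(0), log2fc = numeric(0),
                     t = numeric(0), p = numeric(0),
                     p_adj = numeric(0))
  } else if (pool == "global") {
    ct$p_adj <- adjust_pvalues(ct$p, "BH")
  } else {
    key <- paste(ct$time_i, ct$time_j)
    ct$p_adj <- stats::ave(ct$p, key,
                           FUN = function(p) adjust_pvalues(p, "BH"))
  }
  ct <- ct[!is.na(ct$p), , drop = FALSE]
  rownames(ct) <- NULL
  class(ct) <- c("ContrastTable", "data.frame")
  attr(ct, "window_days") <- window_days
  ct
}

#' Call differentially expressed genes from windowed contrasts
#'
#' A gene is differentially expressed iff at least one windowed
#' contrast has adjusted p below `alpha` and an absolute fold change of
#' `fc_min` or greater (threshold inclusive).  The reported best
#' contrast is the one with the smallest adjusted p among qualifying
#' contrasts (largest |log2 FC| as tie-break), and the direction is the
#' sign of its log2 FC.
#'
#' @param ct a `ContrastTable`.
#' @param alpha adjusted-p threshold (default 0.01, strict).
#' @param fc_min minimum fold change on the linear scale (default 1.7,
#'   inclusive).
#' @return object of class `DEGTable`: data.frame per gene with
#'   `gene`, `best_time_i`, `best_time_j`, `direction`, `max_abs_log2fc`,
#'   `min_p_adj`, `deg`.
#' @export
call_degs <- function(ct, alpha = 0.01, fc_min = 1.7) {
  .assert(inherits(ct, "ContrastTable") || is.data.frame(ct),
          "ct must be a ContrastTable")
  .assert(alpha > 0 && alpha <= 1, "alpha must be in (0, 1]")
  .assert(fc_min >= 1, "fc_min must be >= 1 (linear scale)")
  lfc_min <- log2(fc_min)
  hit <- ct$p_adj < alpha & abs(ct$log2fc) >= lfc_min

  sp <- split(seq_len(nrow(ct)), ct$gene)
  res <- lapply(names(sp), function(g) {
    rows <- sp[[g]]
    qual <- rows[hit[rows]]
    pick <- if (length(qual)) {
      qual[order(ct$p_adj[qual], -abs(ct$log2fc[qual]))[1]]
    } else {
      rows[order(ct$p_adj[rows], -abs(ct$log2fc[rows]))[1]]
    }
    data.frame(gene = g,
               best_time_i = ct$time_i[pick],
               best_time_j = ct$time_j[pick],
               direction = if (length(qual) == 0) NA_character_
                           else if (ct$log2fc[pick] > 0) "up" else "down",
               max_abs_log2fc = max(abs(ct$log2fc[rows])),
               min_p_adj = min(ct$p_adj[rows]),
               deg = length(qual) > 0,
               row.names = NULL)
  })
  out <- do.call(rbind, res)
  class(out) <- c("DEGTable", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "fc_min") <- fc_min
  out
}

#' @export
print.DEGTable <- function(x, ...) {
  cat(sprintf("DEGTable: %d of %d genes called DE (alpha = %g, FC >= %g)\n",
              sum(x$deg), nrow(x), attr(x, "alpha"), attr(x, "fc_min")))
  invisible(as.data.frame(x))
}

#' Step-up false-discovery-rate adjustment
#'
#' Benjamini-Hochberg (`"BH"`) or Benjamini-Yekutieli (`"BY"`) step-up
#' adjusted p-values, clipped at 1; BY multiplies by
#' `c(n) = sum(1/i, i = 1..n)` and is valid under arbitrary dependence.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"BY"`.
#' @return adjusted p-values in the original order.
#' @export
adjust_pvalues <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  .assert(all(is.na(p) | (p >= 0 & p <= 1)),
          "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}
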