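#' Assign binding peaks to genes through a strand-aware window
#'
#' A gene is bound iff some peak overlaps its regulatory window: the
#' transcribed region extended `upstream` bp on the promoter side and
#' `downstream` bp past the 3' end (default -3 kb / +1 kb).  On the
#' `-` strand upstream is to the right.  All coordinates are 0-based
#' half-open (BED dialect); windows are clipped at zero.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param genes data.frame with columns `gene`, `chrom`, `start`,
#'   `end`, `strand` (`+`/`-`).
#' @param upstream window size upstream of the transcribed region
#'   (default 3000).
#' @param downstream window size downstream (default 1000).
#' @return character vector of bound gene ids (a gene set); a peak may
#'   annotate several genes.
#' @export
assign_peaks_to_genes <- function(peaks, genes, upstream = 3000,
                                  downstream = 1000) {
  .assert(all(c("chrom", "start", "end") %in% names(peaks)),
          "peaks need chrom/start/end columns")
  .assert(all(c("gene", "chrom", "start", "end", "strand") %in%
                names(genes)), "genes need gene/chrom/start/end/strand")
  bad <- which(!(peaks$start >= 0 & peaks$start < peaks$end))
  .assert(length(bad) == 0, "malformed peak interval at line %d",
          if (length(bad)) bad[1] else 0L)
  bad <- which(!(genes$start < genes$end & genes$strand %in% c("+", "-")))
  .assert(length(bad) == 0, "malformed gene model at line %d",
          if (length(bad)) bad[1] else 0L)

  win_start <- ifelse(genes$strand == "+", genes$start - upstream,
                      genes$start - downstream)
  win_end <- ifelse(genes$strand == "+", genes$end + downstream,
                    genes$end + upstream)
  win_start <- pmax(win_start, 0)
  # 0-based half-open -> IRanges 1-based closed
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(win_start + 1, win_end))
  p <- GenomicRanges::GRanges(peaks$chrom,
                              IRanges::IRanges(peaks$start + 1,
                                               peaks$end))
  bound <- GenomicRanges::countOverlaps(g, p) > 0
  sort(unique(genes$gene[bound]))
}

#' Resampling-based gene-set enrichment of clusters
#'
#' Compares each cluster's annotated-gene fraction to the distribution
#' obtained from equally sized random gene sets drawn (without
#' replacement) from a background universe.  A cluster is significant
#' when its observed fraction lies beyond `sd_mult` standard deviations
#' (default 3) of the resampled mean; the sign gives the direction
#' (enriched vs depleted).  Degenerate nulls (zero resampling SD) are
#' flagged and never significant.
#'
#' @param clusters a `ClusterAssignment` or named vector
#'   gene -> cluster id.
#' @param annot character vector: the annotated gene set.
#' @param universe character vector of background genes to resample
#'   from (e.g. the DEG list, or all genes on the array).
#' @param n_iter number of random sets per cluster (default 100).
#' @param seed RNG seed.
#' @param sd_mult significance multiple of the null SD (default 3).
#' @param background_label label recorded for the universe used.
#' @return object of class `EnrichmentResult`: data.frame per cluster
#'   with `cluster`, `n`, `p_obs`, `null_mean`, `null_sd`, `z`,
#'   `direction`, `significant`, `degenerate`, and metadata attributes
#'   (`n_iter`, `seed`, `sd_mult`, `background`).
#' @export
resampling_set_enrichment <- function(clusters, annot, universe,
                                      n_iter = 100, seed = 1L,
                                      sd_mult = 3,
                                      background_label = "universe") {
  cl <- if (inherits(clusters, "ClusterAssignment")) clusters$cluster
        else clusters
  .assert(!is.null(names(cl)), "clusters must be a named vector")
  .assert(n_iter >= 2, "n_iter must be >= 2")
  universe <- unique(universe)
  annot <- unique(annot)
  missing <- setdiff(names(cl), universe)
  .assert(length(missing) == 0,
          "cluster genes outside the universe: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  annot_in <- intersect(annot, universe)
  is_annot <- universe %in% annot_in
  cids <- sort(unique(cl))
  .assert(max(table(cl)) <= length(universe),
          "a cluster is larger than the universe")

  res <- .with_seed(seed, {
    lapply(cids, function(cc) {
      genes <- names(cl)[cl == cc]
      n_c <- length(genes)
      p_obs <- mean(genes %in% annot_in)
      draws <- vapply(seq_len(n_iter), function(i)
        mean(is_annot[sample.int(length(universe), n_c)]), 0)
      mu <- mean(draws)
      sdv <- stats::sd(draws)
      z <- if (sdv > 0) (p_obs - mu) / sdv else NA_real_
      data.frame(cluster = cc, n = n_c, p_obs = p_obs, null_mean = mu,
                 null_sd = sdv, z = z,
                 direction = if (p_obs >= mu) "enriched" else "depleted",
                 significant = sdv > 0 && abs(p_obs - mu) > sd_mult * sdv,
                 degenerate = sdv == 0, row.names = NULL)
    })
  })
  out <- do.call(rbind, res)
  attr(out, "n_iter") <- n_iter
  attr(out, "seed") <- seed
  attr(out, "sd_mult") <- sd_mult
  attr(out, "background") <- background_label
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "EnrichmentResult vs '%s' (%d random sets, %g-SD rule): %d/%d flagged\n",
    attr(x, "background"), attr(x, "n_iter"), attr(x, "sd_mult"),
    sum(x$significant), nrow(x)))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Fisher exact term enrichment with Benjamini-Yekutieli correction
#'
#' One-sided (enrichment) Fisher exact test per term on the 2x2 table
#' of cluster membership vs term annotation within the universe, with
#' Benjamini-Yekutieli adjustment across terms (valid under arbitrary
#' dependence between overlapping terms).
#'
#' @param cluster_genes character vector (must lie in `universe`).
#' @param universe background gene ids.
#' @param term_map named list term -> member gene ids; members are
#'   intersected with the universe first, and terms with no universe
#'   members are skipped and reported.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param alternative `"greater"` (enrichment, default) or
#'   `"two.sided"`.
#' @return data.frame per term: `term`, `n_cluster`, `n_term`,
#'   `overlap`, `odds_ratio` (conditional MLE), `p`, `p_adj`,
#'   `significant`; skipped terms in `attr(, "skipped")`.
#' @export
go_enrichment <- function(cluster_genes, universe, term_map,
                          alpha = 0.05,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  cluster_genes <- unique(cluster_genes)
  .assert(all(cluster_genes %in% universe),
          "cluster genes must be a subset of the universe")
  terms <- names(term_map)
  sizes <- vapply(term_map, function(g)
    length(intersect(g, universe)), 0L)
  skipped <- terms[sizes == 0]
  terms <- terms[sizes > 0]
  n_u <- length(universe)
  n_c <- length(cluster_genes)
  res <- lapply(terms, function(tm) {
    tg <- intersect(term_map[[tm]], universe)
    a <- length(intersect(cluster_genes, tg))
    b <- n_c - a
    cc <- length(tg) - a
    d <- n_u - n_c - cc
    ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2),
                             alternative = alternative)
    data.frame(term = tm, n_cluster = n_c, n_term = length(tg),
               overlap = a, odds_ratio = unname(ft$estimate),
               p = ft$p.value, row.names = NULL)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(term = character(0), n_cluster = integer(0),
                      n_term = integer(0), overlap = integer(0),
                      odds_ratio = numeric(0), p = numeric(0))
  out$p_adj <- adjust_pvalues(out$p, "BY")
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Hypergeometric overlap test between two gene lists
#'
#' Upper-tail hypergeometric probability of observing at least the
#' realized overlap between two gene lists drawn from a common
#' universe.
#'
#' @param list_a,list_b character vectors (subsets of `universe`).
#' @param universe background gene ids.
#' @return list with `overlap`, `expected` (`|A||B|/|U|`) and `p`
#'   (`P(X >= overlap)`).
#' @export
list_overlap_test <- function(list_a, list_b, universe) {
  universe <- unique(universe)
  .assert(length(universe) > 0, "empty universe")
  list_a <- unique(list_a)
  list_b <- unique(list_b)
  .assert(all(list_a %in% universe) && all(list_b %in% universe),
          "both lists must be subsets of the universe")
  k <- length(intersect(list_a, list_b))
  n_u <- length(universe)
  p <- stats::phyper(k - 1, length(list_a), n_u - length(list_a),
                     length(list_b), lower.tail = FALSE)
  list(overlap = k,
       expected = length(list_a) * length(list_b) / n_u,
       p = p)
}
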