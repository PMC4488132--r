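#' Scoring scheme for local protein alignment
#'
#' Substitution matrix, affine gap penalties (a gap of length L costs
#' `gap_open + L * gap_extend`), and Karlin-Altschul parameters for the
#' E-value model.  Defaults are BLOSUM62 with gap open 11 / extend 1
#' and the standard published gapped constants lambda = 0.267,
#' K = 0.041 for that scheme.
#'
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend positive gap penalties.
#' @param lambda,K Karlin-Altschul parameters (> 0).
#' @return list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, lambda = 0.267, K = 0.041) {
  .assert(gap_open > 0 && gap_extend > 0, "gap penalties must be > 0")
  .assert(lambda > 0 && K > 0, "lambda and K must be > 0")
  mat <- .load_submatrix(matrix)
  structure(list(matrix_name = matrix, matrix = mat,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

.load_submatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

.check_protein <- function(seq, label = "sequence") {
  .assert(nchar(seq) > 0, "%s is empty", label)
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!res %in% .AA)
  .assert(length(bad) == 0, "invalid residue '%s' at position %d of %s",
          if (length(bad)) res[bad[1]] else "",
          if (length(bad)) bad[1] else 0L, label)
  invisible(TRUE)
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment with affine gaps under the given
#' scoring scheme.  Query coverage is the contiguous span of the query
#' inside the local alignment divided by the query length; an empty
#' optimal alignment (all pair scores negative) has score 0 and
#' coverage 0.
#'
#' @param query,subject amino-acid sequences (single strings, 20-letter
#'   alphabet).
#' @param scheme a [scoring_scheme()].
#' @return list: `score`, `query_start`, `query_end` (1-based,
#'   inclusive; 0/0 for an empty alignment), `coverage`.
#' @export
local_align <- function(query, subject, scheme = scoring_scheme()) {
  .check_protein(query, "query")
  .check_protein(subject, "subject")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  sc <- Biostrings::score(aln)
  if (sc <= 0)
    return(list(score = 0, query_start = 0L, query_end = 0L,
                coverage = 0))
  qs <- Biostrings::start(Biostrings::pattern(aln))
  qe <- Biostrings::end(Biostrings::pattern(aln))
  list(score = sc, query_start = qs, query_end = qe,
       coverage = (qe - qs + 1) / nchar(query))
}

#' Karlin-Altschul E-value of an alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length and
#' `n` the total number of database residues.
#'
#' @param score raw alignment score (>= 0).
#' @param query_len query length in residues.
#' @param db_residues total residues in the searched database.
#' @param scheme a [scoring_scheme()] supplying `lambda` and `K`.
#' @return the E-value.
#' @export
hit_evalue <- function(score, query_len, db_residues,
                       scheme = scoring_scheme()) {
  .assert(all(score >= 0), "score must be >= 0")
  scheme$K * query_len * db_residues * exp(-scheme$lambda * score)
}

# Exact k-mer seeding prefilter (the word-seeding idea of BLAST-style
# search): an inverted index from k-words to sequences; candidate
# pairs must share at least `min_words` distinct words.  Alignments
# strong enough to reach stringent E-value cutoffs contain long
# near-identical stretches and are retained with near-certainty.
.kmer_sets <- function(seqs, k) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  })
}

.kmer_candidates <- function(kmers, min_words = 2L) {
  seq_of <- rep(seq_along(kmers), lengths(kmers))
  words <- unlist(kmers, use.names = FALSE)
  uw <- unique(words)
  code <- match(words, uw)
  posting <- split(seq_of, factor(code, levels = seq_along(uw)))
  codes_by_seq <- split(code, seq_of)
  lapply(seq_along(kmers), function(qi) {
    kk <- codes_by_seq[[as.character(qi)]]
    if (is.null(kk)) return(integer(0))
    post <- unlist(posting[kk], use.names = FALSE)
    counts <- tabulate(post, length(kmers))
    counts[qi] <- 0L
    which(counts >= min_words)
  })
}

#' All-vs-all paralog identification in a proteome
#'
#' Aligns every protein locally against every other, converts scores to
#' E-values, keeps hits with `E <= e_max` and query coverage
#' `>= cov_min`, and retains per query the `top_n` hits with the
#' smallest E-values (self-hits excluded; duplicate subjects collapsed
#' to their best hit).  The per-gene paralog list is directional: A may
#' list B without B listing A.  An exact-k-mer seeding prefilter
#' (candidate pairs must share a length-`seed_k` word) skips pairs that
#' cannot plausibly reach the E-value cutoff; set `seed_k = 0` for an
#' exhaustive scan.
#'
#' @param proteome named character vector gene -> amino-acid sequence.
#' @param scheme a [scoring_scheme()].
#' @param e_max E-value cutoff (default 1e-20).
#' @param cov_min minimum query coverage (default 0.80).
#' @param top_n hits retained per query (default 5).
#' @param seed_k word length of the seeding prefilter (default 5;
#'   0 = no prefilter).
#' @param seed_min_words minimum number of distinct shared words for a
#'   pair to be aligned (default 2).
#' @return object of class `ParalogMap`: list with `hits` (named list
#'   per query of data.frames `subject`, `score`, `coverage`,
#'   `evalue`, sorted by ascending E-value) and `genes_with_paralogs`
#'   (flat character vector of queries retaining >= 1 hit).
#' @export
find_paralogs <- function(proteome, scheme = scoring_scheme(),
                          e_max = 1e-20, cov_min = 0.80, top_n = 5,
                          seed_k = 5, seed_min_words = 2L) {
  .assert(length(proteome) >= 2, "need at least two sequences")
  .assert(!is.null(names(proteome)) && !anyDuplicated(names(proteome)),
          "proteome must have unique gene names")
  for (g in names(proteome)) .check_protein(proteome[[g]], g)
  genes <- names(proteome)
  db_res <- sum(nchar(proteome))
  subj_set <- Biostrings::AAStringSet(proteome)

  ## candidate unordered pairs (i < j); one alignment per pair serves
  ## both query directions since the raw score is symmetric
  if (seed_k > 0) {
    cand_list <- .kmer_candidates(.kmer_sets(proteome, seed_k),
                                  seed_min_words)
    pi <- rep(seq_along(genes), lengths(cand_list))
    pj <- unlist(cand_list, use.names = FALSE)
    keep <- pi < pj
    pi <- pi[keep]; pj <- pj[keep]
  } else {
    idx <- which(upper.tri(matrix(0, length(genes), length(genes))),
                 arr.ind = TRUE)
    pi <- idx[, 1]; pj <- idx[, 2]
  }

  lens <- nchar(proteome)
  hits <- stats::setNames(
    rep(list(data.frame(subject = character(0), score = numeric(0),
                        coverage = numeric(0), evalue = numeric(0))),
        length(genes)), genes)
  if (length(pi)) {
    aln <- Biostrings::pairwiseAlignment(
      subj_set[pi], subj_set[pj], type = "local",
      substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
    sc <- Biostrings::score(aln)
    span_i <- Biostrings::end(Biostrings::pattern(aln)) -
      Biostrings::start(Biostrings::pattern(aln)) + 1
    span_j <- Biostrings::end(Biostrings::subject(aln)) -
      Biostrings::start(Biostrings::subject(aln)) + 1
    pos <- sc > 0
    # both directions of every pair, each with its own query length
    long <- data.frame(
      query = c(pi, pj), subject = c(pj, pi),
      score = pmax(c(sc, sc), 0),
      coverage = ifelse(c(pos, pos),
                        c(span_i, span_j) / lens[c(pi, pj)], 0))
    long$evalue <- hit_evalue(long$score, lens[long$query], db_res,
                              scheme)
    long <- long[long$score > 0 & long$evalue <= e_max &
                   long$coverage >= cov_min, , drop = FALSE]
    for (qi in unique(long$query)) {
      df <- long[long$query == qi, c("subject", "score", "coverage",
                                     "evalue"), drop = FALSE]
      df$subject <- genes[df$subject]
      df <- df[order(df$evalue, -df$score), , drop = FALSE]
      df <- df[!duplicated(df$subject), , drop = FALSE]
      hits[[genes[qi]]] <- utils::head(df, top_n)
      rownames(hits[[genes[qi]]]) <- NULL
    }
  }
  structure(list(hits = hits,
                 genes_with_paralogs =
                   genes[vapply(hits, nrow, 0L) > 0],
                 e_max = e_max, cov_min = cov_min, top_n = top_n),
            class = "ParalogMap")
}

#' @export
print.ParalogMap <- function(x, ...) {
  cat(sprintf(
    "ParalogMap: %d/%d genes with >= 1 paralog (E <= %g, cov >= %g, top %d)\n",
    length(x$genes_with_paralogs), length(x$hits), x$e_max, x$cov_min,
    x$top_n))
  invisible(x)
}
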