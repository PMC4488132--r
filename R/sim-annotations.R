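#' Specify planted annotation enrichments
#'
#' Describes, per annotation layer, which planted clusters are enriched
#' and at what odds ratio.  The defaults plant two transcription-factor
#' binding layers, a paralog layer concentrated in the early/
#' intermediate clusters, three enriched functional terms plus a set of
#' unenriched decoy terms, and one designated peak tissue per cluster in
#' the atlas.
#'
#' @param n_clusters number of planted clusters in the truth table.
#' @param binding list of binding layers, each
#'   `list(tf =, target_clusters =, odds_ratio =, background_rate =)`.
#' @param paralog single layer `list(target_clusters =, odds_ratio =,
#'   background_rate =, identity =, family_size =)` where `family_size`
#'   is the inclusive range of paralog-family sizes and `identity` the
#'   expected pairwise sequence identity within a family.
#' @param terms list of planted term layers (same shape as binding but
#'   with a `term` label); decoy terms are added on top.
#' @param n_decoy_terms number of unplanted terms with random
#'   annotation rates.
#' @param tissues tissue-group labels of the synthetic atlas.
#' @param cluster_tissue integer-named character vector mapping planted
#'   cluster id to its designated peak tissue; defaults to cycling
#'   `tissues` over `1:n_clusters`.
#' @return list of class `enrich_spec`.
#' @export
enrich_spec <- function(n_clusters = 15,
                        binding = list(
                          list(tf = "TF1",
                               target_clusters = 1:min(3, n_clusters),
                               odds_ratio = 4, background_rate = 0.10),
                          list(tf = "TF2",
                               target_clusters =
                                 unique(pmin(4:6, n_clusters)),
                               odds_ratio = 4, background_rate = 0.10)),
                        paralog = list(
                          target_clusters =
                            unique(pmin(c(5, 11, 12, 15), n_clusters)),
                          odds_ratio = 4, background_rate = 0.15,
                          identity = 0.9, family_size = c(2, 4)),
                        terms = list(
                          list(term = "TERM:0001",
                               target_clusters = 1,
                               odds_ratio = 6, background_rate = 0.05),
                          list(term = "TERM:0002",
                               target_clusters = min(2, n_clusters),
                               odds_ratio = 6, background_rate = 0.05),
                          list(term = "TERM:0003",
                               target_clusters = min(3, n_clusters),
                               odds_ratio = 6, background_rate = 0.05)),
                        n_decoy_terms = 12,
                        tissues = c("meristem", "sepal", "petal",
                                    "stamen", "carpel", "pollen",
                                    "ovule", "leaf", "root", "seedling"),
                        cluster_tissue = NULL) {
  if (is.null(cluster_tissue)) {
    cluster_tissue <- rep_len(tissues, n_clusters)
    names(cluster_tissue) <- as.character(seq_len(n_clusters))
  }
  structure(list(n_clusters = n_clusters, binding = binding,
                 paralog = paralog, terms = terms,
                 n_decoy_terms = n_decoy_terms, tissues = tissues,
                 cluster_tissue = cluster_tissue),
            class = "enrich_spec")
}

# Draw an annotation flag per gene so that the annotated fraction in the
# target clusters has the requested odds ratio against the background
# rate (exact counts, random membership).
.plant_layer <- function(truth, target_clusters, odds_ratio,
                         background_rate, layer) {
  p0 <- background_rate
  .assert(odds_ratio > 0, "layer '%s': odds ratio must be > 0", layer)
  .assert(p0 > 0 && p0 < 1,
          "layer '%s': background rate must be in (0, 1)", layer)
  o1 <- odds_ratio * p0 / (1 - p0)
  p1 <- o1 / (1 + o1)
  in_target <- !is.na(truth$cluster) & truth$cluster %in% target_clusters
  n1 <- sum(in_target)
  n0 <- sum(!in_target)
  .assert(n1 > 0, "layer '%s': no genes in target clusters", layer)
  k1 <- round(p1 * n1)
  k0 <- round(p0 * n0)
  .assert(!(odds_ratio > 1 && k1 == 0),
          "layer '%s': requested odds ratio infeasible for cluster size %d",
          layer, n1)
  flag <- logical(nrow(truth))
  flag[sample(which(in_target), k1)] <- TRUE
  flag[sample(which(!in_target), k0)] <- TRUE
  flag
}

.AA <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
         "S","T","W","Y","V")

.random_protein <- function(len) paste(sample(.AA, len, replace = TRUE),
                                       collapse = "")

# i.i.d. substitution at rate (1 - identity); substitutions always
# change the residue
.mutate_protein <- function(seq, identity) {
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(res)) > identity
  if (any(hit))
    res[hit] <- vapply(res[hit],
                       function(a) sample(setdiff(.AA, a), 1L), "")
  paste(res, collapse = "")
}

#' Generate the annotation layers of the synthetic study
#'
#' Produces, from a simulated time course's truth table, every external
#' dataset the downstream stages consume: a tissue atlas whose planted
#' clusters peak in designated tissues, transcription-factor binding
#' peaks with matching gene models laid out on synthetic chromosomes,
#' functional-term annotations, and a proteome in which paralog
#' families are mutated copies of a common ancestral sequence.
#' Enriched layers are planted at exact counts so the realized odds
#' ratio matches the request up to rounding.
#'
#' @param config the [sim_config()] of the study.
#' @param truth truth table from [generate_timecourse()].
#' @param spec an [enrich_spec()]; its `n_clusters` should equal
#'   `config$n_archetypes`.
#' @return list of class `AnnotationBundle`:
#'   \describe{
#'     \item{atlas}{gene x tissue matrix.}
#'     \item{peaks}{named list (per TF) of BED-like data.frames
#'       (`chrom`, `start`, `end`, `name`, `score`, `strand`),
#'       0-based half-open.}
#'     \item{gene_models}{data.frame `gene`, `chrom`, `start`, `end`
#'       (0-based half-open transcribed region), `strand`.}
#'     \item{term_map}{named list term -> member gene ids.}
#'     \item{proteome}{named character vector gene -> amino-acid
#'       sequence.}
#'     \item{bound}{named list (per TF) of truly bound gene ids.}
#'     \item{paralog_families}{list of gene-id vectors partitioning the
#'       genes planted with paralogs.}
#'     \item{truth}{the input truth table augmented with per-layer
#'       flags (`bound_<tf>`, `has_paralog`, `paralog_family`,
#'       `peak_tissue`).}
#'   }
#' @export
generate_annotations <- function(config, truth,
                                 spec = enrich_spec(config$n_archetypes)) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  .assert(inherits(spec, "enrich_spec"), "spec must be an enrich_spec")
  seeds <- .layer_seeds(config$seed)
  genes <- truth$gene
  ng <- length(genes)

  .with_seed(seeds[["annotations"]], {
    ## gene models on 5 synthetic chromosomes: 2 kb transcribed regions
    ## spaced 20 kb apart so regulatory windows never overlap
    chrom <- paste0("Chr", (seq_len(ng) - 1L) %% 5L + 1L)
    idx_on_chrom <- ave(seq_len(ng), chrom, FUN = seq_along)
    start <- (idx_on_chrom - 1L) * 20000L + 5000L
    gene_models <- data.frame(gene = genes, chrom = chrom,
                              start = start, end = start + 2000L,
                              strand = sample(c("+", "-"), ng,
                                              replace = TRUE))

    ## binding layers: planted bound sets plus a peak inside each bound
    ## gene's regulatory window (-3 kb upstream / +1 kb downstream)
    bound <- list()
    peaks <- list()
    for (b in spec$binding) {
      flag <- .plant_layer(truth, b$target_clusters, b$odds_ratio,
                           b$background_rate, paste0("binding:", b$tf))
      bound[[b$tf]] <- genes[flag]
      gm <- gene_models[flag, , drop = FALSE]
      width <- 200L
      # offset of the peak start relative to the upstream window edge
      off <- floor(stats::runif(nrow(gm)) * (3000 + 2000 + 1000 - width))
      pk_start <- ifelse(gm$strand == "+", gm$start - 3000L + off,
                         gm$start - 1000L + off)
      pk_start <- pmax(pk_start, 0L)
      peaks[[b$tf]] <- data.frame(
        chrom = gm$chrom, start = as.integer(pk_start),
        end = as.integer(pk_start + width),
        name = sprintf("%s_peak%04d", b$tf, seq_len(nrow(gm))),
        score = round(stats::runif(nrow(gm), 10, 1000)),
        strand = ".")
      truth[[paste0("bound_", b$tf)]] <- flag
    }

    ## paralog layer: planted flags, then a family partition
    pl <- spec$paralog
    has_par <- .plant_layer(truth, pl$target_clusters, pl$odds_ratio,
                            pl$background_rate, "paralog")
    par_genes <- sample(genes[has_par])   # shuffle before chunking
    fams <- list()
    i <- 1L
    while (i <= length(par_genes)) {
      sz <- sample(seq(pl$family_size[1], pl$family_size[2]), 1L)
      j <- min(i + sz - 1L, length(par_genes))
      fams[[length(fams) + 1L]] <- par_genes[i:j]
      i <- j + 1L
    }
    # a trailing singleton cannot be a family; merge it into the last
    if (length(fams) > 1L && length(fams[[length(fams)]]) == 1L) {
      fams[[length(fams) - 1L]] <- c(fams[[length(fams) - 1L]],
                                     fams[[length(fams)]])
      fams[[length(fams)]] <- NULL
    }
    truth$has_paralog <- truth$gene %in% unlist(fams)
    fam_id <- rep(NA_integer_, ng)
    for (f in seq_along(fams)) fam_id[match(fams[[f]], genes)] <- f
    truth$paralog_family <- fam_id

    ## functional terms: planted + decoys
    term_map <- list()
    for (tm in spec$terms) {
      flag <- .plant_layer(truth, tm$target_clusters, tm$odds_ratio,
                           tm$background_rate, paste0("term:", tm$term))
      term_map[[tm$term]] <- genes[flag]
      truth[[paste0("term_", tm$term)]] <- flag
    }
    if (spec$n_decoy_terms > 0) {
      for (d in seq_len(spec$n_decoy_terms)) {
        rate <- stats::runif(1, 0.02, 0.10)
        term_map[[sprintf("TERM:9%03d", d)]] <-
          genes[stats::runif(ng) < rate]
      }
    }

    ## tissue atlas: baseline log2 expression everywhere, designated
    ## tissue boosted above the row maximum for planted genes
    tissues <- spec$tissues
    atlas <- matrix(stats::rnorm(ng * length(tissues), 6, 1), ng,
                    dimnames = list(genes, tissues))
    peak_tissue <- rep(NA_character_, ng)
    planted <- !is.na(truth$cluster)
    peak_tissue[planted] <-
      unname(spec$cluster_tissue[as.character(truth$cluster[planted])])
    for (g in which(planted)) {
      atlas[g, peak_tissue[g]] <-
        max(atlas[g, ]) + stats::runif(1, 0.5, 2)
    }
    truth$peak_tissue <- peak_tissue
  })

  ## proteome, on its own stream: family members are mutated copies of
  ## a common ancestor, singletons are independent random sequences
  .with_seed(seeds[["sequences"]], {
    proteome <- character(ng)
    names(proteome) <- genes
    lens <- as.integer(round(stats::runif(ng, 150, 400)))
    # each member diverges from the ancestor at half the target
    # divergence, so the expected pairwise identity within a family
    # is the configured identity level
    anc_keep <- 1 - (1 - pl$identity) / 2
    for (f in seq_along(fams)) {
      members <- match(fams[[f]], genes)
      anc <- .random_protein(lens[members[1]])
      for (m in members)
        proteome[m] <- .mutate_protein(anc, anc_keep)
    }
    singles <- which(!truth$has_paralog)
    for (s in singles) proteome[s] <- .random_protein(lens[s])
  })

  structure(list(atlas = atlas, peaks = peaks, gene_models = gene_models,
                 term_map = term_map, proteome = proteome, bound = bound,
                 paralog_families = fams, truth = truth),
            class = "AnnotationBundle")
}

#' @export
print.AnnotationBundle <- function(x, ...) {
  cat(sprintf(paste0("AnnotationBundle: %d genes, %d tissues, %d TF",
                     " layers, %d terms, %d paralog families\n"),
              nrow(x$atlas), ncol(x$atlas), length(x$peaks),
              length(x$term_map), length(x$paralog_families)))
  invisible(x)
}
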