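#' Configuration of a full pipeline run
#'
#' Collects every threshold of the analysis together with either a
#' synthetic-study configuration or paths to user-supplied inputs
#' (exactly one of the two).  Defaults are the study's published
#' settings: adjusted p < 0.01 with fold change >= 1.7 inside 2-day
#' contrast windows, k = 15 clusters, 100 random sets with a 3-SD
#' rule, E <= 1e-20 with 80 % query coverage and top-5 hits for
#' paralogs, and a 0.05 cutoff for term enrichment.
#'
#' @param sim a [sim_config()] for synthetic mode, or `NULL`.
#' @param inputs named list of file paths for real-data mode
#'   (`expression`, `design`, and optionally `atlas`, `peaks` (named
#'   vector of BED paths per TF), `gene_models`, `terms` (GMT),
#'   `proteome` (FASTA)), or `NULL`.
#' @param alpha adjusted-p threshold for DEG calling.
#' @param fc_min minimum fold change (linear scale, inclusive).
#' @param window_days contrast window (days).
#' @param k number of co-expression clusters.
#' @param n_iter random sets per cluster in resampling enrichment.
#' @param sd_mult SD multiple of the enrichment decision rule.
#' @param e_max,cov_min,top_n paralog filters.
#' @param go_alpha adjusted-p cutoff for term enrichment.
#' @param seed master seed.
#' @param out_dir optional output directory for the TSV contracts.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, inputs = NULL,
                       alpha = 0.01, fc_min = 1.7, window_days = 2,
                       k = 15, n_iter = 100, sd_mult = 3,
                       e_max = 1e-20, cov_min = 0.80, top_n = 5,
                       go_alpha = 0.05, seed = 1L, out_dir = NULL) {
  .assert(xor(is.null(sim), is.null(inputs)),
          "exactly one of 'sim' (synthetic mode) or 'inputs' is required")
  if (!is.null(sim))
    .assert(inherits(sim, "sim_config"), "sim must be a sim_config")
  .assert(alpha > 0 && alpha <= 1, "alpha out of range")
  .assert(fc_min >= 1, "fc_min must be >= 1")
  .assert(window_days > 0, "window_days must be > 0")
  .assert(.is_count(k), "k must be a positive count")
  .assert(n_iter >= 2, "n_iter must be >= 2")
  .assert(sd_mult > 0, "sd_mult must be > 0")
  .assert(e_max > 0 && cov_min > 0 && cov_min <= 1 && .is_count(top_n),
          "invalid paralog thresholds")
  structure(list(sim = sim, inputs = inputs, alpha = alpha,
                 fc_min = fc_min, window_days = window_days, k = k,
                 n_iter = n_iter, sd_mult = sd_mult, e_max = e_max,
                 cov_min = cov_min, top_n = top_n, go_alpha = go_alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full time-course analysis pipeline
#'
#' Executes, in order: data acquisition (synthetic generation or file
#' loading), per-gene model fitting with empirical-Bayes moderation,
#' the global F-scan, windowed-contrast DEG calling, k-means
#' co-expression clustering, tissue-atlas mapping, resampling
#' enrichment of bound-gene and paralog sets (against both the DEG
#' universe and the whole-array universe), term enrichment per
#' cluster, and paralog identification.  Stages whose inputs are
#' absent are skipped and recorded in the run summary.  Output is
#' deterministic for a fixed seed.
#'
#' @param config a [run_config()].
#' @return object of class `ResultsBundle`: list with elements
#'   `expr`, `fit`, `f_scan`, `contrasts`, `degs`, `clusters`,
#'   `elbow` (`NULL` unless requested), `tissue_extremes`,
#'   `enrichment` (list per layer x universe), `go` (list per
#'   cluster), `paralogs`, `truth` (synthetic mode only), and
#'   `provenance` (thresholds, seed, versions, skipped stages).
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "run_config"), "config must be a run_config")
  skipped <- character(0)
  truth <- NULL
  bundle_annot <- NULL

  if (!is.null(config$sim)) {
    sim <- generate_timecourse(config$sim)
    bundle_annot <- generate_annotations(
      config$sim, sim$truth, enrich_spec(config$sim$n_archetypes))
    truth <- bundle_annot$truth
    expr <- sim$expr
    atlas <- bundle_annot$atlas
    peaks <- bundle_annot$peaks
    gene_models <- bundle_annot$gene_models
    term_map <- bundle_annot$term_map
    proteome <- bundle_annot$proteome
  } else {
    inp <- config$inputs
    .assert(!is.null(inp$expression) && !is.null(inp$design),
            "real-data mode requires 'expression' and 'design' paths")
    expr <- read_expression(inp$expression, inp$design)
    atlas <- if (!is.null(inp$atlas)) read_atlas(inp$atlas) else NULL
    peaks <- if (!is.null(inp$peaks))
      lapply(inp$peaks, read_bed) else NULL
    gene_models <- if (!is.null(inp$gene_models)) {
      gm <- read_bed(inp$gene_models, stranded = TRUE)
      data.frame(gene = gm$name, chrom = gm$chrom, start = gm$start,
                 end = gm$end, strand = gm$strand)
    } else NULL
    term_map <- if (!is.null(inp$terms)) read_gmt(inp$terms) else NULL
    proteome <- if (!is.null(inp$proteome)) read_fasta(inp$proteome)
                else NULL
  }

  ## differential expression
  fit <- fit_timecourse(expr)
  mfit <- moderate_variances(fit)
  f_scan <- global_f_test(mfit, alpha = config$alpha)
  ct <- windowed_contrasts(mfit, window_days = config$window_days)
  degs <- call_degs(ct, alpha = config$alpha, fc_min = config$fc_min)
  deg_genes <- degs$gene[degs$deg]
  all_genes <- rownames(expr$M)

  ## co-expression clustering
  clusters <- NULL
  if (length(deg_genes) >= config$k) {
    scaled <- zscore_profiles(expr, deg_genes)
    clusters <- kmeans_cluster(scaled, k = config$k,
                               seed = config$seed, n_init = 25)
  } else skipped <- c(skipped, "cluster (fewer DEGs than k)")

  ## tissue atlas
  tissue_extremes <- NULL
  if (!is.null(atlas) && !is.null(clusters)) {
    tissue_extremes <- map_extreme_tissue(clusters, atlas)
  } else if (is.null(atlas)) skipped <- c(skipped, "atlas (no atlas)")

  ## paralogs
  paralogs <- NULL
  if (!is.null(proteome)) {
    paralogs <- find_paralogs(proteome, e_max = config$e_max,
                              cov_min = config$cov_min,
                              top_n = config$top_n)
  } else skipped <- c(skipped, "paralogs (no proteome)")

  ## resampling enrichment: bound-gene layers and the paralog set,
  ## against the DEG universe and the whole-array universe
  enrichment <- list()
  if (!is.null(clusters)) {
    layers <- list()
    if (!is.null(peaks) && !is.null(gene_models)) {
      for (tf in names(peaks))
        layers[[paste0("bound_", tf)]] <-
          assign_peaks_to_genes(peaks[[tf]], gene_models)
    } else if (is.null(peaks))
      skipped <- c(skipped, "binding enrichment (no peaks)")
    if (!is.null(paralogs))
      layers[["paralog"]] <- paralogs$genes_with_paralogs
    for (nm in names(layers)) {
      enrichment[[paste(nm, "vs_degs", sep = "_")]] <-
        resampling_set_enrichment(clusters, layers[[nm]], deg_genes,
                                  n_iter = config$n_iter,
                                  seed = config$seed,
                                  sd_mult = config$sd_mult,
                                  background_label = "DEGs")
      enrichment[[paste(nm, "vs_genome", sep = "_")]] <-
        resampling_set_enrichment(clusters, layers[[nm]], all_genes,
                                  n_iter = config$n_iter,
                                  seed = config$seed,
                                  sd_mult = config$sd_mult,
                                  background_label = "array")
    }
  }

  ## term enrichment per cluster
  go <- NULL
  if (!is.null(term_map) && !is.null(clusters)) {
    go <- lapply(sort(unique(clusters$cluster)), function(cc)
      go_enrichment(names(clusters$cluster)[clusters$cluster == cc],
                    all_genes, term_map, alpha = config$go_alpha))
    names(go) <- sort(unique(clusters$cluster))
  } else if (is.null(term_map))
    skipped <- c(skipped, "term enrichment (no term map)")

  bundle <- structure(list(
    expr = expr, fit = mfit, f_scan = f_scan, contrasts = ct,
    degs = degs, clusters = clusters,
    tissue_extremes = tissue_extremes, enrichment = enrichment,
    go = go, paralogs = paralogs, truth = truth,
    provenance = list(
      seed = config$seed,
      thresholds = config[c("alpha", "fc_min", "window_days", "k",
                            "n_iter", "sd_mult", "e_max", "cov_min",
                            "top_n", "go_alpha")],
      skipped = skipped,
      package_version = as.character(utils::packageVersion("floraltc")),
      r_version = R.version.string)),
    class = "ResultsBundle")

  if (!is.null(config$out_dir)) write_results(bundle, config$out_dir)
  bundle
}

#' @export
print.ResultsBundle <- function(x, ...) {
  cat("ResultsBundle\n")
  cat(sprintf("  genes: %d  arrays: %d\n", nrow(x$expr$M),
              ncol(x$expr$M)))
  cat(sprintf("  responsive (F-scan): %d;  DEGs (windowed): %d\n",
              sum(x$f_scan$responsive), sum(x$degs$deg)))
  if (!is.null(x$clusters))
    cat(sprintf("  clusters: k = %d (BSS/TSS = %.3f)\n",
                x$clusters$k, x$clusters$bss_tss))
  if (length(x$enrichment))
    cat(sprintf("  enrichment layers: %s\n",
                paste(names(x$enrichment), collapse = ", ")))
  if (!is.null(x$paralogs))
    cat(sprintf("  genes with paralogs: %d\n",
                length(x$paralogs$genes_with_paralogs)))
  if (length(x$provenance$skipped))
    cat(sprintf("  skipped: %s\n",
                paste(x$provenance$skipped, collapse = "; ")))
  invisible(x)
}

#' Write a results bundle as headered TSV contracts
#'
#' Writes every table in the bundle (expression, design, F-scan,
#' contrasts, DEG table, cluster assignment, tissue extremes,
#' enrichment results, term enrichment, paralog hits, truth table when
#' present) plus a `run_summary.tsv` key/value file recording every
#' threshold applied, the seed, versions, and skipped stages.
#'
#' @param bundle a `ResultsBundle`.
#' @param out_dir directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_results <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(name) file.path(out_dir, name)
  write_expression(bundle$expr, fp("expression.tsv"), fp("design.tsv"))
  .write_tsv(bundle$f_scan, fp("f_scan.tsv"))
  .write_tsv(as.data.frame(bundle$contrasts), fp("contrasts.tsv"))
  .write_tsv(as.data.frame(bundle$degs), fp("degs.tsv"))
  if (!is.null(bundle$clusters))
    .write_tsv(data.frame(gene = names(bundle$clusters$cluster),
                          cluster = unname(bundle$clusters$cluster)),
               fp("clusters.tsv"))
  if (!is.null(bundle$tissue_extremes))
    .write_tsv(as.data.frame(bundle$tissue_extremes),
               fp("tissue_extremes.tsv"))
  for (nm in names(bundle$enrichment))
    .write_tsv(as.data.frame(bundle$enrichment[[nm]]),
               fp(sprintf("enrichment_%s.tsv", nm)))
  if (!is.null(bundle$go)) {
    go_all <- do.call(rbind, lapply(names(bundle$go), function(cc)
      cbind(cluster = cc, bundle$go[[cc]])))
    .write_tsv(go_all, fp("term_enrichment.tsv"))
  }
  if (!is.null(bundle$paralogs)) {
    ph <- bundle$paralogs$hits
    flat <- do.call(rbind, lapply(names(ph), function(q)
      if (nrow(ph[[q]])) cbind(query = q, ph[[q]]) else NULL))
    if (!is.null(flat)) .write_tsv(flat, fp("paralogs.tsv"))
  }
  if (!is.null(bundle$truth)) .write_tsv(bundle$truth, fp("truth.tsv"))
  pv <- bundle$provenance
  summ <- data.frame(
    key = c("seed", names(pv$thresholds), "package_version",
            "r_version", "skipped"),
    value = c(pv$seed,
              vapply(pv$thresholds, function(v) format(v), ""),
              pv$package_version, pv$r_version,
              paste(pv$skipped, collapse = "; ")))
  .write_tsv(summ, fp("run_summary.tsv"))
  invisible(out_dir)
}
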