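# Readers and writers for the pipeline's plain-text contracts:
# headered TSV for matrices/tables, BED6 for peaks and gene models,
# GMT for gene sets, FASTA for the proteome.  Readers validate and
# report the offending file/line.

.read_tsv <- function(path, ...) {
  .assert(file.exists(path), "file not found: %s", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

.write_tsv <- function(df, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    df <- cbind(stats::setNames(data.frame(rownames(df),
                                           stringsAsFactors = FALSE),
                                rownames_as),
                as.data.frame(df, check.names = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read an expression matrix with its design
#'
#' Two headered TSV files: the matrix (first column `gene`, one column
#' per array) and the design (`array`, `time_point`, `replicate`).
#'
#' @param em an [expression_matrix()].
#' @param matrix_path,design_path file paths.
#' @return `write_expression` the paths, invisibly; `read_expression`
#'   an `ExpressionMatrix` (M only).
#' @export
write_expression <- function(em, matrix_path, design_path) {
  .write_tsv(em$M, matrix_path, rownames_as = "gene")
  .write_tsv(em$design, design_path)
  invisible(c(matrix_path, design_path))
}

#' @rdname write_expression
#' @export
read_expression <- function(matrix_path, design_path) {
  m <- .read_tsv(matrix_path)
  .assert(names(m)[1] == "gene", "%s: first column must be 'gene'",
          matrix_path)
  dup <- m$gene[duplicated(m$gene)]
  .assert(length(dup) == 0, "%s: duplicate gene id '%s'",
          matrix_path, if (length(dup)) dup[1] else "")
  M <- as.matrix(m[, -1, drop = FALSE])
  rownames(M) <- m$gene
  design <- .read_tsv(design_path)
  .assert(all(c("array", "time_point", "replicate") %in% names(design)),
          "%s: design needs array/time_point/replicate", design_path)
  expression_matrix(M, design)
}

#' Write / read a gene-by-tissue atlas matrix
#' @param atlas gene x tissue matrix.
#' @param path file path.
#' @export
write_atlas <- function(atlas, path) {
  .write_tsv(atlas, path, rownames_as = "gene")
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  m <- .read_tsv(path)
  .assert(names(m)[1] == "gene", "%s: first column must be 'gene'", path)
  A <- as.matrix(m[, -1, drop = FALSE])
  rownames(A) <- m$gene
  A
}

#' Write / read BED6 intervals (0-based half-open)
#'
#' `read_bed` validates coordinates and reports the first offending
#' line.  For gene models the `name` column holds the gene id and the
#' strand must be `+`/`-`.
#'
#' @param bed data.frame `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @param path file path.
#' @param stranded require `+`/`-` strand (gene models).
#' @export
write_bed <- function(bed, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  for (cc in setdiff(cols, names(bed)))
    bed[[cc]] <- if (cc == "score") 0 else "."
  utils::write.table(bed[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path, stranded = FALSE) {
  .assert(file.exists(path), "file not found: %s", path)
  bed <- utils::read.delim(path, header = FALSE,
                           stringsAsFactors = FALSE)
  .assert(ncol(bed) >= 3, "%s: BED needs >= 3 columns", path)
  names(bed)[1:min(6, ncol(bed))] <-
    c("chrom", "start", "end", "name", "score", "strand")[1:min(6, ncol(bed))]
  bad <- which(!(bed$start >= 0 & bed$start < bed$end))
  .assert(length(bad) == 0, "%s line %d: start must satisfy 0 <= start < end",
          path, if (length(bad)) bad[1] else 0L)
  if (stranded) {
    bad <- which(!bed$strand %in% c("+", "-"))
    .assert(length(bad) == 0, "%s line %d: strand must be + or -",
            path, if (length(bad)) bad[1] else 0L)
  }
  bed
}

#' Write / read GMT gene-set files
#'
#' One set per line: `label <TAB> description <TAB> gene1 <TAB> ...`.
#'
#' @param sets named list label -> character vector of gene ids.
#' @param path file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    .assert(length(f) >= 2, "%s line %d: GMT needs label and description",
            path, i)
    .assert(!f[1] %in% names(out), "%s line %d: duplicate set label '%s'",
            path, i, f[1])
    out[[f[1]]] <- if (length(f) > 2) f[-(1:2)] else character(0)
  }
  out
}

#' Write / read a protein FASTA
#'
#' `read_fasta` rejects duplicate sequence ids.
#'
#' @param proteome named character vector gene -> sequence.
#' @param path file path.
#' @export
write_fasta <- function(proteome, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  .assert(length(dup) == 0, "%s: duplicate sequence id '%s'",
          path, if (length(dup)) dup[1] else "")
  stats::setNames(as.character(ss), ids)
}
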