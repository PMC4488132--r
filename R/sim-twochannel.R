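#' Smooth intensity-dependent dye-bias basis
#'
#' The shape `f(A)` along which the raw-array generator injects a
#' two-channel dye bias `M <- M + b * f(A)`; within-array loess
#' normalization is expected to remove it.  Exposed so callers can
#' regress observed M on the same basis.
#'
#' @param A numeric vector of average log2 intensities.
#' @return numeric vector, the basis evaluated at `A` (bounded in
#'   `[-1, 1]`).
#' @export
dye_bias_basis <- function(A) sin((A - 10) / 2)

#' Simulate raw two-channel arrays from a simulated time course
#'
#' Turns the gene-level M-values of [generate_timecourse()] into
#' probe-level red/green foreground and background intensities for each
#' array: per-gene baseline log2 intensities, multiple probes per gene,
#' an additive background, an intensity-dependent dye bias along
#' [dye_bias_basis()], and a block of labelled negative-control probes
#' near background level.  With zero background, zero dye bias, zero
#' probe noise and one probe per gene, recomputing
#' `M = log2(R/G)` reproduces the input M-values exactly.
#'
#' @param config the [sim_config()] used for the time course.
#' @param sim result of [generate_timecourse()] under the same config.
#' @param n_probes_per_gene probes spotted per gene (default 2).
#' @param background mean additive background intensity (default 80;
#'   0 disables background).
#' @param dye_bias amplitude `b` of the intensity-dependent bias
#'   `b * dye_bias_basis(A)` added to every probe's M (default 0).
#' @param probe_noise_sd SD of probe-level M noise (default 0).
#' @param n_negctl number of negative-control probes (default 100).
#' @param n_low_expr number of genes whose baseline intensity is forced
#'   to near-background level, for testing the low-expression filter
#'   (default 0).
#' @return object of class `RawArray`: probe ids, probe-to-gene map
#'   (`NA` for controls), `is_control` flags, probe-by-array intensity
#'   matrices `R_fg`, `R_bg`, `G_fg`, `G_bg`, and the array design.
#' @export
generate_raw_two_channel <- function(config, sim,
                                     n_probes_per_gene = 2,
                                     background = 80,
                                     dye_bias = 0,
                                     probe_noise_sd = 0,
                                     n_negctl = 100,
                                     n_low_expr = 0) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  .assert(is.list(sim) && inherits(sim$expr, "ExpressionMatrix"),
          "sim must be the result of generate_timecourse()")
  .assert(.is_count(n_probes_per_gene), "n_probes_per_gene must be >= 1")
  .assert(n_low_expr >= 0 && n_low_expr <= config$n_genes,
          "n_low_expr out of range")
  seeds <- .layer_seeds(config$seed)
  M_gene <- sim$expr$M
  genes <- rownames(M_gene)
  ng <- length(genes)
  arrays <- colnames(M_gene)
  na <- length(arrays)

  .with_seed(seeds[["raw"]], {
    # per-gene baseline average log2 intensity, kept clear of the
    # ambient control level so only planted low-expression genes fall
    # below the background filter
    L <- stats::rnorm(ng, mean = 10, sd = 1.5)
    low_tail <- L < 7.5
    L[low_tail] <- stats::runif(sum(low_tail), 7.5, 8.5)
    low_idx <- integer(0)
    if (n_low_expr > 0) {
      low_idx <- seq_len(n_low_expr)   # first genes, recorded below
      L[low_idx] <- stats::rnorm(n_low_expr, mean = 3.5, sd = 0.2)
    }
    np <- ng * n_probes_per_gene
    probe_gene <- rep(genes, each = n_probes_per_gene)
    probe_ids <- paste0(probe_gene, "_p", seq_len(n_probes_per_gene))
    probe_off <- stats::rnorm(np, 0, 0.1)   # probe affinity offset on A

    A_probe <- L[rep(seq_len(ng), each = n_probes_per_gene)] + probe_off
    M_probe <- M_gene[rep(seq_len(ng), each = n_probes_per_gene), ,
                      drop = FALSE]
    if (probe_noise_sd > 0)
      M_probe <- M_probe + matrix(stats::rnorm(np * na, 0, probe_noise_sd),
                                  np, na)
    if (dye_bias != 0)
      M_probe <- M_probe + dye_bias * dye_bias_basis(A_probe)

    # negative controls: ambient signal around 2^6
    L_ctl <- stats::rnorm(n_negctl, mean = 6, sd = 0.2)
    ctl_ids <- sprintf("NEGCTL_%03d", seq_len(n_negctl))

    A_all <- c(A_probe, L_ctl)
    M_all <- rbind(M_probe,
                   matrix(stats::rnorm(n_negctl * na, 0, 0.1),
                          n_negctl, na))
    R_sig <- 2^(A_all + M_all / 2)
    G_sig <- 2^(A_all - M_all / 2)

    ntot <- np + n_negctl
    if (background > 0) {
      R_bg <- matrix(background *
                       (1 + 0.1 * stats::rnorm(ntot * na)), ntot, na)
      G_bg <- matrix(background *
                       (1 + 0.1 * stats::rnorm(ntot * na)), ntot, na)
      R_bg[R_bg < 0] <- 0
      G_bg[G_bg < 0] <- 0
    } else {
      R_bg <- G_bg <- matrix(0, ntot, na)
    }
  })

  ids <- c(probe_ids, ctl_ids)
  dn <- list(ids, arrays)
  structure(list(
    probes = ids,
    gene = c(probe_gene, rep(NA_character_, n_negctl)),
    is_control = c(rep(FALSE, np), rep(TRUE, n_negctl)),
    R_fg = matrix(R_sig + R_bg, length(ids), na, dimnames = dn),
    R_bg = `dimnames<-`(R_bg, dn),
    G_fg = matrix(G_sig + G_bg, length(ids), na, dimnames = dn),
    G_bg = `dimnames<-`(G_bg, dn),
    design = sim$expr$design,
    low_expression_genes = genes[low_idx]),
    class = "RawArray")
}

#' @export
print.RawArray <- function(x, ...) {
  cat(sprintf("RawArray: %d probes (%d negative controls) x %d arrays\n",
              length(x$probes), sum(x$is_control), ncol(x$R_fg)))
  invisible(x)
}
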