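#' Configuration of the synthetic flower-development study
#'
#' Bundles every knob of the synthetic-data generator.  The defaults
#' emulate the design of the real study: floral buds sampled at 14
#' time-points over 13 days (dense 0.5-day sampling early, 2-day
#' intervals late), three biologically independent replicate series
#' hybridized against a common reference, and fifteen temporal
#' expression archetypes among the differentially expressed genes.
#'
#' @param n_genes number of genes on the synthetic array.
#' @param time_points strictly increasing vector of sampling times in
#'   days.  The default grid has 14 points: intervals of 0.5-1 d during
#'   early development and 2 d at late stages.
#' @param n_replicates number of biologically independent replicate
#'   series (default 3).
#' @param n_archetypes number of distinct temporal archetypes assigned
#'   to differentially expressed genes (default 15).
#' @param frac_de fraction of genes given a non-flat archetype.
#' @param noise_prior named numeric vector `c(d0 = ..., s0_sq = ...)`:
#'   prior degrees of freedom and prior scale of the scaled
#'   inverse-chi-square distribution from which per-gene residual
#'   variances are drawn.
#' @param fc_scale typical absolute M-value amplitude of an archetype;
#'   per-gene amplitudes are drawn uniformly in
#'   `[0.5, 1.5] * fc_scale`.
#' @param seed master seed; per-layer generator streams (expression,
#'   annotations, sequences) are derived from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       time_points = c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5,
                                       4, 5, 7, 9, 11, 13),
                       n_replicates = 3,
                       n_archetypes = 15,
                       frac_de = 0.3,
                       noise_prior = c(d0 = 4, s0_sq = 0.05),
                       fc_scale = 2,
                       seed = 1L) {
  .assert(.is_count(n_genes), "n_genes must be a positive count")
  .assert(is.numeric(time_points) && length(time_points) >= 2,
          "time_points must be a numeric vector of length >= 2")
  .assert(all(diff(time_points) > 0),
          "time_points must be strictly increasing")
  .assert(.is_count(n_replicates), "n_replicates must be a positive count")
  .assert(.is_count(n_archetypes), "n_archetypes must be >= 1")
  .assert(is.numeric(frac_de) && frac_de > 0 && frac_de <= 1,
          "frac_de must be in (0, 1]")
  .assert(is.numeric(noise_prior) &&
            all(c("d0", "s0_sq") %in% names(noise_prior)),
          "noise_prior must be c(d0 = ..., s0_sq = ...)")
  .assert(noise_prior[["d0"]] > 0 && noise_prior[["s0_sq"]] >= 0,
          "noise_prior: d0 > 0 and s0_sq >= 0 required")
  .assert(is.numeric(fc_scale) && fc_scale > 0, "fc_scale must be > 0")
  structure(list(n_genes = as.integer(n_genes),
                 time_points = as.numeric(time_points),
                 n_replicates = as.integer(n_replicates),
                 n_archetypes = as.integer(n_archetypes),
                 frac_de = frac_de,
                 noise_prior = c(d0 = unname(noise_prior[["d0"]]),
                                 s0_sq = unname(noise_prior[["s0_sq"]])),
                 fc_scale = fc_scale,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d genes, %d time-points (%g-%g d), %d replicates\n",
              x$n_genes, length(x$time_points), min(x$time_points),
              max(x$time_points), x$n_replicates))
  cat(sprintf("  %d archetypes, frac_de = %g, fc_scale = %g\n",
              x$n_archetypes, x$frac_de, x$fc_scale))
  cat(sprintf("  noise prior: d0 = %g, s0_sq = %g; seed = %d\n",
              x$noise_prior[["d0"]], x$noise_prior[["s0_sq"]], x$seed))
  invisible(x)
}
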