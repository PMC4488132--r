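# Temporal archetype library.  Shapes are defined on normalized time
# u in [0, 1] with values in [-1, 1]; a per-gene amplitude rescales them
# to M-value units.  Shapes mimic the profile families seen in real
# floral time courses: early/late activation and repression, transient
# bumps and dips at various stages, and bimodal profiles.

.sigmoid <- function(u, mid, rate = 0.08) 1 / (1 + exp(-(u - mid) / rate))
.bump <- function(u, mid, width = 0.10) exp(-((u - mid)^2) / (2 * width^2))

.archetype_library <- list(
  function(u) 2 * .sigmoid(u, 0.15) - 1,          # early activation
  function(u) 2 * .sigmoid(u, 0.70) - 1,          # late activation
  function(u) 1 - 2 * .sigmoid(u, 0.15),          # early repression
  function(u) 1 - 2 * .sigmoid(u, 0.70),          # late repression
  function(u) 2 * .bump(u, 0.20) - 1,             # early bump
  function(u) 2 * .bump(u, 0.40) - 1,             # mid bump
  function(u) 2 * .bump(u, 0.60) - 1,             # intermediate bump
  function(u) 2 * .bump(u, 0.85) - 1,             # late bump
  function(u) 1 - 2 * .bump(u, 0.30),             # early dip
  function(u) 1 - 2 * .bump(u, 0.70),             # late dip
  function(u) 2 * pmax(.bump(u, 0.12), .bump(u, 0.75)) - 1,  # bimodal
  function(u) 2 * .bump(u, 0.50, 0.22) - 1,       # broad rise-fall
  function(u) 1 - 2 * .bump(u, 0.50, 0.22),       # broad fall-rise
  function(u) 2 * .sigmoid(u, 0.40) - 1,          # mid activation
  function(u) 1 - 2 * .sigmoid(u, 0.40)           # mid repression
)

#' Evaluate the temporal archetypes on a time grid
#'
#' Archetype 0 is the flat/null profile and is not included in the
#' returned matrix.  When more archetypes are requested than the library
#' holds, shapes are recycled with shifted centres.
#'
#' @param time_points numeric vector of sampling times (days).
#' @param n_archetypes number of non-null archetypes.
#' @return matrix `n_archetypes x length(time_points)` of unit-amplitude
#'   profiles (values in `[-1, 1]`).
#' @export
archetype_profiles <- function(time_points, n_archetypes = 15) {
  u <- (time_points - min(time_points)) /
    (max(time_points) - min(time_points))
  nlib <- length(.archetype_library)
  prof <- matrix(0, n_archetypes, length(time_points))
  for (a in seq_len(n_archetypes)) {
    f <- .archetype_library[[(a - 1L) %% nlib + 1L]]
    shift <- 0.07 * ((a - 1L) %/% nlib)    # recycled shapes get offset
    prof[a, ] <- f(pmin(pmax(u - shift, 0), 1))
  }
  rownames(prof) <- paste0("archetype", seq_len(n_archetypes))
  colnames(prof) <- as.character(time_points)
  prof
}

# largest |difference| of a profile between any two time-points lying
# within `window` days of each other (the effect size a windowed
# contrast can see)
.max_window_delta <- function(profile, time_points, window = 2) {
  pairs <- which(outer(time_points, time_points,
                       function(a, b) b > a & b - a <= window),
                 arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(0)
  max(abs(profile[pairs[, 2]] - profile[pairs[, 1]]))
}

#' Simulate the expression time course
#'
#' Draws per-gene residual variances from a scaled inverse-chi-square
#' prior, assigns a fraction `frac_de` of genes a non-flat temporal
#' archetype with a per-gene amplitude, and generates M-values
#' `M[g, t, r] = amplitude_g * archetype_g(t) + e`,
#' `e ~ Normal(0, sigma_g^2)`, for every replicate.  Flat (null) genes
#' have a true mean of zero at every time-point.  Output is
#' deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   \describe{
#'     \item{expr}{[expression_matrix()] of all arrays
#'       (time-points x replicates), M-values only.}
#'     \item{truth}{data.frame, one row per gene: `gene`, `archetype`
#'       (0 = flat), `is_de`, `cluster` (planted cluster id, NA for
#'       null genes), `sigma2` (true residual variance), `amplitude`,
#'       and `max_window_lfc` (largest true |log2 FC| between
#'       time-points within a 2-day window).}
#'     \item{profiles}{true per-gene mean matrix (genes x time-points).}
#'     \item{archetypes}{unit-amplitude archetype matrix.}
#'   }
#' @export
generate_timecourse <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  seeds <- .layer_seeds(config$seed)
  tp <- config$time_points
  n_tp <- length(tp)
  ng <- config$n_genes
  genes <- sprintf("G%05d", seq_len(ng))
  arch <- archetype_profiles(tp, config$n_archetypes)

  .with_seed(seeds[["expression"]], {
    n_de <- round(config$frac_de * ng)
    de_idx <- sample.int(ng, n_de)
    archetype_id <- integer(ng)
    archetype_id[de_idx] <- rep_len(seq_len(config$n_archetypes), n_de)
    amplitude <- numeric(ng)
    amplitude[de_idx] <- config$fc_scale * runif(n_de, 0.5, 1.5)
    d0 <- config$noise_prior[["d0"]]
    s0 <- config$noise_prior[["s0_sq"]]
    sigma2 <- d0 * s0 / stats::rchisq(ng, df = d0)

    profiles <- matrix(0, ng, n_tp, dimnames = list(genes, colnames(arch)))
    nz <- archetype_id > 0L
    profiles[nz, ] <- amplitude[nz] * arch[archetype_id[nz], , drop = FALSE]

    arrays <- as.vector(outer(sprintf("T%02d", seq_len(n_tp)),
                              sprintf("R%d", seq_len(config$n_replicates)),
                              paste, sep = "_"))
    design <- data.frame(
      array = arrays,
      time_point = rep(tp, times = config$n_replicates),
      replicate = rep(seq_len(config$n_replicates), each = n_tp))
    M <- matrix(NA_real_, ng, length(arrays),
                dimnames = list(genes, arrays))
    for (j in seq_along(arrays)) {
      t_idx <- match(design$time_point[j], tp)
      M[, j] <- profiles[, t_idx] + stats::rnorm(ng, 0, sqrt(sigma2))
    }
  })

  mwl <- apply(profiles, 1L, .max_window_delta, time_points = tp,
               window = 2)
  truth <- data.frame(
    gene = genes,
    archetype = archetype_id,
    is_de = archetype_id > 0L,
    cluster = ifelse(archetype_id > 0L, archetype_id, NA_integer_),
    sigma2 = sigma2,
    amplitude = amplitude,
    max_window_lfc = mwl)

  list(expr = expression_matrix(M, design),
       truth = truth,
       profiles = profiles,
       archetypes = arch)
}
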