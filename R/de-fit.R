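#' Fit per-gene linear models over the time course
#'
#' One-way layout on time-point: the coefficient for each time-point is
#' the mean M-value over its replicate arrays, and the residual
#' variance is the usual unbiased pooled estimate across time-points.
#' Genes without enough data (fewer than two time-points observed, or
#' zero residual degrees of freedom) are flagged untestable and carry
#' `NA` statistics.
#'
#' @param em an [expression_matrix()].
#' @return object of class `ModelFit`: list with
#'   \describe{
#'     \item{coef}{genes x time-points matrix of per-time-point means.}
#'     \item{n_obs}{genes x time-points matrix of replicate counts.}
#'     \item{s2}{per-gene residual variance.}
#'     \item{df}{per-gene residual degrees of freedom.}
#'     \item{testable}{logical per gene.}
#'     \item{time_points}{sorted unique time grid (days).}
#'   }
#' @export
fit_timecourse <- function(em) {
  .assert(inherits(em, "ExpressionMatrix"), "em must be an ExpressionMatrix")
  tp <- sort(unique(em$design$time_point))
  .assert(length(tp) >= 2, "need at least two time-points")
  grp <- factor(em$design$time_point, levels = tp)
  M <- em$M
  obs <- (!is.na(M)) * 1
  cnt <- t(rowsum(t(obs), grp))              # genes x time-points
  M0 <- M
  M0[is.na(M0)] <- 0
  sums <- t(rowsum(t(M0), grp))
  coef <- sums / cnt
  coef[cnt == 0] <- NA_real_

  fitted <- coef[, as.integer(grp), drop = FALSE]
  resid <- M - fitted
  rss <- rowSums(resid^2, na.rm = TRUE)
  n_obs_tot <- rowSums(cnt)
  n_tp_used <- rowSums(cnt > 0)
  df <- n_obs_tot - n_tp_used
  testable <- n_tp_used >= 2 & df >= 1
  s2 <- ifelse(df >= 1, rss / pmax(df, 1), NA_real_)
  s2[!testable] <- NA_real_
  df[!testable] <- NA_real_

  dimnames(coef) <- list(rownames(M), as.character(tp))
  dimnames(cnt) <- dimnames(coef)
  structure(list(coef = coef, n_obs = cnt, s2 = s2, df = df,
                 testable = testable, time_points = tp),
            class = "ModelFit")
}

#' @export
print.ModelFit <- function(x, ...) {
  cat(sprintf("ModelFit: %d genes (%d testable) x %d time-points\n",
              nrow(x$coef), sum(x$testable), ncol(x$coef)))
  invisible(x)
}

# Invert the trigamma function by Newton iteration on 1/x scale
# (monotone, well conditioned); used to solve for the prior df.
.trigamma_inverse <- function(y) {
  .assert(is.finite(y) && y > 0, "trigamma inverse needs y > 0")
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks each gene's residual variance toward a prior scale estimated
#' from all genes.  The scaled-inverse-chi-square prior hyperparameters
#' `(d0, s0^2)` are estimated by moment matching on
#' `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)`:
#' the mean of `e` identifies `s0^2` and its excess variance over
#' `trigamma(d_g/2)` identifies `d0` via trigamma inversion.  If the
#' empirical variance of `e` does not exceed the sampling component,
#' `d0` is infinite and every posterior variance equals `s0^2`.
#' The posterior variance is
#' `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`.
#'
#' @param fit a `ModelFit` from [fit_timecourse()].
#' @return object of class `ModeratedFit`: the `ModelFit` plus
#'   `d0`, `s0_sq`, and per-gene posterior variance `s2_post`.
#'   Genes with zero residual variance are excluded from
#'   hyperparameter estimation but still receive a posterior variance.
#' @export
moderate_variances <- function(fit) {
  .assert(inherits(fit, "ModelFit"), "fit must be a ModelFit")
  use <- fit$testable & is.finite(fit$s2) & fit$s2 > 0
  .assert(sum(fit$testable & is.finite(fit$s2)) >= 50,
          "need at least 50 testable genes")
  .assert(any(use), "all residual variances are zero: degenerate input")
  s2 <- fit$s2[use]
  dg <- fit$df[use]
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  sampling_var <- mean(trigamma(dg / 2))
  excess <- evar - sampling_var
  if (excess > 0) {
    d0 <- 2 * .trigamma_inverse(excess)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  s2_post <- rep(NA_real_, length(fit$s2))
  idx <- fit$testable & is.finite(fit$s2)
  if (is.finite(d0)) {
    s2_post[idx] <- (d0 * s0_sq + fit$df[idx] * fit$s2[idx]) /
      (d0 + fit$df[idx])
  } else {
    s2_post[idx] <- s0_sq
  }
  out <- fit
  out$d0 <- d0
  out$s0_sq <- s0_sq
  out$s2_post <- s2_post
  class(out) <- c("ModeratedFit", "ModelFit")
  out
}

#' @export
print.ModeratedFit <- function(x, ...) {
  cat(sprintf("ModeratedFit: %d genes, prior d0 = %s, s0^2 = %.4g\n",
              nrow(x$coef),
              if (is.finite(x$d0)) sprintf("%.2f", x$d0) else "Inf",
              x$s0_sq))
  invisible(x)
}

#' Moderated global F-scan across the time course
#'
#' Tests, per gene, equality of all time-point coefficients with a
#' moderated F-statistic (between-time-point mean square over the
#' posterior variance), with `n_tp - 1` and `d_g + d0` degrees of
#' freedom, followed by Benjamini-Hochberg adjustment across genes.
#' Genes with adjusted p below `alpha` are "responsive".
#'
#' @param mfit a `ModeratedFit`.
#' @param alpha significance level on the adjusted p (default 0.01).
#' @return data.frame `gene`, `F`, `p`, `p_adj`, `responsive`;
#'   untestable genes are excluded and listed in
#'   `attr(, "untestable")`.
#' @export
global_f_test <- function(mfit, alpha = 0.01) {
  .assert(inherits(mfit, "ModeratedFit"), "mfit must be a ModeratedFit")
  ok <- mfit$testable & is.finite(mfit$s2_post) & mfit$s2_post > 0
  coef <- mfit$coef[ok, , drop = FALSE]
  n <- mfit$n_obs[ok, , drop = FALSE]
  grand <- rowSums(coef * n, na.rm = TRUE) / rowSums(n)
  ssb <- rowSums(n * (coef - grand)^2, na.rm = TRUE)
  df1 <- rowSums(n > 0) - 1
  Fstat <- (ssb / df1) / mfit$s2_post[ok]
  df2 <- mfit$df[ok] + mfit$d0
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p, method = "BH")
  res <- data.frame(gene = rownames(mfit$coef)[ok], F = Fstat, p = p,
                    p_adj = p_adj, responsive = p_adj < alpha,
                    row.names = NULL)
  attr(res, "untestable") <- rownames(mfit$coef)[!ok]
  res
}
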