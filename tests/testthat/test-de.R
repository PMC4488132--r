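small_em <- function(M, tp, rep) {
  colnames(M) <- sprintf("a%d", seq_len(ncol(M)))
  expression_matrix(M, data.frame(array = colnames(M), time_point = tp,
                                  replicate = rep))
}

test_that("per-gene fit equals direct group means and variances", {
  set.seed(1)
  tp <- rep(c(0, 1, 3), each = 3)
  M <- matrix(rnorm(50 * 9), 50, dimnames = list(sprintf("g%d", 1:50)))
  em <- small_em(M, tp, rep(1:3, 3))
  fit <- fit_timecourse(em)
  for (g in c(1, 17, 50)) {
    means <- tapply(M[g, ], tp, mean)
    expect_equal(unname(fit$coef[g, ]), as.vector(means),
                 tolerance = 1e-12)
    rss <- sum(unlist(tapply(M[g, ], tp,
                             function(x) (x - mean(x))^2)))
    expect_equal(unname(fit$s2[g]), rss / (9 - 3), tolerance = 1e-12)
  }
  expect_true(all(fit$df == 6))
})

test_that("replicate means and zero-variance cases are exact", {
  em <- small_em(matrix(c(1.0, 1.2, 0.8, 2, 2, 2), 1,
                        dimnames = list("g1")),
                 rep(c(0, 1), each = 3), rep(1:3, 2))
  fit <- fit_timecourse(em)
  expect_equal(unname(fit$coef["g1", "0"]), 1.0)
  expect_equal(unname(fit$coef["g1", "1"]), 2.0)
  # replicates all equal within each time-point: zero residual variance
  em2 <- small_em(matrix(rep(c(5, 7), each = 3), 1,
                         dimnames = list("g1")),
                  rep(c(0, 1), each = 3), rep(1:3, 2))
  expect_equal(fit_timecourse(em2)$s2[["g1"]], 0)
})

test_that("variance moderation matches the no-spread and outlier limits", {
  ng <- 100
  mk_fit <- function(s2) structure(
    list(coef = matrix(0, ng, 2,
                       dimnames = list(sprintf("g%d", 1:ng), 0:1)),
         n_obs = matrix(3, ng, 2), s2 = s2, df = rep(20, ng),
         testable = rep(TRUE, ng), time_points = c(0, 1)),
    class = "ModelFit")
  # all variances equal: infinite prior df, full shrinkage
  mf <- moderate_variances(mk_fit(rep(0.05, ng)))
  expect_identical(mf$d0, Inf)
  expect_true(all(mf$s2_post == mf$s0_sq))
  # s0 carries the log-scale sampling correction at d = 20
  expect_equal(mf$s0_sq, 0.05 * exp(log(10) - digamma(10)),
               tolerance = 1e-9)
  # one huge variance among many small: shrunk strictly between
  s2 <- rep(0.05, ng); s2[1] <- 5
  mf2 <- moderate_variances(mk_fit(s2))
  expect_true(is.finite(mf2$d0))
  expect_gt(mf2$s2_post[1], mf2$s0_sq)
  expect_lt(mf2$s2_post[1], 5)
  expect_true(all(mf2$s2_post >= pmin(s2, mf2$s0_sq) - 1e-12 &
                    mf2$s2_post <= pmax(s2, mf2$s0_sq) + 1e-12))
  expect_error(moderate_variances(mk_fit(rep(0, ng))), "degenerate")
})

test_that("hyperparameters are recovered from a hierarchical simulation", {
  set.seed(7)
  ng <- 5000
  sig2 <- 4 * 0.05 / rchisq(ng, 4)
  s2 <- sig2 * rchisq(ng, 20) / 20
  fit <- structure(
    list(coef = matrix(0, ng, 2,
                       dimnames = list(sprintf("g%d", 1:ng), 0:1)),
         n_obs = matrix(3, ng, 2), s2 = s2, df = rep(20, ng),
         testable = rep(TRUE, ng), time_points = c(0, 1)),
    class = "ModelFit")
  mf <- moderate_variances(fit)
  expect_lt(abs(mf$d0 - 4) / 4, 0.15)
  expect_lt(abs(mf$s0_sq - 0.05) / 0.05, 0.15)
  # independent cross-check against the established implementation
  sv <- limma::squeezeVar(s2, df = 20)
  expect_equal(mf$d0, sv$df.prior, tolerance = 1e-6)
  expect_equal(mf$s0_sq, sv$var.prior, tolerance = 1e-6)
  expect_equal(unname(mf$s2_post), unname(sv$var.post),
               tolerance = 1e-6)
})

test_that("the F-scan is null-calibrated and catches planted shifts", {
  # essentially all-null study: uniform p for the flat genes
  sim <- generate_timecourse(sim_config(n_genes = 2000, frac_de = 0.001,
                                        seed = 71))
  mfit <- moderate_variances(fit_timecourse(sim$expr))
  fs <- global_f_test(mfit)
  null_p <- fs$p[fs$gene %in% sim$truth$gene[!sim$truth$is_de]]
  expect_gt(ks.test(null_p, "punif")$p.value, 0.01)
  # flat gene: F = 0, p = 1
  flat <- small_em(matrix(rep(1, 12), 2, 6,
                          dimnames = list(c("g1", "g2"))),
                   rep(c(0, 1, 2), each = 2), rep(1:2, 3))
  # build a moderated fit by hand around the flat gene
  fitf <- fit_timecourse(flat)
  fitf$s2[] <- 0.1; fitf$df[] <- 3; fitf$testable[] <- TRUE
  mff <- fitf; mff$d0 <- 10; mff$s0_sq <- 0.1
  mff$s2_post <- rep(0.1, 2)
  class(mff) <- c("ModeratedFit", "ModelFit")
  fsf <- global_f_test(mff)
  expect_equal(fsf$F, c(0, 0))
  expect_equal(fsf$p, c(1, 1))
  # a 10-sigma shift at one time-point is always detected
  M <- sim$expr$M
  sd1 <- sqrt(sim$truth$sigma2[1])
  shift_arrays <- sim$expr$design$time_point == 5
  M[1, shift_arrays] <- M[1, shift_arrays] + 10 * sd1
  mfit2 <- moderate_variances(fit_timecourse(
    expression_matrix(M, sim$expr$design)))
  fs2 <- global_f_test(mfit2)
  expect_lt(fs2$p_adj[fs2$gene == rownames(M)[1]], 1e-6)
})

test_that("the 2-day window yields exactly the expected contrast pairs", {
  tp <- c(0, 1, 2, 3, 4, 5, 7, 9, 11, 13)
  wp <- window_pairs(tp, 2)
  expected <- rbind(c(0, 1), c(0, 2), c(1, 2), c(1, 3), c(2, 3),
                    c(2, 4), c(3, 4), c(3, 5), c(4, 5), c(5, 7),
                    c(7, 9), c(9, 11), c(11, 13))
  got <- as.matrix(wp[, c("time_i", "time_j")])
  expect_equal(nrow(wp), 13)
  expect_setequal(paste(got[, 1], got[, 2]),
                  paste(expected[, 1], expected[, 2]))
  expect_error(window_pairs(tp, 0), "window")
})

test_that("windowed contrasts give t = 0, p = 1 for unchanged genes", {
  cfg <- sim_config(n_genes = 100, seed = 3)
  sim <- generate_timecourse(cfg)
  mfit <- moderate_variances(fit_timecourse(sim$expr))
  mfit$coef[5, ] <- 2.5   # force a perfectly flat fitted profile
  ct <- windowed_contrasts(mfit)
  g5 <- ct[ct$gene == rownames(mfit$coef)[5], ]
  expect_true(all(g5$t == 0))
  expect_true(all(g5$p == 1))
  expect_true(all(abs(ct$time_j - ct$time_i) <= 2))
  expect_true(all(ct$p_adj >= ct$p - 1e-15))
})

test_that("DEG thresholds are applied inclusively", {
  ct <- data.frame(gene = c("g1", "g2", "g3"),
                   time_i = 0, time_j = 1,
                   log2fc = c(log2(1.8), log2(1.6), log2(1.7)),
                   t = 5, p = c(1e-4, 1e-4, 2e-4),
                   p_adj = c(0.005, 0.005, 0.009))
  class(ct) <- c("ContrastTable", "data.frame")
  dt <- call_degs(ct)
  expect_true(dt$deg[dt$gene == "g1"])    # p 0.005, FC 1.8
  expect_false(dt$deg[dt$gene == "g2"])   # FC 1.6 below cutoff
  expect_true(dt$deg[dt$gene == "g3"])    # FC exactly 1.7: inclusive
  expect_equal(dt$direction[dt$gene == "g1"], "up")
})

test_that("tightening either threshold never adds DEGs", {
  cfg <- sim_config(n_genes = 800, seed = 19)
  sim <- generate_timecourse(cfg)
  ct <- windowed_contrasts(moderate_variances(fit_timecourse(sim$expr)))
  base <- call_degs(ct, alpha = 0.01, fc_min = 1.7)
  lower_alpha <- call_degs(ct, alpha = 0.001, fc_min = 1.7)
  higher_fc <- call_degs(ct, alpha = 0.01, fc_min = 2.5)
  expect_true(all(lower_alpha$gene[lower_alpha$deg] %in%
                    base$gene[base$deg]))
  expect_true(all(higher_fc$gene[higher_fc$deg] %in%
                    base$gene[base$deg]))
})

test_that("step-up adjustment matches the exhaustive reference", {
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BY"),
               rep(0.04 * 25 / 12, 4))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
  set.seed(11)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))
    expect_equal(adjust_pvalues(p, "BH"), ref_stepup(p, "BH"),
                 tolerance = 1e-12)
    expect_equal(adjust_pvalues(p, "BY"), ref_stepup(p, "BY"),
                 tolerance = 1e-12)
  }
})

test_that("planted DE pipeline controls FDR and finds strong effects", {
  called_false <- 0; called_total <- 0
  strong_found <- 0; strong_total <- 0
  for (s in 1:5) {
    cfg <- sim_config(n_genes = 2000, frac_de = 0.3, seed = 400 + s)
    sim <- generate_timecourse(cfg)
    ct <- windowed_contrasts(
      moderate_variances(fit_timecourse(sim$expr)))
    dt <- call_degs(ct)
    tr <- sim$truth[match(dt$gene, sim$truth$gene), ]
    called_false <- called_false + sum(dt$deg & !tr$is_de)
    called_total <- called_total + sum(dt$deg)
    strong <- tr$is_de & tr$max_window_lfc >= 1.5 &
      sqrt(tr$sigma2) <= 0.25
    strong_found <- strong_found + sum(dt$deg[strong])
    strong_total <- strong_total + sum(strong)
  }
  expect_lte(called_false / called_total, 0.05)
  expect_gte(strong_found / strong_total, 0.9)
})
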