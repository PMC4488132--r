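test_that("config validation rejects bad designs", {
  expect_error(sim_config(time_points = c(0, 1, 1)), "increasing")
  expect_error(sim_config(frac_de = 0), "frac_de")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(noise_prior = c(d0 = -1, s0_sq = 1)), "d0")
})

test_that("zero-noise limit returns the archetype means exactly", {
  cfg <- sim_config(n_genes = 200, noise_prior = c(d0 = 4, s0_sq = 0),
                    seed = 11)
  sim <- generate_timecourse(cfg)
  tp <- cfg$time_points
  for (r in 1:3) {
    arr <- sim$expr$design$array[sim$expr$design$replicate == r]
    expect_equal(unname(sim$expr$M[, arr]), unname(sim$profiles),
                 tolerance = 1e-12)
  }
})

test_that("the same seed reproduces the study byte for byte", {
  cfg <- sim_config(n_genes = 150, seed = 99)
  s1 <- generate_timecourse(cfg)
  s2 <- generate_timecourse(cfg)
  expect_identical(s1, s2)
  a1 <- generate_annotations(cfg, s1$truth, enrich_spec(15))
  a2 <- generate_annotations(cfg, s2$truth, enrich_spec(15))
  expect_identical(a1, a2)
  r1 <- generate_raw_two_channel(cfg, s1, dye_bias = 0.5)
  r2 <- generate_raw_two_channel(cfg, s2, dye_bias = 0.5)
  expect_identical(r1, r2)
})

test_that("frac_de fixes the planted DE fraction up to rounding", {
  cfg <- sim_config(n_genes = 2000, frac_de = 0.3, seed = 5)
  sim <- generate_timecourse(cfg)
  expect_equal(sum(sim$truth$is_de), round(0.3 * 2000))
  expect_true(all(sim$truth$is_de == (sim$truth$archetype != 0)))
  expect_true(all(is.na(sim$truth$cluster[!sim$truth$is_de])))
})

test_that("empirical per-gene variance converges to the drawn sigma^2", {
  cfg <- sim_config(n_genes = 100, n_replicates = 200, frac_de = 0.3,
                    seed = 21)
  sim <- generate_timecourse(cfg)
  fit <- fit_timecourse(sim$expr)
  ratio <- fit$s2 / sim$truth$sigma2
  expect_lt(abs(mean(ratio) - 1), 0.05)
  expect_gt(mean(abs(ratio - 1) < 0.10), 0.95)
})

test_that("identity raw-array configuration reproduces gene M exactly", {
  cfg <- sim_config(n_genes = 120, seed = 7)
  sim <- generate_timecourse(cfg)
  raw <- generate_raw_two_channel(cfg, sim, n_probes_per_gene = 1,
                                  background = 0, dye_bias = 0,
                                  probe_noise_sd = 0)
  raw <- compute_ma(background_subtract(raw))
  M <- raw$M[!raw$is_control, ]
  rownames(M) <- raw$gene[!raw$is_control]
  expect_equal(M, sim$expr$M, tolerance = 1e-9)
})

test_that("negative-control probes sit below the gene-probe intensities", {
  cfg <- sim_config(n_genes = 500, seed = 13)
  sim <- generate_timecourse(cfg)
  raw <- generate_raw_two_channel(cfg, sim)
  gene_fg <- raw$R_fg[!raw$is_control, 1]
  ctl_fg <- raw$R_fg[raw$is_control, 1]
  expect_lt(mean(ctl_fg), quantile(gene_fg, 0.05))
})

test_that("injected dye bias is recovered by regression on its basis", {
  b <- 0.8
  cfg <- sim_config(n_genes = 1500, frac_de = 0.1,
                    noise_prior = c(d0 = 20, s0_sq = 0.01), seed = 31)
  sim <- generate_timecourse(cfg)
  raw <- generate_raw_two_channel(cfg, sim, n_probes_per_gene = 1,
                                  background = 0, dye_bias = b)
  raw <- compute_ma(background_subtract(raw))
  null_probes <- raw$gene %in% sim$truth$gene[!sim$truth$is_de] &
    !raw$is_control
  M <- as.vector(raw$M[null_probes, ])
  f <- as.vector(dye_bias_basis(raw$A[null_probes, ]))
  slope <- coef(lm(M ~ f))[2]
  expect_equal(unname(slope), b, tolerance = 0.05)
})

test_that("null planting gives homogeneous annotated fractions", {
  cfg <- sim_config(n_genes = 3000, frac_de = 0.5, seed = 17)
  sim <- generate_timecourse(cfg)
  sp <- enrich_spec(15,
                    binding = list(list(tf = "TFnull",
                                        target_clusters = 1:3,
                                        odds_ratio = 1,
                                        background_rate = 0.2)))
  ann <- generate_annotations(cfg, sim$truth, sp)
  tr <- ann$truth
  tgt <- !is.na(tr$cluster) & tr$cluster %in% 1:3
  expect_lt(abs(mean(tr$bound_TFnull[tgt]) -
                  mean(tr$bound_TFnull[!tgt])), 0.04)
})

test_that("planted odds ratios are realized within 25 percent", {
  cfg <- sim_config(n_genes = 5000, frac_de = 0.5, seed = 23)
  sim <- generate_timecourse(cfg)
  ann <- generate_annotations(cfg, sim$truth)
  tr <- ann$truth
  for (layer in c("bound_TF1", "bound_TF2")) {
    tcl <- if (layer == "bound_TF1") 1:3 else 4:6
    tgt <- !is.na(tr$cluster) & tr$cluster %in% tcl
    p1 <- mean(tr[[layer]][tgt]); p0 <- mean(tr[[layer]][!tgt])
    or_emp <- (p1 / (1 - p1)) / (p0 / (1 - p0))
    expect_lt(abs(or_emp - 4) / 4, 0.25)
  }
})

test_that("paralog families hold the requested pairwise identity", {
  cfg <- sim_config(n_genes = 300, frac_de = 0.5, seed = 29)
  sim <- generate_timecourse(cfg)
  sp <- enrich_spec(15)
  sp$paralog$identity <- 0.95
  sp$paralog$family_size <- c(3, 3)
  ann <- generate_annotations(cfg, sim$truth, sp)
  fams <- Filter(function(f) length(f) == 3, ann$paralog_families)
  expect_gt(length(fams), 0)
  for (f in fams[seq_len(min(5, length(fams)))]) {
    seqs <- ann$proteome[f]
    for (i in 1:2) for (j in (i + 1):3)
      expect_gte(pairwise_identity(seqs[i], seqs[j]), 0.9)
  }
})

test_that("planted clusters peak in their designated atlas tissue", {
  cfg <- sim_config(n_genes = 1000, frac_de = 0.5, seed = 37)
  sim <- generate_timecourse(cfg)
  ann <- generate_annotations(cfg, sim$truth)
  tr <- ann$truth
  for (cc in c(1, 6)) {
    idx <- which(!is.na(tr$cluster) & tr$cluster == cc)
    mx <- colnames(ann$atlas)[max.col(ann$atlas[tr$gene[idx], ])]
    expect_gt(mean(mx == tr$peak_tissue[idx]), 0.9)
  }
})

test_that("infeasible planting requests name the offending layer", {
  cfg <- sim_config(n_genes = 200, frac_de = 0.5, seed = 3)
  sim <- generate_timecourse(cfg)
  sp <- enrich_spec(15,
                    binding = list(list(tf = "TFbad",
                                        target_clusters = 1,
                                        odds_ratio = -2,
                                        background_rate = 0.1)))
  expect_error(generate_annotations(cfg, sim$truth, sp), "TFbad")
})
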