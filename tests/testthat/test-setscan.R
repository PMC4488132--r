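test_that("strand-aware window rule resolves every boundary case", {
  bound <- assign_peaks_to_genes(fixture_peaks, fixture_genes)
  expect_true("gPlus" %in% bound)     # p1 within 3 kb upstream
  expect_true("gMinus" %in% bound)    # p2 upstream on - strand
  # p3 ends 100 bp short of the gPlus window; p4 abuts it exactly
  # (half-open: no overlap); without p1/p5/p8 gPlus would be unbound
  no_near <- fixture_peaks[c(3, 4), ]
  expect_false("gPlus" %in% assign_peaks_to_genes(no_near,
                                                  fixture_genes))
  # p5 overlaps the last base before the +1 kb window end
  expect_true("gPlus" %in%
                assign_peaks_to_genes(fixture_peaks[5, ],
                                      fixture_genes))
  # p6 overlaps the - strand downstream edge by one base
  expect_true("gNegDown" %in%
                assign_peaks_to_genes(fixture_peaks[6, ],
                                      fixture_genes))
  # clipped window at the chromosome start still catches p7
  expect_true("gClip" %in% bound)
  # the wide p8 annotates two genes at once, but not gFar
  hit8 <- assign_peaks_to_genes(fixture_peaks[8, ], fixture_genes)
  expect_setequal(hit8, c("gMid", "gNegDown"))
  expect_false("gFar" %in% bound)
})

test_that("exact-boundary peaks obey half-open coordinates", {
  # end exactly at window start: no overlap
  p <- data.frame(chrom = "Chr1", start = 6900L, end = 7000L)
  expect_length(assign_peaks_to_genes(p, fixture_genes), 0)
  # one base inside
  p$end <- 7001L
  expect_equal(assign_peaks_to_genes(p, fixture_genes), "gPlus")
  # start exactly at window end: no overlap
  p2 <- data.frame(chrom = "Chr1", start = 13000L, end = 13100L)
  expect_length(assign_peaks_to_genes(p2, fixture_genes), 0)
})

test_that("peak order and peak splitting do not change assignments", {
  bound <- assign_peaks_to_genes(fixture_peaks, fixture_genes)
  shuffled <- fixture_peaks[c(5, 2, 8, 1, 7, 3, 6, 4), ]
  expect_identical(assign_peaks_to_genes(shuffled, fixture_genes),
                   bound)
  split8 <- rbind(fixture_peaks[-8, ],
                  data.frame(chrom = "Chr1", start = c(29000L, 40000L),
                             end = c(40000L, 52000L),
                             name = c("p8a", "p8b")))
  expect_identical(assign_peaks_to_genes(split8, fixture_genes), bound)
})

test_that("malformed intervals are rejected with their line", {
  bad <- rbind(fixture_peaks[1:2, ],
               data.frame(chrom = "Chr1", start = 500L, end = 400L,
                          name = "pbad"))
  expect_error(assign_peaks_to_genes(bad, fixture_genes), "line 3")
})

test_that("degenerate annotation universes are never significant", {
  cl <- setNames(rep(1:2, each = 20), sprintf("g%d", 1:40))
  universe <- sprintf("g%d", 1:100)
  sat <- resampling_set_enrichment(cl, universe, universe, seed = 1)
  expect_true(all(sat$p_obs == 1 & sat$null_mean == 1))
  expect_true(all(!sat$significant) && all(sat$degenerate))
  empty <- resampling_set_enrichment(cl, character(0), universe,
                                     seed = 1)
  expect_true(all(empty$p_obs == 0 & empty$null_mean == 0))
  expect_true(all(!empty$significant))
})

test_that("resampled null matches the hypergeometric moments", {
  set.seed(77)
  universe <- sprintf("g%d", 1:5000)
  annot <- sample(universe, 500)
  planted <- c(sample(annot, 180), sample(setdiff(universe, annot),
                                          120))
  cl <- setNames(rep(1, 300), planted)
  er <- resampling_set_enrichment(cl, annot, universe, n_iter = 100,
                                  seed = 9)
  hm <- hyper_frac_moments(5000, 500, 300)
  expect_lt(abs(er$null_mean - hm["mean"]), 3 * hm["sd"] / sqrt(100))
  expect_lt(abs(er$null_sd - hm["sd"]) / hm["sd"], 0.25)
  # planted cluster at 60 % annotated vs 10 % background: z ~ 30
  expect_gt(er$z, 10)
  expect_true(er$significant)
  expect_equal(er$direction, "enriched")
  expect_equal(er$p_obs, 0.6)
})

test_that("random annotations are flagged in at most 2 % of tests", {
  universe <- sprintf("g%d", 1:2000)
  flags <- 0; total <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    cl <- setNames(sample(rep(1:15, length.out = 600)),
                   sample(universe, 600))
    annot <- sample(universe, 300)
    er <- resampling_set_enrichment(cl, annot, universe, n_iter = 100,
                                    seed = 2000 + s)
    flags <- flags + sum(er$significant)
    total <- total + nrow(er)
  }
  expect_lte(flags / total, 0.02)
})

test_that("cluster exceeding the universe is rejected", {
  cl <- setNames(rep(1, 5), sprintf("g%d", 1:5))
  expect_error(resampling_set_enrichment(cl, "g1", sprintf("g%d", 1:3)),
               "universe")
})

test_that("Fisher enrichment p equals the tail enumeration", {
  universe <- sprintf("g%d", 1:8)
  cluster <- universe[1:4]
  term_map <- list(T1 = universe[c(1, 2, 3, 5)])
  # table a=3 b=1 c=1 d=3: one-sided p = 17/70
  res <- go_enrichment(cluster, universe, term_map)
  expect_equal(res$p, 17 / 70, tolerance = 1e-12)
  expect_equal(res$p, fisher_tail_oracle(3, 1, 1, 3),
               tolerance = 1e-12)
  # term identical to a half-universe cluster: p = 1/C(100,50)
  u2 <- sprintf("h%d", 1:100)
  res2 <- go_enrichment(u2[1:50], u2, list(T = u2[1:50]))
  expect_equal(res2$p, 1 / choose(100, 50), tolerance = 1e-9)
  expect_true(res2$significant)
  # disjoint term: no evidence of enrichment
  res3 <- go_enrichment(u2[1:50], u2, list(T = u2[51:60]))
  expect_equal(res3$p, 1)
  # zero-universe terms are skipped and reported
  res4 <- go_enrichment(u2[1:10], u2, list(T = u2[1:5], Z = "nope"))
  expect_equal(attr(res4, "skipped"), "Z")
})

test_that("Fisher p matches enumeration across random small tables", {
  set.seed(3)
  for (i in 1:60) {
    N <- sample(4:60, 1)
    a <- sample(0:N, 1); b <- sample(0:(N - a), 1)
    cc <- sample(0:(N - a - b), 1); d <- N - a - b - cc
    if (a + b == 0 || a + cc == 0) next
    universe <- sprintf("u%d", 1:N)
    cluster <- universe[seq_len(a + b)]
    term <- universe[c(seq_len(a),
                       if (cc > 0) a + b + seq_len(cc) else integer(0))]
    res <- go_enrichment(cluster, universe, list(T = term))
    expect_equal(res$p, fisher_tail_oracle(a, b, cc, d),
                 tolerance = 1e-10)
  }
})

test_that("BY correction is applied across terms within a cluster", {
  universe <- sprintf("g%d", 1:40)
  cluster <- universe[1:10]
  tm <- list(A = universe[1:10], B = universe[11:20],
             C = universe[c(1:5, 21:25)], D = universe[31:40])
  res <- go_enrichment(cluster, universe, tm)
  expect_equal(sort(res$p_adj),
               sort(ref_stepup(res$p, "BY")), tolerance = 1e-12)
})

test_that("list overlap follows the hypergeometric tail", {
  u <- sprintf("g%d", 1:100)
  a <- u[1:10]; b <- u[10:19]    # overlap 1
  ov <- list_overlap_test(a, b, u)
  expect_equal(ov$overlap, 1)
  expect_equal(ov$expected, 1)
  expect_equal(ov$p, 1 - choose(90, 10) / choose(100, 10),
               tolerance = 1e-12)
  # identical lists: the smallest attainable p
  self <- list_overlap_test(a, a, u)
  expect_equal(self$p, 1 / choose(100, 10) *
                 sum(choose(10, 10) * choose(90, 0)), tolerance = 1e-9)
  # disjoint lists: large p
  dis <- list_overlap_test(u[1:10], u[11:20], u)
  expect_gte(dis$p, 0.5)
  expect_error(list_overlap_test(a, b, character(0)), "universe")
})
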