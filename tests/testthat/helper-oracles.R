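# Independent reference implementations used as oracles.  These are
# deliberately naive (loops, direct enumeration) and share no code with
# the package internals they check.

# step-up FDR adjustment from the definition: sort p, apply the step-up
# factor, enforce monotonicity from the largest rank down
ref_stepup <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  n <- length(p)
  ord <- order(p)
  cn <- if (method == "BY") sum(1 / seq_len(n)) else 1
  adj_sorted <- numeric(n)
  prev <- Inf
  for (i in n:1) {
    val <- min(1, cn * n / i * p[ord[i]], prev)
    adj_sorted[i] <- val
    prev <- val
  }
  out <- numeric(n)
  out[ord] <- adj_sorted
  out
}

# Smith-Waterman with affine gaps (Gotoh), gap of length L costs
# open + L * ext; returns the optimal local score
sw_oracle <- function(a, b, mat, open, ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)       # best ending in match/mismatch
  E <- matrix(-Inf, n + 1, m + 1)    # gap in A (consuming B)
  F <- matrix(-Inf, n + 1, m + 1)    # gap in B (consuming A)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      s <- H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]]
      H[i, j] <- max(0, s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# one-sided (enrichment) Fisher p by direct tail enumeration with
# binomial coefficients: table (a, b / c, d), tail over k >= a
fisher_tail_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  m <- a + c      # annotated in universe
  k <- a + b      # cluster size
  kmax <- min(m, k)
  denom <- choose(N, k)
  sum(vapply(a:kmax, function(x)
    choose(m, x) * choose(N - m, k - x), 0)) / denom
}

# hypergeometric mean and SD of the annotated fraction of a random
# n-subset drawn without replacement from a universe with K annotated
# of N genes
hyper_frac_moments <- function(N, K, n) {
  mu <- K / N
  v <- n * (K / N) * (1 - K / N) * (N - n) / (N - 1) / n^2
  c(mean = mu, sd = sqrt(v))
}

random_protein <- function(len) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
          "S","T","W","Y","V")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

pairwise_identity <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  stopifnot(length(a) == length(b))
  mean(a == b)
}

# small, fast low-noise study used by several clustering tests
lownoise_config <- function(n_genes = 900, seed = 42, k = 15) {
  sim_config(n_genes = n_genes, frac_de = 0.5, n_archetypes = k,
             noise_prior = c(d0 = 20, s0_sq = 0.01), seed = seed)
}

# hand-built fixture: six genes, eight peaks, both strands, all
# boundary cases of the -3 kb / +1 kb half-open window rule
# windows: gPlus [7000,13000)  gMinus [9000,15000)  gMid [27000,32000)
#          gNegDown [49000,54000)  gClip [0,2000)  gFar [67000,72000)
fixture_genes <- data.frame(
  gene = c("gPlus", "gMinus", "gMid", "gNegDown", "gClip", "gFar"),
  chrom = c("Chr1", "Chr2", "Chr1", "Chr1", "Chr3", "Chr1"),
  start = c(10000L, 10000L, 30000L, 50000L, 200L, 70000L),
  end = c(12000L, 12000L, 31000L, 51000L, 1000L, 71000L),
  strand = c("+", "-", "+", "-", "+", "+"))

fixture_peaks <- data.frame(
  chrom = c("Chr1", "Chr2", "Chr1", "Chr1", "Chr1", "Chr1", "Chr3",
            "Chr1"),
  start = c(8000L, 13500L, 6500L, 6990L, 12999L, 48900L, 0L, 29000L),
  end = c(8500L, 13600L, 6900L, 7000L, 13100L, 49001L, 100L, 52000L),
  name = paste0("p", 1:8))
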