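test_that("pair counts classify transitions and transversions correctly", {
  pc0 <- pair_counts("ACGT", "ACGT")
  expect_equal(c(pc0$P, pc0$Q), c(0, 0))

  pc_ts <- pair_counts("AAAA", "GAAA")
  expect_equal(pc_ts$n_ts, 1L)
  expect_equal(pc_ts$n_tv, 0L)

  pc_tv <- pair_counts("AAAA", "TAAA")
  expect_equal(pc_tv$n_tv, 1L)
  expect_equal(pc_tv$n_ts, 0L)

  # missing sites excluded pairwise; theta over both sequences
  pc <- pair_counts("ACG-", "ACGN")
  expect_equal(pc$n, 3L)
  expect_equal(pc$theta, 4 / 6)

  expect_error(pair_counts("--", "AA"), "no comparable sites")
})

test_that("p and T3P distances evaluate their formulas", {
  pc <- pair_counts("AAAT", "AAAA")
  expect_equal(p_distance(pc), 0.25)

  fake <- structure(list(n = 100, P = 0.1, Q = 0.05, theta = 0.5, h = 0.5),
                    class = "pair_counts")
  expect_equal(p_distance(fake), 0.15)
  expect_equal(t3p_distance(fake), -0.5 * log(0.75) - 0.25 * log(0.9),
               tolerance = 1e-12)
  expect_equal(t3p_distance(fake), 0.17018, tolerance = 1e-4)

  # saturation: log-domain violation errors
  sat <- structure(list(P = 0.6, Q = 0.3, theta = 0.5, h = 0.5),
                   class = "pair_counts")
  expect_error(t3p_distance(sat), "saturation")
})

test_that("T3P reduces to the K2P closed form at theta = 0.5", {
  for (PQ in list(c(0.1, 0.05), c(0.02, 0.01), c(0.2, 0.1))) {
    pc <- structure(list(P = PQ[1], Q = PQ[2], theta = 0.5, h = 0.5),
                    class = "pair_counts")
    expect_equal(t3p_distance(pc), oracle_k2p(PQ[1], PQ[2]),
                 tolerance = 1e-12)
  }
})

test_that("distances agree with the ape reference implementation", {
  skip_if_not_installed("ape")
  # p-distance on a random 4-sequence alignment
  seqs <- random_seqs(4, 300, seed = 5)
  aln <- make_aln(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- aln$ids
  expect_equal(unname(cr_dist(aln, "p")[lower.tri(diag(4))]),
               as.vector(ape::dist.dna(ape::as.DNAbin(m), model = "raw")),
               tolerance = 1e-12)
  # T3P on pairs at realistic divergences (ape estimates theta from the
  # whole alignment, so the comparison is per pair where the site sets
  # coincide exactly)
  for (d in c(0.05, 0.15, 0.3)) {
    sim <- simulate_alignment(n_groups = 2, samples_per_group = 1,
                              seq_length = 2000, theta_gc = 0.35,
                              within_div = 0, between_div = d,
                              seed = 600 + round(100 * d))
    s <- crhaplo:::aln_strings(sim$alignment)
    pm <- do.call(rbind, strsplit(unname(s), ""))
    rownames(pm) <- names(s)
    ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(pm), model = "T92"))
    expect_equal(t3p_distance(pair_counts(s[1], s[2])), ref,
                 tolerance = 1e-9)
  }
})

test_that("distance matrices are symmetric, and T3P >= p when defined", {
  seqs <- random_seqs(6, 120, seed = 9)
  aln <- make_aln(seqs)
  Dp <- cr_dist(aln, "p")
  # random sequences sit near saturation; the T3P log-domain guard reports it
  expect_warning(Dt <- cr_dist(aln, "t3p"), "saturated")
  expect_equal(Dp, t(Dp))
  expect_equal(Dt, t(Dt))
  ok <- !is.na(Dt)
  expect_true(all(Dt[ok] >= Dp[ok] - 1e-12))
})

test_that("group means equal a brute-force pair enumeration", {
  seqs <- random_seqs(6, 50, seed = 17)
  grp <- c("a", "a", "a", "b", "b", "b")
  aln <- make_aln(seqs, groups = grp)

  within_brute <- mean(c(oracle_p(seqs[1], seqs[2]),
                         oracle_p(seqs[1], seqs[3]),
                         oracle_p(seqs[2], seqs[3])))
  w <- group_mean_distance(aln, metric = "p", scope = "within", groups = "a")
  expect_equal(w$mean, within_brute * 100, tolerance = 1e-12)
  expect_equal(w$n_pairs, 3L)

  between_brute <- mean(outer(1:3, 4:6,
                              Vectorize(function(i, j) oracle_p(seqs[i], seqs[j]))))
  b <- group_mean_distance(aln, metric = "p", scope = "between",
                           groups = c("a", "b"))
  expect_equal(b$mean, between_brute * 100, tolerance = 1e-12)
  expect_equal(b$n_pairs, 9L)

  # two singleton groups: between mean is their pairwise distance
  aln2 <- make_aln(seqs[1:2], groups = c("x", "y"))
  b2 <- group_mean_distance(aln2, metric = "p", scope = "between",
                            groups = c("x", "y"))
  expect_equal(b2$mean, oracle_p(seqs[1], seqs[2]) * 100)

  # within-group of identical sequences is zero
  aln3 <- make_aln(rep(seqs[1], 3), groups = rep("z", 3))
  expect_equal(group_mean_distance(aln3, scope = "within", groups = "z")$mean, 0)
})

test_that("distance means on a haplotype set use unique haplotypes", {
  seqs <- c(rep("AAAA", 5), "AAAT", rep("TTTT", 2))
  grp <- c(rep("a", 6), "b", "b")
  aln <- make_aln(seqs, groups = grp)
  haps <- collapse_haplotypes(aln)
  w_all <- group_mean_distance(aln, scope = "within", groups = "a")
  w_hap <- group_mean_distance(haps, scope = "within", groups = "a")
  # unique haplotypes: single pair AAAA/AAAT -> 0.25; all samples dilute it
  expect_equal(w_hap$mean, 25)
  expect_true(w_all$mean < w_hap$mean)
})

test_that("column bootstrap is seeded, reproducible, and tracks the analytic SE", {
  # zero-variation alignment has SE exactly 0
  mono <- make_aln(rep("ACGTACGT", 3), groups = rep("g", 3))
  statf <- function(a) mean(cr_dist(a, "p")[upper.tri(diag(3))])
  expect_equal(bootstrap_se(statf, mono, 50, seed = 1), 0)

  aln <- make_aln(random_seqs(2, 100, seed = 3), groups = c("a", "b"))
  stat2 <- function(a) cr_dist(a, "p")[1, 2]
  s1 <- bootstrap_se(stat2, aln, 100, seed = 42)
  s2 <- bootstrap_se(stat2, aln, 100, seed = 42)
  expect_identical(s1, s2)
  expect_error(bootstrap_se(stat2, aln, 100), "seed")

  # analytic binomial oracle sqrt(p(1-p)/n) for the p-distance of one pair
  p <- stat2(aln)
  analytic <- sqrt(p * (1 - p) / 100)
  s_big <- bootstrap_se(stat2, aln, 2000, seed = 7)
  expect_lt(abs(s_big - analytic) / analytic, 0.20)
})

test_that("rate ratios reproduce the published marker comparisons", {
  # printed T3P(CR)/T3P(COI) column pairs and their printed ratios
  expect_equal(round(rate_ratio(6.58, 5.41), 2), 1.22)
  expect_equal(round(rate_ratio(7.00, 7.03), 2), 1.00)
  expect_equal(round(rate_ratio(6.61, 7.26), 2), 0.91)
  expect_equal(round(rate_ratio(11.50, 6.75), 1), 1.7)
  expect_equal(rate_ratio(5, 5), 1.0)
  expect_error(rate_ratio(5, 0), "division")
})

test_that("T3P recovers the generating divergence on simulated data", {
  for (true_d in c(0.01, 0.05, 0.15)) {
    sim <- simulate_alignment(n_groups = 2, samples_per_group = 1,
                              seq_length = 10000, theta_gc = 0.4, kappa = 4,
                              within_div = 0, between_div = true_d,
                              seed = 1000 + round(true_d * 1000))
    s <- crhaplo:::aln_strings(sim$alignment)
    pc <- pair_counts(s[1], s[2])
    est <- t3p_distance(pc)
    # delta-method analytic SE of the T3P estimator at the observed P, Q
    w1 <- 1 - pc$P / pc$h - pc$Q
    w2 <- 1 - 2 * pc$Q
    c1 <- 1 / w1
    c2 <- pc$h / w1 + (1 - pc$h) / w2
    se <- sqrt((c1^2 * pc$P + c2^2 * pc$Q -
                  (c1 * pc$P + c2 * pc$Q)^2) / pc$n)
    expect_lt(abs(est - true_d), 3 * se)
  }
})
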