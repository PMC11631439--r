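test_that("pairwise SNP counts use comparable loci and dosage differences", {
  gm <- toy_matrix()
  # a = (0,1,2,0,1), b = (0,2,2,1,1): differ at loci 2 and 4
  expect_equal(pairwise_snp_count(gm, "a", "b")$count, 2)
  expect_equal(pairwise_snp_count(gm, "a", "a")$count, 0)
  # c has a missing locus: only 4 comparable with a
  pc <- pairwise_snp_count(gm, "a", "c")
  expect_equal(pc$comparable, 4)
  expect_error(pairwise_snp_count(gm, "a", "nope"), "unknown")
  # disjoint missingness -> zero comparable loci, count 0
  gm2 <- genotype_matrix(matrix(c(1L, NA, NA, 2L), ncol = 2),
                         gm$loci[1:2, ], c("x", "y"))
  p0 <- pairwise_snp_count(gm2, "x", "y")
  expect_equal(c(p0$count, p0$comparable), c(0, 0))
})

test_that("pairwise distribution summarises pairs and scales by callable", {
  gm <- toy_matrix()
  pw <- pairwise_distribution(gm, callable_total = 1000)
  expect_equal(pw$n_pairs, 3)
  single <- pairwise_distribution(subset_genotypes(gm, samples = c("a", "b")))
  expect_equal(single$mean, pairwise_snp_count(gm, "a", "b")$count)
  expect_equal(pw$mean_fraction, pw$mean / 1000)
  # identical samples -> mean and sd zero
  gmid <- genotype_matrix(matrix(1L, 4, 3), toy_matrix()$loci[1:4, ],
                          c("p", "q", "r"))
  pwid <- pairwise_distribution(gmid)
  expect_equal(c(pwid$mean, pwid$sd), c(0, 0))
})

test_that("between-clade pairs exceed within-clade pairs on structured data", {
  cfg <- sim_config(k_clades = 2, n_per_clade = 8, n_admixed = 0, fst = 0.3,
                    n_loci = 500, ploidy_probs = c(0, 1, 0, 0),
                    homozygous_fraction = 0)
  gen <- simulate_genotypes(cfg, simulate_frequencies(cfg, 5), seed = 6)
  gm <- gen$matrix
  clade <- gen$truth$samples$clade
  pw <- pairwise_distribution(gm)
  same <- clade[match(pw$pairs$i, gm$samples)] ==
    clade[match(pw$pairs$j, gm$samples)]
  expect_gt(mean(pw$pairs$count[!same]), mean(pw$pairs$count[same]))
})

test_that("site pi matches the unbiased estimator and its invariances", {
  # 2 haploids with different alleles -> 1
  expect_equal(site_pi(c(0L, 1L), c(1L, 1L)), 1)
  # 4 copies with counts 2/2 -> (4/3)(1 - 1/2) = 2/3
  expect_equal(site_pi(c(1L, 1L), c(2L, 2L)), 2 / 3)
  expect_equal(site_pi(c(2L, 0L), c(2L, 2L)), 2 / 3)
  # monomorphic -> 0; single copy -> NA
  expect_equal(site_pi(c(2L, 2L), c(2L, 2L)), 0)
  expect_true(is.na(site_pi(c(1L), c(1L))))
  # allele-label swap invariance
  d <- c(0L, 1L, 2L, 2L); pl <- rep(2L, 4)
  expect_equal(site_pi(d, pl), site_pi(2L - d, pl))
  # sample relabeling invariance
  expect_equal(site_pi(d, pl), site_pi(rev(d), pl))
  # missing calls reduce n
  expect_equal(site_pi(c(1L, NA), c(2L, 2L)), site_pi(1L, 2L))
})

test_that("windowed pi uses the callable denominator and reports the median", {
  loci <- data.frame(chrom = "c1", pos = c(500, 15000), ref = "A", alt = "G")
  dos <- matrix(c(0L, 1L, 1L, 1L), 2, 2)  # site 1: pi (4/3)(1-5/8)=0.5
  gm <- genotype_matrix(dos, loci, c("x", "y"))
  tr <- windowed_pi(gm, c(c1 = 20000), window = 10000, step = 10000)
  # one SNP of known site pi in a 10,000-site window
  expect_equal(tr$pi[1], site_pi(dos[1, ], gm$ploidy) / 10000)
  expect_equal(tr$n_snps, c(1, 1))
  expect_equal(median_pi(tr), median(tr$pi))
  # empty window contributes 0
  loci2 <- data.frame(chrom = "c1", pos = 500, ref = "A", alt = "G")
  gm2 <- genotype_matrix(dos[1, , drop = FALSE], loci2, c("x", "y"))
  tr2 <- windowed_pi(gm2, c(c1 = 20000), window = 10000, step = 10000)
  expect_equal(tr2$pi[2], 0)
  # callable_fraction scales the denominator
  tr3 <- windowed_pi(gm, c(c1 = 20000), window = 10000, step = 10000,
                     callable_fraction = 0.5)
  expect_equal(tr3$pi[1], 2 * tr$pi[1])
})

test_that("median windowed pi tracks the simulated diversity level", {
  cfg <- sim_config(k_clades = 1, n_per_clade = 30, n_admixed = 0,
                    fst = 0.05, n_loci = 2000,
                    chrom_lengths = c(cA = 150000, cB = 50000),
                    ploidy_probs = c(0, 1, 0, 0), homozygous_fraction = 0)
  freqs <- simulate_frequencies(cfg, 8)
  gen <- simulate_genotypes(cfg, freqs, seed = 9)
  tr <- windowed_pi(gen$matrix, cfg$chrom_lengths)
  # expected per-site pi at a locus ~ 2 p (1-p); average over loci and
  # scale by SNP density
  esite <- mean(2 * freqs$ancestral * (1 - freqs$ancestral))
  expected <- esite * cfg$n_loci / sum(cfg$chrom_lengths)
  expect_lt(abs(median_pi(tr) - expected) / expected, 0.1)
})

test_that("rank correlation matches direct computation with ties", {
  expect_equal(rank_correlation(1:10, (1:10)^2)$rho, 1)
  expect_equal(rank_correlation(1:10, -(1:10))$rho, -1)
  x <- c(2, 2, 3, 4, 4, 7); y <- c(1, 3, 2, 5, 4, 6)
  rx <- rank(x); ry <- rank(y)
  manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(rank_correlation(x, y)$rho, manual)
  expect_error(rank_correlation(rep(1, 5), 1:5), "constant")
})

test_that("mean over all pairs equals the per-site exchangeable average", {
  set.seed(31)
  dos <- matrix(sample(0:2, 60, replace = TRUE), 10, 6)
  gm <- genotype_matrix(dos, data.frame(chrom = "c", pos = 1:10,
                                        ref = "A", alt = "G"),
                        paste0("s", 1:6))
  pw <- pairwise_distribution(gm)
  persite <- sum(apply(dos, 1, function(v) {
    pr <- utils::combn(6, 2)
    mean(v[pr[1, ]] != v[pr[2, ]])
  }))
  expect_equal(pw$mean, persite)
})
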