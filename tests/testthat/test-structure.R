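sim_gm <- function(dos, ploidy = 2L) {
  dos <- as.matrix(dos)
  storage.mode(dos) <- "integer"
  genotype_matrix(dos, data.frame(chrom = "c", pos = seq_len(nrow(dos)),
                                  ref = "A", alt = "G"),
                  paste0("s", seq_len(ncol(dos))),
                  ploidy = rep(ploidy, ncol(dos)))
}

test_that("MAF filter retains strictly above the threshold", {
  # 10 diploids: dosage columns built for exact frequencies
  dos <- rbind(c(1, rep(0, 9)),           # MAF 0.05 exactly -> dropped
               c(1, 1, 1, 1, 1, 1, rep(0, 4)),  # 0.30 -> kept
               rep(0, 10),                # monomorphic -> dropped
               c(2, 2, 1, rep(0, 7)))     # 0.25 -> kept
  gm <- sim_gm(t(t(dos)))
  out <- filter_biallelic_maf(gm, 0.05)
  expect_equal(n_loci(out), 2)
  expect_equal(out$loci$pos, c(2, 4))
})

test_that("LD pruning removes one of a duplicated pair and satisfies r2 bound", {
  set.seed(17)
  base <- matrix(rbinom(30 * 60, 2, 0.4), nrow = 30)
  base[5, ] <- base[4, ]  # duplicated locus, r2 = 1
  gm <- sim_gm(base)
  pruned <- ld_prune(gm, window = 10, step = 1, r2_max = 0.5)
  removed <- attr(pruned, "removed")
  expect_true(5 %in% removed)       # later locus of the pair goes
  expect_false(4 %in% removed)
  # postcondition: no surviving windowed pair above the bound
  dos <- pruned$dosage
  L <- nrow(dos)
  viol <- FALSE
  for (s in seq_len(max(1, L - 1))) {
    w <- s:min(s + 9, L)
    if (length(w) < 2) next
    r2 <- suppressWarnings(cor(t(dos[w, , drop = FALSE])))^2
    diag(r2) <- 0
    if (any(r2 > 0.5, na.rm = TRUE)) viol <- TRUE
  }
  expect_false(viol)
})

test_that("independent loci survive pruning", {
  set.seed(23)
  dos <- matrix(rbinom(40 * 500, 2, 0.5), nrow = 40)
  gm <- sim_gm(dos)
  pruned <- ld_prune(gm, window = 10, step = 1, r2_max = 0.5)
  expect_equal(n_loci(pruned), 40)
})

test_that("IBS distance matches hand-computed values", {
  # 4 loci x 3 samples
  dos <- matrix(c(0, 1, 2, 0,
                  0, 1, 2, 0,
                  2, 2, 0, 2), ncol = 3)
  gm <- sim_gm(dos)
  D <- ibs_distance(gm)
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_equal(D["s1", "s2"], 0)
  # s1 vs s3: |0-2|,|1-2|,|2-0|,|0-2| = 2,1,2,2 -> mean 7/4 / 2
  expect_equal(D["s1", "s3"], 7 / 8)
  expect_equal(D, t(D))
  # opposite homozygotes at every locus -> 1
  gm2 <- sim_gm(matrix(c(0, 0, 2, 2), ncol = 2))
  expect_equal(ibs_distance(gm2)["s1", "s2"], 1)
})

test_that("neighbor joining is exact on additive 4- and 8-taxon trees", {
  for (ntips in c(4, 8)) {
    set.seed(ntips)
    true <- ape::rtree(ntips, rooted = FALSE)
    true$edge.length <- runif(nrow(true$edge), 0.05, 0.5)
    D <- ape::cophenetic.phylo(true)
    est <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(true), est), 0,
                 ignore_attr = TRUE)
    # path lengths reproduce the input matrix
    D2 <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
    expect_lt(max(abs(D2 - D)), 1e-10)
  }
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
  Dna <- matrix(NA_real_, 3, 3); diag(Dna) <- 0
  expect_error(neighbor_joining(Dna), "incomplete")
})

test_that("NJ is invariant to taxon input order", {
  set.seed(5)
  true <- ape::rtree(6, rooted = FALSE)
  D <- ape::cophenetic.phylo(true)
  perm <- sample(rownames(D))
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("admixture EM: K=1 closed form and fixed-population recovery", {
  set.seed(12)
  dos <- matrix(rbinom(50 * 8, 2, 0.3), nrow = 50)
  gm <- sim_gm(dos)
  f1 <- admixture_em(gm, K = 1)
  expect_equal(unname(f1$Q[, 1]), rep(1, 8))
  expect_equal(as.numeric(f1$F), pmin(pmax(rowMeans(dos) / 2, 1e-6), 1 - 1e-6),
               tolerance = 1e-12)
  # two populations fixed for alternate alleles
  dos2 <- cbind(matrix(0L, 40, 4), matrix(2L, 40, 4))
  gm2 <- sim_gm(dos2)
  f2 <- admixture_em(gm2, K = 2, seed = 2)
  Q <- f2$Q
  memb <- apply(Q, 1, which.max)
  expect_equal(length(unique(memb[1:4])), 1)
  expect_true(memb[1] != memb[5])
  expect_true(all(abs(apply(Q, 1, max) - 1) < 1e-3))
  expect_error(admixture_em(gm2, K = 20), "exceeds")
})

test_that("EM log-likelihood is monotone and Q rows stay on the simplex", {
  cfg <- sim_config(k_clades = 2, n_per_clade = 10, n_admixed = 5,
                    fst = 0.2, n_loci = 300, ploidy_probs = c(0, 1, 0, 0),
                    homozygous_fraction = 0)
  gen <- simulate_genotypes(cfg, simulate_frequencies(cfg, 3), seed = 4)
  fit <- admixture_em(gen$matrix, K = 2, seed = 5)
  expect_true(all(diff(fit$trace) > -1e-6))
  expect_equal(unname(rowSums(fit$Q)), rep(1, nrow(fit$Q)), tolerance = 1e-8)
  expect_true(all(fit$Q >= 0 & fit$Q <= 1))
  expect_true(all(fit$F >= 1e-6 & fit$F <= 1 - 1e-6))
})

test_that("clade assignment applies the strict 60% rule", {
  Q <- rbind(c(0.61, 0.39), c(0.60, 0.40), c(1.0, 0.0), c(0.45, 0.55))
  rownames(Q) <- paste0("s", 1:4)
  asg <- assign_clades(Q, threshold = 0.60)
  expect_equal(asg$component, c(1L, NA, 1L, NA))
  expect_equal(asg$assigned, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("superclade grouping labels mapped clades and warns on unknown ids", {
  asg <- data.frame(sample = paste0("s", 1:4),
                    component = c(1L, 2L, 3L, NA),
                    max_q = c(0.9, 0.8, 0.7, 0.5),
                    assigned = c(TRUE, TRUE, TRUE, FALSE))
  out <- group_superclades(asg, list(A = c(1, 2), B = 3))
  expect_equal(out$superclade, c("A", "A", "B", NA))
  expect_warning(group_superclades(asg, list(A = c(1, 9))), "unknown clade")
  out0 <- group_superclades(asg, list())
  expect_true(all(is.na(out0$superclade)))
})
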