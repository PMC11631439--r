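test_that("carrier counts tally carriers and conserve the variant total", {
  dos <- matrix(c(1L, 0L, 0L,   # k = 1
                  1L, 1L, 0L,   # k = 2
                  2L, 1L, 1L,   # k = 3
                  0L, 0L, 1L),  # k = 1
                nrow = 4, byrow = TRUE)
  gm <- genotype_matrix(dos, data.frame(chrom = "c", pos = 1:4,
                                        ref = "A", alt = "G"),
                        c("s1", "s2", "s3"))
  cc <- carrier_counts(gm)
  expect_equal(cc$c_k, c(2L, 1L, 1L))
  expect_equal(sum(cc$c_k), 4)
  expect_equal(cc$c_k[1], 2)  # singletons
  expect_error(carrier_counts(genotype_matrix(matrix(integer(0), 0, 2),
    data.frame(chrom = character(0), pos = integer(0)), c("a", "b"))),
    "empty")
})

test_that("exact expected rarefaction matches closed-form toy cases", {
  # N = 4, one variant with k = 2 carriers, n = 2, non-singleton:
  # of the 6 pairs exactly one contains both carriers -> 1/6
  cc <- carrier_counts(2L, n_samples = 4)
  expect_equal(expected_rarefaction(cc, 2, min_carriers = 2), 1 / 6)
  # n = N recovers the observed counts
  expect_equal(expected_rarefaction(cc, 4, 1), 1)
  expect_equal(expected_rarefaction(cc, 4, 2), 1)
  # k = N: present in every subsample
  ccN <- carrier_counts(4L, n_samples = 4)
  expect_equal(expected_rarefaction(ccN, 1:4, 1), rep(1, 4))
  expect_error(expected_rarefaction(cc, 0, 1), "out of range")
})

test_that("exact expectation equals exhaustive subset enumeration (N <= 12)", {
  set.seed(41)
  for (N in c(6, 9, 12)) {
    dos <- matrix(rbinom(20 * N, 1, 0.25), nrow = 20)
    storage.mode(dos) <- "integer"
    gm <- genotype_matrix(dos, data.frame(chrom = "c", pos = 1:20,
                                          ref = "A", alt = "G"),
                          paste0("s", seq_len(N)), ploidy = rep(1L, N))
    cc <- carrier_counts(gm)
    for (mc in 1:2) {
      for (n in c(1, 2, N %/% 2, N)) {
        expect_equal(expected_rarefaction(cc, n, mc),
                     rarefaction_oracle(gm, n, mc), tolerance = 1e-12,
                     info = sprintf("N=%d n=%d mc=%d", N, n, mc))
      }
    }
  }
})

test_that("curves are monotone and non-singleton lies below all-variant", {
  cfg <- sim_config(k_clades = 2, n_per_clade = 10, n_admixed = 0,
                    n_loci = 400, ploidy_probs = c(0, 1, 0, 0))
  gen <- simulate_genotypes(cfg, simulate_frequencies(cfg, 2), seed = 3)
  cc <- carrier_counts(gen$matrix)
  c1 <- rarefaction_curve(cc, grid = 15, min_carriers = 1)
  c2 <- rarefaction_curve(cc, grid = 15, min_carriers = 2)
  expect_true(all(diff(c1$y) >= -1e-9))
  expect_true(all(diff(c2$y) >= -1e-9))
  expect_true(all(c2$y <= c1$y + 1e-9))
  # y(N) equals observed counts
  expect_equal(c1$y[nrow(c1)], sum(cc$c_k))
  expect_equal(c2$y[nrow(c2)], sum(cc$c_k[-1]))
})

test_that("Monte-Carlo rarefaction agrees with the exact expectation", {
  dos <- matrix(c(1L, 0L, 0L, 0L,
                  1L, 1L, 0L, 0L,
                  1L, 1L, 1L, 0L), nrow = 3, byrow = TRUE)
  gm <- genotype_matrix(dos, data.frame(chrom = "c", pos = 1:3,
                                        ref = "A", alt = "G"),
                        paste0("s", 1:4), ploidy = rep(1L, 4))
  cc <- carrier_counts(gm)
  mc <- monte_carlo_rarefaction(gm, 2, reps = 10000, seed = 5, min_carriers = 2)
  exact <- expected_rarefaction(cc, 2, 2)
  expect_lt(abs(mc$mean - exact), 3 * mc$se + 1e-9)
  # reps = 1 at n = N gives the observed count exactly
  expect_equal(monte_carlo_rarefaction(gm, 4, reps = 1, seed = 1)$mean, 3)
  # fixed seed reproducibility
  expect_identical(monte_carlo_rarefaction(gm, 2, reps = 50, seed = 9),
                   monte_carlo_rarefaction(gm, 2, reps = 50, seed = 9))
})

test_that("subsample-level singleton semantics differ from pre-filtering", {
  # a variant with 2 carriers among N=4 is a non-singleton of the full
  # population, but in a subsample of 2 it usually appears once: the
  # expectation under min_carriers=2 (1/6) is below the rarefaction of the
  # pre-filtered non-singleton set under min_carriers=1
  cc <- carrier_counts(2L, n_samples = 4)
  expect_lt(expected_rarefaction(cc, 2, 2), expected_rarefaction(cc, 2, 1))
  expect_equal(expected_rarefaction(cc, 2, 1), 1 - choose(2, 2) / choose(4, 2))
})

test_that("power-law fit recovers noise-free parameters", {
  x <- c(5, 10, 20, 50, 100, 200, 500, 1000)
  y <- 242965 * x^0.276 - 288549 + 3e5  # shifted into positive range
  fit <- fit_power_law(data.frame(n = x, y = y))
  expect_true(fit$converged)
  expect_equal(unname(fit$params["a"]), 242965, tolerance = 1e-4)
  expect_equal(unname(fit$params["b"]), 0.276, tolerance = 1e-4)
  expect_identical(fit$asymptote, Inf)
  expect_error(fit_power_law(data.frame(n = 1:3, y = 1:3)), "4 grid points")
})

test_that("Michaelis-Menten fit recovers parameters and identities", {
  x <- c(2, 5, 10, 25, 50, 120, 300)
  y <- 1000 * x / (50 + x)
  fit <- fit_michaelis_menten(data.frame(n = x, y = y))
  expect_equal(unname(fit$params["Vmax"]), 1000, tolerance = 1e-6)
  expect_equal(unname(fit$params["K"]), 50, tolerance = 1e-6)
  # half-saturation identity y(K) = Vmax / 2
  expect_equal(fit$fitted(unname(fit$params["K"])), unname(fit$params["Vmax"]) / 2)
  expect_equal(fit$asymptote, 1000, tolerance = 1e-6)
  # Vmax bias shrinks with noise (two noise levels)
  set.seed(7)
  noisy <- function(s) {
    yy <- y * (1 + rnorm(length(y), 0, s))
    abs(fit_michaelis_menten(data.frame(n = x, y = yy))$asymptote - 1000)
  }
  expect_lt(mean(replicate(20, noisy(0.002))), mean(replicate(20, noisy(0.05))))
})

test_that("coverage fraction uses the MM asymptote and refuses power laws", {
  x <- c(2, 5, 10, 25, 50, 120, 300)
  fit <- fit_michaelis_menten(data.frame(n = x, y = 1000 * x / (50 + x)))
  # fitted_at_N mode on exact MM data gives N / (K + N)
  cv <- coverage_fraction(fit, observed_count = NA, N = 100,
                          numerator_mode = "fitted_at_N")
  expect_equal(cv$fraction, 100 / 150, tolerance = 1e-6)
  # observed equal to Vmax -> 1
  expect_equal(coverage_fraction(fit, 1000, 100)$fraction, 1, tolerance = 1e-6)
  pl <- fit_power_law(data.frame(n = x, y = 5 * x^0.5))
  expect_error(coverage_fraction(pl, 10, 100), "infinity")
})

test_that("MM extrapolation recovers a clade-structured species pool", {
  # species pool: every locus of a clade-structured population eventually
  # reaches two carriers; the sampled panel sees only part of it
  cfg <- sim_config(k_clades = 10, n_per_clade = 15, n_admixed = 0,
                    fst = 0.5, n_loci = 20000,
                    ancestral_range = c(0.01, 0.3),
                    ploidy_probs = c(0, 1, 0, 0), homozygous_fraction = 0)
  gen <- simulate_genotypes(cfg, simulate_frequencies(cfg, 2), seed = 3)
  cc <- carrier_counts(gen$matrix)
  curve <- rarefaction_curve(cc, grid = 50, min_carriers = 2)
  fit <- fit_michaelis_menten(curve)
  obs <- sum(cc$c_k[-1])
  est <- coverage_fraction(fit, obs, cc$N)$fraction
  truth <- obs / cfg$n_loci
  expect_lt(abs(est - truth), 0.05)
})
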