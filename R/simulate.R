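#' Configuration of the synthetic population generator
#'
#' Defines a clade-structured population in the style of a yeast
#' resequencing panel: K clades diverged from a common ancestral allele
#' frequency under the Balding-Nichols model (divergence F), plus admixed
#' individuals with Dirichlet ancestry; mixed ploidy (1n-4n); a
#' homozygous-regime fraction mimicking selfed/homothallic isolates; CNV
#' segments and whole-chromosome aneuploidies driving the depth
#' simulation; and binomial allelic read counts at heterozygous sites.
#'
#' Defaults follow the composition reported for large S. cerevisiae
#' panels: 74% diploids, 6% haploids, 20% polyploids (split between 3n
#' and 4n), 42% homozygous isolates, and a four-chromosome toy genome of
#' 1,500/1,000/600/300 kb that reproduces the short-chromosome aneuploidy
#' bias at toy scale.
#'
#' @param k_clades number of clades.
#' @param n_per_clade samples per clade.
#' @param n_admixed additional admixed samples.
#' @param fst Balding-Nichols divergence F in (0,1).
#' @param n_loci number of SNP loci.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param ancestral_range range of the uniform ancestral frequency draw.
#' @param ploidy_probs probabilities of ploidy 1..4 per sample.
#' @param homozygous_fraction fraction of samples in the homozygous
#'   regime (all calls homozygous).
#' @param coverage mean sequencing depth.
#' @param depth_dispersion negative-binomial size parameter of the
#'   per-window read counts (extra-Poisson noise; the default 100 gives a
#'   window-depth coefficient of variation near 10% at 30x, typical of
#'   short-read bin depths).
#' @param read_length read length (bp) converting coverage to window read
#'   counts.
#' @param cnv_truth data.frame(sample, chrom, start, end, ratio) of CNV
#'   segments (0-based half-open, bp), or NULL for the default single
#'   1.5x segment in sample 1.
#' @param aneuploidy_truth data.frame(sample, chrom, ratio) of
#'   whole-chromosome events, or NULL for the default chrIV gain in
#'   sample 2.
#' @param n_cds number of coding sequences to lay down.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(k_clades = 3, n_per_clade = 30, n_admixed = 10,
                       fst = 0.2, n_loci = 3000,
                       chrom_lengths = c(chrI = 1500000, chrII = 1000000,
                                         chrIII = 600000, chrIV = 300000),
                       ancestral_range = c(0.05, 0.95),
                       ploidy_probs = c(0.06, 0.74, 0.12, 0.08),
                       homozygous_fraction = 0.42,
                       coverage = 30, depth_dispersion = 100,
                       read_length = 150,
                       cnv_truth = NULL, aneuploidy_truth = NULL,
                       n_cds = 200) {
  stopifnot(fst > 0, fst < 1, k_clades >= 1, n_loci >= 1,
            abs(sum(ploidy_probs) - 1) < 1e-8,
            homozygous_fraction >= 0, homozygous_fraction <= 1)
  n_samples <- k_clades * n_per_clade + n_admixed
  samples <- sprintf("S%03d", seq_len(n_samples))
  if (is.null(cnv_truth)) {
    ch2 <- min(2, length(chrom_lengths))
    len2 <- chrom_lengths[[ch2]]
    cnv_truth <- data.frame(sample = samples[1],
                            chrom = names(chrom_lengths)[ch2],
                            start = 1000 * floor(0.10 * len2 / 1000),
                            end = 1000 * floor(0.15 * len2 / 1000),
                            ratio = 1.5, stringsAsFactors = FALSE)
  }
  if (is.null(aneuploidy_truth))
    aneuploidy_truth <- data.frame(sample = samples[2],
                                   chrom = names(chrom_lengths)[length(chrom_lengths)],
                                   ratio = 1.5, stringsAsFactors = FALSE)
  structure(list(k_clades = k_clades, n_per_clade = n_per_clade,
                 n_admixed = n_admixed, fst = fst, n_loci = n_loci,
                 chrom_lengths = chrom_lengths,
                 ancestral_range = ancestral_range,
                 ploidy_probs = ploidy_probs,
                 homozygous_fraction = homozygous_fraction,
                 coverage = coverage, depth_dispersion = depth_dispersion,
                 read_length = read_length,
                 cnv_truth = cnv_truth, aneuploidy_truth = aneuploidy_truth,
                 n_cds = n_cds, samples = samples),
            class = "sim_config")
}

#' Draw ancestral and per-clade allele frequencies
#'
#' Ancestral frequencies p_l are uniform on the configured range;
#' per-clade frequencies follow the Balding-Nichols model,
#' f_kl ~ Beta(p_l (1-F)/F, (1-p_l)(1-F)/F), independently per clade, so
#' that E[f_kl] = p_l and Var[f_kl] = F p_l (1 - p_l).
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return list: `ancestral` (length n_loci), `clade` (K x n_loci matrix).
#' @export
simulate_frequencies <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    p <- stats::runif(cfg$n_loci, cfg$ancestral_range[1], cfg$ancestral_range[2])
    a <- p * (1 - cfg$fst) / cfg$fst
    b <- (1 - p) * (1 - cfg$fst) / cfg$fst
    f <- t(vapply(seq_len(cfg$k_clades), function(k)
      stats::rbeta(cfg$n_loci, a, b), numeric(cfg$n_loci)))
    list(ancestral = p, clade = f)
  })
}

#' Simulate genotypes and truth tables
#'
#' Pure-clade samples have one-hot ancestry; admixed samples draw their Q
#' row from a symmetric Dirichlet. Sample i with ploidy m_i draws its
#' dosage at locus l as Binomial(m_i, sum_k q_ik f_kl); samples in the
#' homozygous regime instead draw all m_i copies of a single allele, so
#' they carry no heterozygous genotypes. Haploids are homozygous by
#' construction.
#'
#' @param cfg a [sim_config()].
#' @param freqs result of [simulate_frequencies()].
#' @param seed RNG seed.
#' @return list: `matrix` (a [genotype_matrix()]), `truth` (list with
#'   per-sample data.frame `samples` (clade, ploidy, regime), `Q`, clade
#'   frequencies, and totals: n_variants, n_non_singleton).
#' @export
simulate_genotypes <- function(cfg, freqs, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  K <- cfg$k_clades
  ns <- length(cfg$samples)
  with_seed(seed, {
    clade <- rep(c(seq_len(K), NA), c(rep(cfg$n_per_clade, K), cfg$n_admixed))
    Q <- matrix(0, ns, K)
    for (i in seq_len(ns)) {
      if (!is.na(clade[i])) Q[i, clade[i]] <- 1
      else {
        g <- stats::rgamma(K, 1)
        Q[i, ] <- g / sum(g)
      }
    }
    ploidy <- sample(1:4, ns, replace = TRUE, prob = cfg$ploidy_probs)
    homozygous <- stats::runif(ns) < cfg$homozygous_fraction
    P <- Q %*% freqs$clade                    # ns x n_loci expected freq
    dosage <- matrix(0L, cfg$n_loci, ns)
    for (i in seq_len(ns)) {
      dosage[, i] <- if (homozygous[i] || ploidy[i] == 1L)
        ploidy[i] * stats::rbinom(cfg$n_loci, 1, P[i, ])
      else
        stats::rbinom(cfg$n_loci, ploidy[i], P[i, ])
    }
    loci <- layout_loci(cfg)
    gm <- genotype_matrix(dosage, loci, cfg$samples, ploidy = ploidy)
    carriers <- rowSums(dosage >= 1L)
    truth <- list(
      samples = data.frame(sample = cfg$samples, clade = clade,
                           ploidy = ploidy, homozygous = homozygous,
                           stringsAsFactors = FALSE),
      Q = Q,
      clade_freqs = freqs$clade,
      n_variants = sum(carriers >= 1),
      n_non_singleton = sum(carriers >= 2))
    list(matrix = gm, truth = truth)
  })
}

# sorted SNP positions allocated to chromosomes proportionally to length
layout_loci <- function(cfg) {
  lens <- cfg$chrom_lengths
  n_per <- round(cfg$n_loci * lens / sum(lens))
  n_per[length(n_per)] <- cfg$n_loci - sum(n_per[-length(n_per)])
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_along(lens), function(ci) {
    pos <- sort(sample.int(lens[ci] - 1, n_per[ci])) + 1L
    ref <- sample(bases, n_per[ci], replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    data.frame(chrom = names(lens)[ci], pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate per-window sequencing depth
#'
#' Per-sample, per-1-kb-window depths are negative binomial: the window's
#' read count is NB with mean coverage x copy_ratio(window) x
#' window / read_length and the configured dispersion, scaled back to a
#' mean depth. Simulating at read-count resolution keeps the relative
#' noise of window means realistic (about 10% at 30x) instead of the
#' per-base Poisson scale. The copy ratio comes from the sample's CNV and
#' aneuploidy truth (1 elsewhere).
#'
#' @param cfg a [sim_config()].
#' @param sample sample id.
#' @param seed RNG seed.
#' @return a [depth_profile()].
#' @export
simulate_depth <- function(cfg, sample, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  lens <- cfg$chrom_lengths
  wins <- do.call(rbind, lapply(names(lens), function(ch) {
    starts <- seq(0, lens[[ch]] - 1, by = 1000)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + 1000, lens[[ch]]),
               stringsAsFactors = FALSE)
  }))
  ratio <- rep(1, nrow(wins))
  an <- cfg$aneuploidy_truth
  an <- an[an$sample == sample, , drop = FALSE]
  for (i in seq_len(nrow(an)))
    ratio[wins$chrom == an$chrom[i]] <- an$ratio[i]
  cnv <- cfg$cnv_truth
  cnv <- cnv[cnv$sample == sample, , drop = FALSE]
  for (i in seq_len(nrow(cnv))) {
    hit <- wins$chrom == cnv$chrom[i] & wins$start < cnv$end[i] &
      wins$end > cnv$start[i]
    ratio[hit] <- cnv$ratio[i]
  }
  with_seed(seed, {
    width <- wins$end - wins$start
    reads <- stats::rnbinom(nrow(wins), size = cfg$depth_dispersion,
                            mu = cfg$coverage * ratio * width / cfg$read_length)
    wins$depth <- reads * cfg$read_length / width
    depth_profile(wins, sample = sample)
  })
}

#' Simulate alternate-allele read fractions at heterozygous sites
#'
#' At each heterozygous site of a sample (dosage d of m copies), the
#' alternate read count is Binomial(site coverage, d/m) and the fraction
#' alt/coverage; fractions at 0 or 1 (no read of one allele) are dropped,
#' as are fractions outside the retention interval. Site coverages are
#' Poisson around the configured mean.
#'
#' @param gm a [genotype_matrix()] from [simulate_genotypes()].
#' @param sample sample id.
#' @param coverage mean site coverage.
#' @param seed RNG seed.
#' @param retain open retention interval (default (0.1, 0.9)).
#' @return a [base_frequency_sample()].
#' @export
simulate_allele_fractions <- function(gm, sample, coverage = 30, seed = 1,
                                      retain = c(0.1, 0.9)) {
  stopifnot(inherits(gm, "genotype_matrix"))
  j <- match(sample, gm$samples)
  if (is.na(j)) stop("unknown sample: ", sample)
  m <- gm$ploidy[j]
  d <- gm$dosage[, j]
  het <- which(!is.na(d) & d > 0L & d < m)
  with_seed(seed, {
    cov <- pmax(1, stats::rpois(length(het), coverage))
    alt <- stats::rbinom(length(het), cov, d[het] / m)
    frac <- alt / cov
    keep <- frac > retain[1] & frac < retain[2]
    base_frequency_sample(sample, frac[keep], cov[keep])
  })
}

#' Simulate a labelled allele-fraction sample of known ploidy
#'
#' Benchmark-grade generator for the ploidy criteria: heterozygous-site
#' dosages are drawn uniformly from 1..(ploidy-1) and read counts are
#' binomial at the given coverage; fractions outside the retention
#' interval are dropped.
#'
#' @param ploidy true ploidy (2, 3 or 4).
#' @param n_sites number of heterozygous sites.
#' @param coverage site coverage (fixed).
#' @param seed RNG seed.
#' @param retain open retention interval.
#' @return a [base_frequency_sample()] with attribute `true_ploidy`.
#' @export
simulate_fraction_sample <- function(ploidy, n_sites = 2000, coverage = 100,
                                     seed = 1, retain = c(0.1, 0.9)) {
  stopifnot(ploidy %in% 2:4)
  with_seed(seed, {
    d <- sample(seq_len(ploidy - 1), n_sites, replace = TRUE)
    alt <- stats::rbinom(n_sites, coverage, d / ploidy)
    frac <- alt / coverage
    keep <- frac > retain[1] & frac < retain[2]
    out <- base_frequency_sample(sprintf("sim%dn", ploidy), frac[keep],
                                 rep(coverage, sum(keep)))
    attr(out, "true_ploidy") <- ploidy
    out
  })
}

#' Lay down coding sequences on the toy genome
#'
#' Non-overlapping CDS intervals of 900-1,800 bp placed uniformly,
#' allocated to chromosomes proportionally to length.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return data.frame: chrom, start, end, name (BED-style, 0-based).
#' @export
simulate_cds <- function(cfg, seed = 1) {
  lens <- cfg$chrom_lengths
  n_per <- pmax(1, round(cfg$n_cds * lens / sum(lens)))
  with_seed(seed, {
    out <- lapply(seq_along(lens), function(ci) {
      n <- n_per[ci]
      slot <- floor(lens[[ci]] / n)
      width <- sample(900:1800, n, replace = TRUE)
      width <- pmin(width, slot - 10)
      start <- (seq_len(n) - 1) * slot +
        vapply(slot - width, function(s) sample.int(max(s, 1), 1), integer(1))
      data.frame(chrom = names(lens)[ci], start = start,
                 end = start + width, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out$name <- sprintf("CDS%04d", seq_len(nrow(out)))
    out
  })
}

#' Simulate a complete population
#'
#' Convenience wrapper chaining [simulate_frequencies()],
#' [simulate_genotypes()], per-sample [simulate_depth()] (only for
#' samples carrying CNV/aneuploidy truth plus a configurable number of
#' background samples) and [simulate_cds()].
#'
#' @param cfg a [sim_config()].
#' @param seed master seed; stage seeds are derived deterministically.
#' @param depth_samples sample ids to simulate depth for; defaults to the
#'   samples named in the CNV/aneuploidy truth plus the first two others.
#' @return list: cfg, freqs, matrix, truth, cds, depth (named list of
#'   [depth_profile()]s).
#' @export
simulate_population <- function(cfg = sim_config(), seed = 1,
                                depth_samples = NULL) {
  freqs <- simulate_frequencies(cfg, seed = seed)
  gen <- simulate_genotypes(cfg, freqs, seed = seed + 1)
  cds <- simulate_cds(cfg, seed = seed + 2)
  if (is.null(depth_samples))
    depth_samples <- unique(c(cfg$cnv_truth$sample, cfg$aneuploidy_truth$sample,
                              utils::head(setdiff(cfg$samples,
                                c(cfg$cnv_truth$sample,
                                  cfg$aneuploidy_truth$sample)), 2)))
  depth <- lapply(stats::setNames(nm = depth_samples), function(s)
    simulate_depth(cfg, s, seed = seed + 3 + match(s, cfg$samples)))
  list(cfg = cfg, freqs = freqs, matrix = gen$matrix, truth = gen$truth,
       cds = cds, depth = depth)
}
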