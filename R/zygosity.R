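#' Count heterozygous SNPs for a sample
#'
#' Number of retained SNP loci at which the sample's genotype carries at
#' least two distinct alleles; missing calls are skipped.
#'
#' @param x a [genotype_matrix()].
#' @param sample sample id or column index.
#' @return integer count.
#' @export
count_het_snps <- function(x, sample) {
  stopifnot(inherits(x, "genotype_matrix"))
  j <- if (is.character(sample)) match(sample, x$samples) else sample
  if (is.na(j) || j < 1 || j > length(x$samples))
    stop("unknown sample: ", sample)
  sum(het_matrix(x)[, j], na.rm = TRUE)
}

#' Classify a sample as heterozygous or homozygous
#'
#' A sample is heterozygous when its heterozygous-SNP count strictly
#' exceeds the threshold (default 500); otherwise homozygous. The
#' heterozygosity rate is the het-SNP count over the total number of
#' callable sites.
#'
#' @param n_het heterozygous SNP count.
#' @param callable_total total callable sites (ledger total).
#' @param threshold het-SNP count above which a sample is heterozygous.
#' @param sample optional sample id carried through.
#' @return object of class `zygosity_call`: list(sample, n_het,
#'   het_fraction, zygosity, threshold).
#' @export
classify_zygosity <- function(n_het, callable_total, threshold = 500,
                              sample = NA_character_) {
  stopifnot(callable_total > 0, n_het >= 0)
  structure(list(sample = sample,
                 n_het = as.integer(n_het),
                 het_fraction = n_het / callable_total,
                 zygosity = if (n_het > threshold) "heterozygous" else "homozygous",
                 threshold = threshold),
            class = "zygosity_call")
}

#' Zygosity table for all samples
#'
#' @param x a [genotype_matrix()].
#' @param callable_total ledger total of callable sites.
#' @param threshold het-SNP threshold (default 500).
#' @return data.frame: sample, n_het, het_fraction, zygosity.
#' @export
zygosity_table <- function(x, callable_total, threshold = 500) {
  stopifnot(inherits(x, "genotype_matrix"))
  hm <- het_matrix(x)
  n_het <- colSums(hm, na.rm = TRUE)
  data.frame(sample = x$samples,
             n_het = as.integer(n_het),
             het_fraction = n_het / callable_total,
             zygosity = ifelse(n_het > threshold, "heterozygous", "homozygous"),
             stringsAsFactors = FALSE)
}

#' Extract alternate-allele read fractions at heterozygous sites
#'
#' Builds the allelic read-fraction sample that ploidy inference consumes:
#' at each biallelic heterozygous SNP call of the sample with AD coverage
#' at or above `min_cov`, the fraction alt_reads / (ref_reads + alt_reads).
#' Fractions outside the open retention interval are dropped (extreme
#' fractions are dominated by mapping and sequencing artefacts).
#'
#' @param vs a `variant_set` with AD.
#' @param sample sample id.
#' @param min_cov minimum site coverage (default 10).
#' @param retain open retention interval for fractions, default (0.1, 0.9).
#' @return object of class `base_frequency_sample`: list(sample, fractions,
#'   coverages).
#' @export
extract_base_frequencies <- function(vs, sample, min_cov = 10,
                                     retain = c(0.1, 0.9)) {
  stopifnot(inherits(vs, "variant_set"))
  j <- match(sample, vs$samples)
  if (is.na(j)) stop("unknown sample: ", sample)
  snp <- vs$sites$locus_class == "snp" & !grepl(",", vs$sites$alt, fixed = TRUE)
  gt <- vs$gt[snp, j]
  ad <- vs$ad[snp, j]
  het <- !is.na(gt) & vapply(gt, function(g) {
    al <- strsplit(g, "[/|]")[[1]]
    length(unique(al)) > 1
  }, logical(1))
  ad <- ad[het]
  counts <- t(vapply(ad, function(a) {
    if (is.na(a)) return(c(NA_real_, NA_real_))
    v <- suppressWarnings(as.numeric(strsplit(a, ",", fixed = TRUE)[[1]]))
    c(v[1], v[2])
  }, numeric(2)))
  if (!length(ad)) counts <- matrix(numeric(0), 0, 2)
  cov <- counts[, 1] + counts[, 2]
  frac <- counts[, 2] / cov
  keep <- !is.na(cov) & cov >= min_cov & frac > retain[1] & frac < retain[2]
  base_frequency_sample(sample, frac[keep], cov[keep])
}

#' @rdname extract_base_frequencies
#' @param fractions numeric vector in (0,1).
#' @param coverages numeric vector of site coverages.
#' @export
base_frequency_sample <- function(sample, fractions, coverages = rep(NA_real_, length(fractions))) {
  stopifnot(length(fractions) == length(coverages),
            all(fractions > 0 & fractions < 1))
  structure(list(sample = sample, fractions = as.numeric(fractions),
                 coverages = as.numeric(coverages)),
            class = "base_frequency_sample")
}

#' @export
#' @method print base_frequency_sample
print.base_frequency_sample <- function(x, ...) {
  cat("base_frequency_sample '", x$sample, "': ", length(x$fractions),
      " het-site allele fractions\n", sep = "")
  invisible(x)
}
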