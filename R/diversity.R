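#' Number of SNP differences between two samples
#'
#' Counts the loci at which both samples have non-missing genotypes and
#' their alternate-allele dosages differ; any difference at a site counts
#' as one SNP site (heterozygous vs homozygous included).
#'
#' @param x a [genotype_matrix()].
#' @param sample_i,sample_j sample ids or column indices.
#' @return list: count, comparable (number of loci compared).
#' @export
pairwise_snp_count <- function(x, sample_i, sample_j) {
  stopifnot(inherits(x, "genotype_matrix"))
  i <- if (is.character(sample_i)) match(sample_i, x$samples) else sample_i
  j <- if (is.character(sample_j)) match(sample_j, x$samples) else sample_j
  if (is.na(i) || is.na(j)) stop("unknown sample id")
  a <- x$dosage[, i]; b <- x$dosage[, j]
  ok <- !is.na(a) & !is.na(b)
  list(count = sum(a[ok] != b[ok]), comparable = sum(ok))
}

#' Distribution of pairwise SNP counts over random sample pairs
#'
#' Samples unordered sample pairs uniformly without replacement (or all
#' pairs) and summarises the per-pair SNP-difference counts, also as
#' fractions of callable sites.
#'
#' @param x a [genotype_matrix()].
#' @param n_pairs number of pairs, or "all".
#' @param seed RNG seed for pair sampling.
#' @param callable_total callable-site total for the fraction scale.
#' @return object of class `pairwise_summary`: list(pairs data.frame
#'   (i, j, count), n_pairs, mean, sd, max, mean_fraction, max_fraction).
#' @export
pairwise_distribution <- function(x, n_pairs = "all", seed = 1,
                                  callable_total = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  ns <- length(x$samples)
  if (ns < 2) stop("at least 2 samples required")
  all_pairs <- utils::combn(ns, 2)
  total <- ncol(all_pairs)
  idx <- if (identical(n_pairs, "all") || n_pairs >= total) seq_len(total)
         else with_seed(seed, sample.int(total, n_pairs))
  counts <- vapply(idx, function(k) {
    pairwise_snp_count(x, all_pairs[1, k], all_pairs[2, k])$count
  }, numeric(1))
  pairs <- data.frame(i = x$samples[all_pairs[1, idx]],
                      j = x$samples[all_pairs[2, idx]],
                      count = counts, stringsAsFactors = FALSE)
  ct <- callable_total
  structure(list(pairs = pairs, n_pairs = length(idx),
                 mean = mean(counts), sd = stats::sd(counts),
                 max = max(counts),
                 mean_fraction = if (is.null(ct)) NA_real_ else mean(counts) / ct,
                 max_fraction = if (is.null(ct)) NA_real_ else max(counts) / ct),
            class = "pairwise_summary")
}

#' @export
#' @method print pairwise_summary
print.pairwise_summary <- function(x, ...) {
  cat(sprintf("pairwise SNP differences over %d pairs: mean %.1f +/- %.1f, max %d\n",
              x$n_pairs, x$mean, x$sd, as.integer(x$max)))
  if (!is.na(x$mean_fraction))
    cat(sprintf("  as fraction of callable sites: mean %.2f%%, max %.2f%%\n",
                100 * x$mean_fraction, 100 * x$max_fraction))
  invisible(x)
}

#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity over the observed allele copies: with
#' n observed copies and allele frequencies p_a,
#' pi = (n/(n-1)) (1 - sum p_a^2). Missing calls reduce n; mixed-ploidy
#' samples contribute their own allele-copy numbers.
#'
#' @param dosage integer vector of alt-allele dosages (NA = missing).
#' @param ploidy integer vector of per-sample allele copies.
#' @return per-site pi, or NA when fewer than 2 copies are observed.
#' @export
site_pi <- function(dosage, ploidy) {
  stopifnot(length(dosage) == length(ploidy))
  ok <- !is.na(dosage) & !is.na(ploidy)
  n <- sum(ploidy[ok])
  if (n < 2) return(NA_real_)
  alt <- sum(dosage[ok])
  p <- alt / n
  (n / (n - 1)) * (1 - p^2 - (1 - p)^2)
}

#' Sliding-window nucleotide diversity
#'
#' Computes pi in sliding windows (default 10-kb windows advanced by 1-kb
#' steps): the sum of per-site pi over SNP loci in the window divided by
#' the number of callable positions in the window. When no per-position
#' callable information is available the window length is used as the
#' denominator, which deflates pi over masked regions.
#'
#' @param x a [genotype_matrix()].
#' @param chrom_lengths named vector of chromosome lengths (1-based
#'   coordinates; windows are `[start, start+window-1]`).
#' @param window,step window size and step in bp (defaults 10000 / 1000).
#' @param callable_fraction optional single fraction or named per-chrom
#'   vector scaling the window-length denominator to callable positions.
#' @return object of class `pi_track`: data.frame (chrom, start, end,
#'   n_snps, callable, pi) with the median pi as attribute `median_pi`
#'   (also via [median_pi()]).
#' @export
windowed_pi <- function(x, chrom_lengths, window = 10000, step = 1000,
                        callable_fraction = 1) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.data.frame(chrom_lengths))
    chrom_lengths <- stats::setNames(chrom_lengths[[2]], chrom_lengths[[1]])
  spi <- apply(x$dosage, 1, site_pi, ploidy = x$ploidy)
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    on_ch <- x$loci$chrom == ch
    pos <- x$loci$pos[on_ch]
    val <- spi[on_ch]
    starts <- seq(1, max(1, len - window + 1), by = step)
    cf <- if (length(callable_fraction) > 1) callable_fraction[[ch]] else callable_fraction
    rows <- lapply(starts, function(s) {
      e <- min(s + window - 1, len)
      inw <- pos >= s & pos <= e
      callable <- (e - s + 1) * cf
      if (callable <= 0) return(NULL)
      data.frame(chrom = ch, start = s, end = e,
                 n_snps = sum(inw),
                 callable = callable,
                 pi = sum(val[inw], na.rm = TRUE) / callable,
                 stringsAsFactors = FALSE)
    })
    out[[ch]] <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  }
  track <- do.call(rbind, out)
  rownames(track) <- NULL
  structure(track, class = c("pi_track", "data.frame"),
            median_pi = stats::median(track$pi))
}

#' @rdname windowed_pi
#' @param track a `pi_track`.
#' @export
median_pi <- function(track) attr(track, "median_pi")

#' Spearman rank correlation with large-sample p-value
#'
#' Rank correlation with midranks for ties and the asymptotic two-sided
#' p approximation, as used for the ploidy-versus-heterozygosity trend.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list: rho, n, p_value.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for a constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), n = length(x), p_value = ct$p.value)
}
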