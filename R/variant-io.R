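#' Read a multi-sample VCF into a variant set
#'
#' Parses a VCF 4.x file (plain or bgzipped) with per-sample GT calls and,
#' when present, DP, GQ and AD FORMAT fields, into a `variant_set`: a
#' site-by-sample representation that downstream filtering, zygosity and
#' diversity functions consume. Records are returned in coordinate order
#' (chromosome order of appearance, then position). Multi-allelic records
#' are preserved; genotypes containing "." are flagged missing.
#'
#' Invariant records (ALT "." or `<NON_REF>`) are retained: they feed the
#' callable-site ledger. gVCF-style non-variant blocks are recognised via
#' the INFO `END` tag and contribute their full span to the ledger.
#'
#' @param path path to a VCF file.
#' @param region optional "chrom" or "chrom:start-end" string; sites outside
#'   the region are dropped after reading.
#' @return an object of class `variant_set`: a list with elements
#'   `sites` (data.frame: chrom, pos, ref, alt, locus_class, span),
#'   `gt`, `dp`, `gq`, `ad` (site x sample matrices) and `samples`.
#' @export
read_multisample_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e), call. = FALSE)
  )
  if (nrow(vcf@gt) == 0L || !"FORMAT" %in% colnames(vcf@gt))
    stop("VCF has no genotype (FORMAT/GT) section: ", path)
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt)))
    stop("VCF records without a GT FORMAT field: ", path)

  fix <- vcf@fix
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."
  info <- fix[, "INFO"]

  gt <- vcf@gt[, setdiff(colnames(vcf@gt), "FORMAT"), drop = FALSE]
  samples <- colnames(gt)
  get_field <- function(tag, numeric = FALSE) {
    if (!any(grepl(paste0("(^|:)", tag, "(:|$)"), fmt))) {
      m <- matrix(if (numeric) NA_real_ else NA_character_,
                  nrow = length(pos), ncol = length(samples),
                  dimnames = list(NULL, samples))
      return(m)
    }
    m <- vcfR::extract.gt(vcf, element = tag, as.numeric = numeric)
    dimnames(m) <- list(NULL, samples)
    m
  }
  gt_m <- get_field("GT")
  dp_m <- get_field("DP", numeric = TRUE)
  gq_m <- get_field("GQ", numeric = TRUE)
  ad_m <- get_field("AD")

  # genotypes with any missing allele are treated as missing calls
  gt_m[!is.na(gt_m) & grepl("\\.", gt_m)] <- NA_character_

  span <- rep(1L, length(pos))
  has_end <- grepl("(^|;)END=", info %||% "")
  has_end[is.na(has_end)] <- FALSE
  if (any(has_end)) {
    endv <- suppressWarnings(as.integer(sub(".*(?:^|;)END=([0-9]+).*", "\\1", info[has_end])))
    span[has_end] <- pmax(1L, endv - pos[has_end] + 1L)
  }

  locus_class <- classify_locus(ref, alt)
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      locus_class = locus_class, span = span,
                      stringsAsFactors = FALSE)

  o <- order(match(chrom, unique(chrom)), pos)
  vs <- structure(list(
    sites = sites[o, , drop = FALSE],
    gt = gt_m[o, , drop = FALSE],
    dp = dp_m[o, , drop = FALSE],
    gq = gq_m[o, , drop = FALSE],
    ad = ad_m[o, , drop = FALSE],
    samples = samples
  ), class = "variant_set")
  rownames(vs$sites) <- NULL
  if (!is.null(region)) vs <- subset_region(vs, region)
  vs
}

subset_region <- function(vs, region) {
  parts <- strsplit(region, "[:-]")[[1]]
  keep <- vs$sites$chrom == parts[1]
  if (length(parts) == 3)
    keep <- keep & vs$sites$pos >= as.integer(parts[2]) & vs$sites$pos <= as.integer(parts[3])
  vs$sites <- vs$sites[keep, , drop = FALSE]
  rownames(vs$sites) <- NULL
  for (f in c("gt", "dp", "gq", "ad")) vs[[f]] <- vs[[f]][keep, , drop = FALSE]
  vs
}

#' @export
#' @method print variant_set
print.variant_set <- function(x, ...) {
  tab <- table(factor(x$sites$locus_class,
                      levels = c("invariant", "snp", "indel", "complex")))
  cat("variant_set:", nrow(x$sites), "sites x", length(x$samples), "samples\n")
  cat("  ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Classify a locus as invariant, SNP, InDel or complex
#'
#' A locus is a SNP when the REF allele and every ALT allele are single
#' bases; an InDel when at least one allele differs in length and no ALT is
#' SNP-type; and complex when both SNP-type and InDel-type ALT alleles are
#' present. Complex loci are excluded from both the SNP and InDel outputs
#' and from the callable-site ledger. Vectorised over sites.
#'
#' @param ref character vector of REF alleles.
#' @param alt character vector of comma-separated ALT alleles ("." or "" for
#'   invariant positions; `<NON_REF>`-only records are invariant too).
#' @return character vector in {"invariant","snp","indel","complex"}.
#' @export
classify_locus <- function(ref, alt) {
  stopifnot(length(ref) == length(alt), all(nzchar(ref)))
  vapply(seq_along(ref), function(i) {
    alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
    alts <- alts[!alts %in% c(".", "", "<NON_REF>", "*")]
    if (!length(alts)) return("invariant")
    snp_type <- nchar(alts) == 1L & nchar(ref[i]) == 1L
    if (all(snp_type)) "snp" else if (!any(snp_type)) "indel" else "complex"
  }, character(1))
}

#' Filtering thresholds for multi-sample VCF data
#'
#' Bundles the per-call quality thresholds and cohort-level missingness and
#' excess-heterozygosity rules. Defaults are DP >= 10 and GQ >= 20 per call,
#' per-sample missing genotypes strictly below 20%, per-locus missing
#' genotypes strictly below 1%, and removal of sites whose exact
#' excess-heterozygosity tail probability exceeds 0.99.
#'
#' The direction of the ExcHet rule is configurable because the published
#' threshold does not state whether flagged sites are kept or removed:
#' `remove_above` (default) drops sites with tail probability > threshold
#' (extreme heterozygote *deficiency* configurations), `remove_below` drops
#' sites with tail probability < 1 - threshold style excess, `off` disables
#' the test.
#'
#' @param dp_min minimum read depth per call (inclusive).
#' @param gq_min minimum genotype quality per call (inclusive).
#' @param sample_missing_max samples with missing-call fraction at or above
#'   this value are excluded (strict "below 20%" retention).
#' @param site_missing_max sites with missing fraction at or above this
#'   value are excluded (strict "below 1%" retention).
#' @param exc_het_threshold probability threshold for the ExcHet rule.
#' @param exc_het_mode one of "remove_above", "remove_below", "off".
#' @return object of class `filter_config`.
#' @export
filter_config <- function(dp_min = 10, gq_min = 20,
                          sample_missing_max = 0.20, site_missing_max = 0.01,
                          exc_het_threshold = 0.99,
                          exc_het_mode = c("remove_above", "remove_below", "off")) {
  exc_het_mode <- match.arg(exc_het_mode)
  stopifnot(dp_min >= 0, gq_min >= 0,
            sample_missing_max >= 0, sample_missing_max <= 1,
            site_missing_max >= 0, site_missing_max <= 1,
            exc_het_threshold >= 0, exc_het_threshold <= 1)
  structure(list(dp_min = dp_min, gq_min = gq_min,
                 sample_missing_max = sample_missing_max,
                 site_missing_max = site_missing_max,
                 exc_het_threshold = exc_het_threshold,
                 exc_het_mode = exc_het_mode),
            class = "filter_config")
}

#' Mask low-quality genotype calls
#'
#' Sets to missing every per-sample call with DP below `dp_min` or GQ below
#' `gq_min` (thresholds inclusive on the retained side: DP >= dp_min and
#' GQ >= gq_min are kept). Calls whose DP (or GQ) tag is absent fail the
#' corresponding check whenever its threshold is positive — a conservative
#' reading for data lacking the annotation.
#'
#' @param vs a `variant_set`.
#' @param cfg a [filter_config()].
#' @return the `variant_set` with failing calls set to missing.
#' @export
apply_quality_filter <- function(vs, cfg = filter_config()) {
  stopifnot(inherits(vs, "variant_set"), inherits(cfg, "filter_config"))
  bad <- matrix(FALSE, nrow(vs$gt), ncol(vs$gt))
  if (cfg$dp_min > 0) bad <- bad | is.na(vs$dp) | vs$dp < cfg$dp_min
  if (cfg$gq_min > 0) bad <- bad | is.na(vs$gq) | vs$gq < cfg$gq_min
  vs$gt[bad] <- NA_character_
  vs
}

#' Exact excess-heterozygosity tail probability
#'
#' One-sided tail probability of observing at least the given number of
#' heterozygotes under the exact conditional distribution of the
#' heterozygote count given the observed allele counts (the Levene/Haldane
#' distribution used by Hardy-Weinberg exact tests). Small values signal an
#' excess of heterozygotes; monomorphic sites return 1.
#'
#' @param n_aa,n_ab,n_bb diploid genotype counts (hom-ref, het, hom-alt).
#' @return tail probability P(het count >= n_ab | allele counts).
#' @export
excess_het_probability <- function(n_aa, n_ab, n_bb) {
  stop_if_not_scalar_count(n_aa, "n_aa")
  stop_if_not_scalar_count(n_ab, "n_ab")
  stop_if_not_scalar_count(n_bb, "n_bb")
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("at least one diploid genotype required")
  na <- 2 * n_aa + n_ab   # copies of allele A
  nb <- 2 * n_bb + n_ab
  if (na == 0 || nb == 0) return(1)
  hs <- feasible_het_counts(na, nb)
  logp <- vapply(hs, function(h) log_levene_weight(h, na, n), numeric(1))
  logp <- logp - max(logp)
  p <- exp(logp) / sum(exp(logp))
  sum(p[hs >= n_ab])
}

# heterozygote counts compatible with the allele counts: same parity as na,
# at most min(na, nb)
feasible_het_counts <- function(na, nb) {
  seq(na %% 2, min(na, nb), by = 2)
}

# log number of genotype configurations with h heterozygotes:
# n! / (naa! h! nbb!) * 2^h with naa = (na - h)/2, nbb = (nb - h)/2
log_levene_weight <- function(h, na, n) {
  naa <- (na - h) / 2
  nbb <- n - naa - h
  lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) + h * log(2)
}

#' Filter a variant set into a genotype matrix and callable-site ledger
#'
#' Applies the full cohort filter: (1) per-call quality masking
#' ([apply_quality_filter()]); (2) exclusion of samples whose missing-call
#' fraction over variant loci reaches `sample_missing_max` — sample
#' exclusion strictly precedes site exclusion; (3) exclusion of sites whose
#' missing fraction over the retained samples reaches `site_missing_max`;
#' (4) the exact ExcHet rule on SNP sites, computed on diploid-coded
#' genotypes only. Complex loci (mixed SNP/InDel alleles) are excluded
#' throughout and never enter the ledger.
#'
#' The callable-site ledger counts, per chromosome, the retained invariant
#' positions (including gVCF block spans) plus the retained SNP loci; it is
#' the denominator of every downstream rate statistic.
#'
#' Multi-allelic SNP loci are decomposed to biallelic form for the genotype
#' matrix: the most frequent ALT allele is kept and genotypes carrying any
#' other ALT are set missing at that locus.
#'
#' @param vs a `variant_set`.
#' @param cfg a [filter_config()].
#' @param quality apply the per-call quality mask first (default TRUE).
#' @return list with `matrix` (a [genotype_matrix()] over retained SNP
#'   loci), `ledger` (a `callable_ledger`), `excluded_samples` (data.frame
#'   sample/missing_fraction), `indel_sites` and `snp_sites` (site tables of
#'   the retained loci per class).
#' @export
filter_matrix <- function(vs, cfg = filter_config(), quality = TRUE) {
  stopifnot(inherits(vs, "variant_set"))
  if (length(vs$samples) < 2) stop("at least 2 samples required")
  if (quality) vs <- apply_quality_filter(vs, cfg)

  cls <- vs$sites$locus_class
  variant_rows <- cls %in% c("snp", "indel")

  # -- sample exclusion first (missingness over non-complex variant loci)
  miss_frac <- colMeans(is.na(vs$gt[variant_rows, , drop = FALSE]))
  if (!any(variant_rows)) miss_frac <- rep(0, length(vs$samples))
  excluded <- miss_frac >= cfg$sample_missing_max
  if (all(excluded))
    stop("all samples excluded by the missingness filter; per-sample missing fractions: ",
         paste(sprintf("%s=%.3f", vs$samples, miss_frac), collapse = ", "))
  excluded_df <- data.frame(sample = vs$samples[excluded],
                            missing_fraction = unname(miss_frac[excluded]),
                            stringsAsFactors = FALSE)
  keep_samples <- vs$samples[!excluded]
  gt <- vs$gt[, !excluded, drop = FALSE]

  # -- then site exclusion among retained samples (all classes)
  site_miss <- rowMeans(is.na(gt))
  keep_site <- site_miss < cfg$site_missing_max & cls != "complex"

  # -- ExcHet on SNP sites, diploid-coded genotypes only
  if (cfg$exc_het_mode != "off") {
    snp_idx <- which(keep_site & cls == "snp")
    for (i in snp_idx) {
      d <- diploid_dosage(gt[i, ])
      counts <- c(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
                  sum(d == 2, na.rm = TRUE))
      if (sum(counts) == 0) next
      p <- excess_het_probability(counts[1], counts[2], counts[3])
      drop <- switch(cfg$exc_het_mode,
                     remove_above = p > cfg$exc_het_threshold,
                     remove_below = p < 1 - cfg$exc_het_threshold)
      if (drop) keep_site[i] <- FALSE
    }
  }

  sites <- vs$sites[keep_site, , drop = FALSE]
  gt <- gt[keep_site, , drop = FALSE]
  cls_kept <- cls[keep_site]

  ledger <- build_ledger(sites, cls_kept)
  snp_rows <- cls_kept == "snp"
  gm <- genotype_matrix_from_gt(gt[snp_rows, , drop = FALSE],
                                sites[snp_rows, , drop = FALSE], keep_samples)
  list(matrix = gm,
       ledger = ledger,
       excluded_samples = excluded_df,
       snp_sites = sites[snp_rows, , drop = FALSE],
       indel_sites = sites[cls_kept == "indel", , drop = FALSE])
}

build_ledger <- function(sites, cls) {
  callable <- cls == "invariant" | cls == "snp"
  if (!any(callable))
    return(callable_ledger(data.frame(chrom = character(0),
                                      callable = integer(0))))
  span <- ifelse(cls == "invariant", sites$span, 1L)
  agg <- stats::aggregate(span[callable],
                          by = list(chrom = sites$chrom[callable]), FUN = sum)
  callable_ledger(data.frame(chrom = agg$chrom, callable = agg$x,
                             stringsAsFactors = FALSE))
}

#' Callable-site ledger
#'
#' Per-chromosome counts of callable positions: invariant positions plus
#' retained SNP loci. The genome total (the denominator of heterozygosity,
#' pairwise-fraction and diversity rates) is `sum(x$callable)`, available
#' via [ledger_total()].
#'
#' @param df data.frame with columns `chrom` and `callable`.
#' @return object of class `callable_ledger` (a data.frame).
#' @export
callable_ledger <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "callable") %in% names(df)),
            all(df$callable >= 0))
  structure(df, class = c("callable_ledger", "data.frame"))
}

#' @rdname callable_ledger
#' @param x a `callable_ledger`.
#' @export
ledger_total <- function(x) {
  stopifnot(inherits(x, "callable_ledger"))
  sum(x$callable)
}

#' Write filtering outputs to disk
#'
#' Writes the callable-site ledger and the sample exclusion report as TSV
#' files, the plain-text interchange format of the pipeline.
#'
#' @param filtered result of [filter_matrix()].
#' @param prefix output path prefix; files `<prefix>.ledger.tsv` and
#'   `<prefix>.excluded.tsv` are created.
#' @return invisibly, the paths written.
#' @export
write_filter_outputs <- function(filtered, prefix) {
  paths <- c(ledger = paste0(prefix, ".ledger.tsv"),
             excluded = paste0(prefix, ".excluded.tsv"))
  utils::write.table(as.data.frame(filtered$ledger), paths["ledger"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(filtered$excluded_samples, paths["excluded"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
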