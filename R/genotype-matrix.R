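#' Genotype dosage matrix
#'
#' The backbone container of the pipeline: biallelic SNP loci (rows) by
#' samples (columns), each cell the integer count of alternate-allele
#' copies (0..ploidy) or NA for a missing call. Per-sample ploidy is the
#' number of allele copies in the sample's genotype calls (NA when
#' unknown); a cell is heterozygous when its dosage is strictly between 0
#' and the sample's ploidy.
#'
#' @param dosage integer matrix, loci x samples.
#' @param loci data.frame with columns chrom, pos, ref, alt (one row per
#'   dosage row).
#' @param samples character vector of sample ids (one per dosage column).
#' @param ploidy integer vector of per-sample ploidy, NA allowed.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, loci, samples, ploidy = rep(2L, length(samples))) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(nrow(dosage) == nrow(loci), ncol(dosage) == length(samples),
            length(ploidy) == length(samples),
            all(c("chrom", "pos") %in% names(loci)))
  known <- !is.na(ploidy)
  if (any(known)) {
    over <- sweep(dosage[, known, drop = FALSE], 2, ploidy[known], ">")
    if (any(over, na.rm = TRUE)) stop("dosage exceeds sample ploidy")
  }
  colnames(dosage) <- samples
  structure(list(dosage = dosage, loci = as.data.frame(loci),
                 samples = samples, ploidy = as.integer(ploidy)),
            class = "genotype_matrix")
}

#' @export
#' @method print genotype_matrix
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "loci x", length(x$samples), "samples\n")
  pl <- table(x$ploidy, useNA = "ifany")
  cat("  ploidy:", paste(names(pl), pl, sep = "n=", collapse = "  "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Number of loci / samples in a genotype matrix
#' @param x a `genotype_matrix`.
#' @export
n_loci <- function(x) nrow(x$dosage)

#' @rdname n_loci
#' @export
n_samples <- function(x) length(x$samples)

#' Subset a genotype matrix by loci and/or samples
#'
#' @param x a `genotype_matrix`.
#' @param loci integer or logical index over rows.
#' @param samples integer, logical or character index over samples.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(x, loci = NULL, samples = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (!is.null(loci)) {
    x$dosage <- x$dosage[loci, , drop = FALSE]
    x$loci <- x$loci[loci, , drop = FALSE]
    rownames(x$loci) <- NULL
  }
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, x$samples)
    x$dosage <- x$dosage[, samples, drop = FALSE]
    x$ploidy <- x$ploidy[samples]
    x$samples <- x$samples[samples]
  }
  x
}

#' Logical heterozygosity matrix
#'
#' TRUE where a call carries at least two distinct alleles: dosage strictly
#' between 0 and the sample's ploidy. Samples of unknown ploidy use the
#' maximum observed dosage in their column as the copy number bound.
#'
#' @param x a `genotype_matrix`.
#' @return logical matrix, loci x samples (NA where the call is missing).
#' @export
het_matrix <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  pl <- x$ploidy
  if (anyNA(pl)) {
    obs_max <- apply(x$dosage, 2, function(col) max(col, 0L, na.rm = TRUE))
    pl[is.na(pl)] <- pmax(2L, obs_max[is.na(pl)])
  }
  x$dosage > 0L & sweep(x$dosage, 2, pl, "<")
}

# dosage coding of diploid-style GT strings ("0/0", "0|1", ...); genotypes
# carrying allele indices other than {0, alt_index} count that allele as alt
gt_to_dosage <- function(gt_strings, alt_index = 1L) {
  vapply(gt_strings, function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
    if (anyNA(al)) return(NA_integer_)
    sum(al == alt_index)
  }, integer(1), USE.NAMES = FALSE)
}

# number of allele copies per GT string
gt_copies <- function(gt_strings) {
  vapply(gt_strings, function(g) {
    if (is.na(g)) return(NA_integer_)
    length(strsplit(g, "[/|]")[[1]])
  }, integer(1), USE.NAMES = FALSE)
}

# dosage restricted to diploid-coded calls; other ploidies -> NA
diploid_dosage <- function(gt_strings) {
  d <- gt_to_dosage(gt_strings)
  cp <- gt_copies(gt_strings)
  d[!is.na(cp) & cp != 2L] <- NA_integer_
  d
}

# Build a biallelic genotype_matrix from GT strings over SNP loci.
# Multi-allelic loci keep their most frequent ALT allele; genotypes carrying
# any other ALT allele are set missing.
genotype_matrix_from_gt <- function(gt, sites, samples) {
  n <- nrow(gt)
  dosage <- matrix(NA_integer_, n, length(samples))
  alt_kept <- character(n)
  for (i in seq_len(n)) {
    alts <- strsplit(sites$alt[i], ",", fixed = TRUE)[[1]]
    row <- gt[i, ]
    alleles <- lapply(row, function(g) {
      if (is.na(g)) return(integer(0))
      suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
    })
    if (length(alts) > 1L) {
      counts <- tabulate(unlist(alleles), nbins = length(alts) + 1L)[-1]
      major <- which.max(counts)
    } else major <- 1L
    alt_kept[i] <- alts[major]
    dosage[i, ] <- vapply(alleles, function(al) {
      if (!length(al)) return(NA_integer_)
      if (any(!al %in% c(0L, major))) return(NA_integer_)
      sum(al == major)
    }, integer(1))
  }
  cp <- apply(gt, 2, function(col) {
    v <- gt_copies(col)
    v <- v[!is.na(v)]
    if (!length(v)) NA_integer_ else as.integer(names(which.max(table(v))))
  })
  loci <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
                     alt = alt_kept, stringsAsFactors = FALSE)
  genotype_matrix(dosage, loci, samples, ploidy = as.integer(cp))
}
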