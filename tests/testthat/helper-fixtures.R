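# Small in-code fixtures shared across test files.

# A hand-built 3-sample VCF covering invariant, SNP, multi-allelic SNP,
# indel and complex loci, with DP/GQ/AD fields.
write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    "##contig=<ID=chr2,length=5000>",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP:GQ:AD\t0/1:30:99:15,15\t0/0:25:80:25,0\t1/1:40:99:0,40",
    "chr1\t200\t.\tA\t.\t.\tPASS\t.\tGT:DP:GQ:AD\t0/0:30:99:30,0\t0/0:30:99:30,0\t0/0:30:99:30,0",
    "chr1\t300\t.\tC\tT,G\t.\tPASS\t.\tGT:DP:GQ:AD\t0/1:30:99:15,15,0\t0/0:30:99:30,0,0\t0/1:30:99:14,16,0",
    "chr1\t400\t.\tA\tAT\t.\tPASS\t.\tGT:DP:GQ:AD\t0/1:30:99:15,15\t0/0:30:99:30,0\t0/0:30:99:30,0",
    "chr1\t500\t.\tA\tG,AT\t.\tPASS\t.\tGT:DP:GQ:AD\t0/1:30:99:15,15,0\t0/0:30:99:30,0,0\t./.:.:.:.",
    "chr2\t100\t.\tT\tC\t.\tPASS\t.\tGT:DP:GQ:AD\t0/1:9:60:5,4\t0/1:30:19:15,15\t0/1:30:99:16,14",
    "chr2\t150\t.\tG\t.\t.\tPASS\tEND=159\tGT:DP:GQ:AD\t0/0:30:99:30,0\t0/0:30:99:30,0\t0/0:30:99:30,0"
  )
  writeLines(lines, path)
  path
}

# genotype matrix fixture: 5 diploid loci x 3 samples
toy_matrix <- function() {
  dosage <- matrix(c(0L, 1L, 2L, 0L, 1L,
                     0L, 2L, 2L, 1L, 1L,
                     0L, 0L, 2L, NA, 1L), ncol = 3)
  loci <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40, 50),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(dosage, loci, c("a", "b", "c"))
}

# independent enumeration oracle for the heterozygote-excess tail:
# exact distribution of the het count given allele counts, summed by
# direct combinatorial weights on each feasible genotype configuration
exchet_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n_bb + n_ab
  if (na == 0 || nb == 0) return(1)
  hs <- seq(na %% 2, min(na, nb), by = 2)
  w <- vapply(hs, function(h) {
    naa <- (na - h) / 2
    nbb <- n - naa - h
    exp(lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
          h * log(2) + lgamma(na + 1) + lgamma(nb + 1) - lgamma(2 * n + 1))
  }, numeric(1))
  sum(w[hs >= n_ab]) / sum(w)
}

# brute-force rarefaction oracle: enumerate every n-subset of the samples
rarefaction_oracle <- function(gm, n, min_carriers) {
  carrier <- !is.na(gm$dosage) & gm$dosage >= 1L
  subs <- utils::combn(ncol(carrier), n)
  mean(apply(subs, 2, function(cols)
    sum(rowSums(carrier[, cols, drop = FALSE]) >= min_carriers)))
}
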