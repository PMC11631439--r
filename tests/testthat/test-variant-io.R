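test_that("VCF round-trips in coordinate order with classes and missing flags", {
  vs <- read_multisample_vcf(write_toy_vcf())
  expect_s3_class(vs, "variant_set")
  expect_equal(nrow(vs$sites), 7)
  expect_equal(vs$samples, c("s1", "s2", "s3"))
  # coordinate order within chromosome
  expect_true(all(diff(vs$sites$pos[vs$sites$chrom == "chr1"]) > 0))
  # classification: snp, invariant, multi-allelic snp, indel, complex
  expect_equal(vs$sites$locus_class[1:5],
               c("snp", "invariant", "snp", "indel", "complex"))
  # ./. flagged missing
  expect_true(is.na(vs$gt[5, "s3"]))
  # gVCF block span from INFO END
  expect_equal(vs$sites$span[vs$sites$chrom == "chr2" & vs$sites$pos == 150], 10)
})

test_that("region subsetting and missing-GT errors behave", {
  p <- write_toy_vcf()
  vs <- read_multisample_vcf(p, region = "chr1:250-450")
  expect_equal(vs$sites$pos, c(300, 400))
  expect_error(read_multisample_vcf(tempfile()), "not found")
})

test_that("locus classification follows the SNP/InDel/complex rule", {
  expect_equal(classify_locus("A", "G"), "snp")
  expect_equal(classify_locus("A", "AT"), "indel")
  expect_equal(classify_locus("AT", "A"), "indel")
  expect_equal(classify_locus("A", "G,AT"), "complex")
  expect_equal(classify_locus("A", "."), "invariant")
  expect_equal(classify_locus(c("A", "C"), c("G,T", "CAA,CTT")),
               c("snp", "indel"))
})

test_that("quality filter masks calls below inclusive DP/GQ thresholds", {
  vs <- read_multisample_vcf(write_toy_vcf())
  f <- apply_quality_filter(vs, filter_config())
  # DP=30, GQ=99 retained; DP=9 masked; GQ=19 masked
  expect_false(is.na(f$gt[1, "s1"]))
  chr2row <- which(f$sites$chrom == "chr2" & f$sites$pos == 100)
  expect_true(is.na(f$gt[chr2row, "s1"]))   # DP 9 < 10
  expect_true(is.na(f$gt[chr2row, "s2"]))   # GQ 19 < 20
  expect_false(is.na(f$gt[chr2row, "s3"]))  # DP 30, GQ 99 (inclusive)
})

test_that("excess-het tail probability matches exhaustive enumeration", {
  cases <- list(c(25, 50, 25), c(50, 0, 50), c(0, 50, 0), c(10, 5, 3),
                c(1, 1, 1), c(40, 20, 40), c(3, 0, 97))
  for (cs in cases) {
    expect_equal(excess_het_probability(cs[1], cs[2], cs[3]),
                 exchet_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-10,
                 info = paste(cs, collapse = ","))
  }
  # monomorphic sites return 1
  expect_equal(excess_het_probability(10, 0, 0), 1)
  # no configuration has fewer hets than zero
  expect_equal(excess_het_probability(50, 0, 50), 1)
  # all-het configuration: single most-heterozygous state, small tail
  expect_lt(excess_het_probability(0, 50, 0), 1e-10)
})

test_that("filter_matrix excludes samples before sites and builds the ledger", {
  # 10 invariant + 3 SNP + 1 indel + 1 complex, complete genotypes
  ns <- 5
  hdr <- c("##fileformat=VCFv4.2", "##contig=<ID=c1,length=100000>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("s", 1:ns)), collapse = "\t"))
  gts <- function(g) paste(rep(g, ns), collapse = "\t")
  recs <- c(
    sprintf("c1\t%d\t.\tA\t.\t.\t.\t.\tGT\t%s", 1:10, gts("0/0")),
    sprintf("c1\t%d\t.\tA\tG\t.\t.\t.\tGT\t%s", 101:103,
            paste(c("0/1", "0/0", "0/0", "0/1", "0/0"), collapse = "\t")),
    sprintf("c1\t%d\t.\tA\tAT\t.\t.\t.\tGT\t%s", 200, gts("0/1")),
    sprintf("c1\t%d\t.\tA\tG,AT\t.\t.\t.\tGT\t%s", 300, gts("0/1"))
  )
  p <- tempfile(fileext = ".vcf")
  writeLines(c(hdr, recs), p)
  vs <- read_multisample_vcf(p)
  res <- filter_matrix(vs, filter_config(dp_min = 0, gq_min = 0,
                                         exc_het_mode = "off"))
  expect_equal(ledger_total(res$ledger), 13)   # 10 invariant + 3 SNPs
  expect_equal(nrow(res$indel_sites), 1)
  expect_equal(nrow(res$excluded_samples), 0)  # all sites complete

  # a sample with 25% missing variant calls is excluded; its absence can
  # rescue sites that would otherwise fail the per-site missingness rule
  recs2 <- c(
    sprintf("c1\t%d\t.\tA\tG\t.\t.\t.\tGT\t%s", 1:4,
            c(paste(c("./.", "0/1", "0/0", "0/1", "0/1"), collapse = "\t"),
              paste(c("0/1", "0/0", "0/1", "0/0", "0/1"), collapse = "\t"),
              paste(c("0/0", "0/1", "0/1", "0/1", "0/0"), collapse = "\t"),
              paste(c("0/1", "0/0", "0/0", "0/1", "0/1"), collapse = "\t")))
  )
  p2 <- tempfile(fileext = ".vcf")
  writeLines(c(hdr, recs2), p2)
  vs2 <- read_multisample_vcf(p2)
  res2 <- filter_matrix(vs2, filter_config(dp_min = 0, gq_min = 0,
                                           sample_missing_max = 0.25,
                                           site_missing_max = 0.01,
                                           exc_het_mode = "off"))
  # s1 has 1/4 = 25% missing -> excluded at the strict threshold;
  # site 1 then has no missing calls among retained samples and survives
  expect_equal(res2$excluded_samples$sample, "s1")
  expect_equal(nrow(res2$snp_sites), 4)
})

test_that("filtering is a fixed point when reapplied", {
  hdr <- c("##fileformat=VCFv4.2", "##contig=<ID=c1,length=100000>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("s", 1:5)), collapse = "\t"))
  set.seed(42)
  recs <- vapply(1:20, function(i) {
    g <- sample(c("0/0", "0/1", "1/1", "./."), 5, replace = TRUE,
                prob = c(0.5, 0.25, 0.2, 0.05))
    sprintf("c1\t%d\t.\tA\tG\t.\t.\t.\tGT\t%s", i * 10,
            paste(g, collapse = "\t"))
  }, character(1))
  p <- tempfile(fileext = ".vcf")
  writeLines(c(hdr, recs), p)
  vs <- read_multisample_vcf(p)
  cfg <- filter_config(dp_min = 0, gq_min = 0, site_missing_max = 0.25)
  res1 <- filter_matrix(vs, cfg)
  # rebuild a variant set restricted to what survived (sites and samples),
  # refilter: nothing further may change
  keep <- paste(vs$sites$chrom, vs$sites$pos) %in%
    paste(res1$snp_sites$chrom, res1$snp_sites$pos)
  cols <- res1$matrix$samples
  vs2 <- vs
  vs2$sites <- vs$sites[keep, , drop = FALSE]
  for (f in c("gt", "dp", "gq", "ad"))
    vs2[[f]] <- vs[[f]][keep, cols, drop = FALSE]
  vs2$samples <- cols
  res2 <- filter_matrix(vs2, cfg)
  expect_equal(res2$snp_sites$pos, res1$snp_sites$pos)
  expect_equal(unname(res2$matrix$dosage), unname(res1$matrix$dosage))
})

test_that("multi-allelic SNPs decompose to the major alternate allele", {
  vs <- read_multisample_vcf(write_toy_vcf())
  res <- filter_matrix(vs, filter_config(dp_min = 0, gq_min = 0,
                                         site_missing_max = 1,
                                         exc_het_mode = "off"))
  i <- which(res$matrix$loci$pos == 300)
  expect_equal(res$matrix$loci$alt[i], "T")
  expect_equal(unname(res$matrix$dosage[i, ]), c(1L, 0L, 1L))
})
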