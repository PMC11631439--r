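#' Write a simulated population to disk
#'
#' Emits the on-disk interchange files of the pipeline: a multi-sample
#' VCF with GT/DP/GQ/AD and gVCF-style invariant blocks (so the
#' callable-site ledger can be rebuilt from the file alone), per-sample
#' window depth TSVs, the CDS BED, the chromosome-length TSV and
#' machine-readable truth tables. Deterministic given the seed.
#'
#' @param sim result of [simulate_population()].
#' @param dir output directory (created if needed).
#' @param seed seed for the per-call read-count simulation in the VCF.
#' @return invisibly, a named vector of file paths.
#' @export
write_population <- function(sim, dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "depth"), showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "population.vcf"),
             cds = file.path(dir, "cds.bed"),
             chrom_lengths = file.path(dir, "chrom_lengths.tsv"),
             samples = file.path(dir, "truth_samples.tsv"),
             totals = file.path(dir, "truth_totals.tsv"),
             cnv = file.path(dir, "truth_cnv.tsv"),
             aneuploidy = file.path(dir, "truth_aneuploidy.tsv"))
  write_population_vcf(sim$matrix, paths["vcf"], sim$cfg$chrom_lengths,
                       coverage = sim$cfg$coverage, seed = seed)
  utils::write.table(sim$cds, paths["cds"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(chrom = names(sim$cfg$chrom_lengths),
                                length = unname(sim$cfg$chrom_lengths)),
                     paths["chrom_lengths"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  st <- sim$truth$samples
  Q <- sim$truth$Q
  colnames(Q) <- paste0("q", seq_len(ncol(Q)))
  utils::write.table(cbind(st, round(Q, 6)), paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(metric = c("n_variants", "n_non_singleton"),
                                value = c(sim$truth$n_variants,
                                          sim$truth$n_non_singleton)),
                     paths["totals"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$cfg$cnv_truth, paths["cnv"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$cfg$aneuploidy_truth, paths["aneuploidy"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in names(sim$depth)) {
    p <- file.path(dir, "depth", paste0(s, ".depth.tsv"))
    utils::write.table(as.data.frame(sim$depth[[s]]), p, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths[paste0("depth_", s)] <- p
  }
  invisible(paths)
}

#' Write a genotype matrix as a multi-sample VCF
#'
#' SNP records carry GT (ploidy-length), simulated DP (negative binomial
#' around `coverage`), AD consistent with the genotype dosage and GQ as a
#' deterministic function of depth (min(99, 3 DP) — a synthetic
#' convention standing in for a caller's quality model). Invariant
#' gVCF-style block records with INFO END fill the gaps between SNP loci
#' so the file carries the full callable-site information.
#'
#' @param gm a [genotype_matrix()].
#' @param path output VCF path.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param coverage mean depth used for the simulated DP/AD fields.
#' @param seed RNG seed for read counts.
#' @param invariant_blocks write the invariant blocks (default TRUE).
#' @return invisibly, `path`.
#' @export
write_population_vcf <- function(gm, path, chrom_lengths, coverage = 30,
                                 seed = 1, invariant_blocks = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ns <- length(gm$samples)
  truth_n <- sum(!is.na(gm$dosage))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=popsaturate-simulator",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
            as.integer(chrom_lengths)),
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of non-variant block\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"))
  L <- n_loci(gm)
  with_seed(seed, {
    dp <- matrix(pmax(2L, stats::rnbinom(L * ns, size = 20, mu = coverage)),
                 L, ns)
    recs <- character(L)
    for (i in seq_len(L)) {
      cells <- character(ns)
      for (j in seq_len(ns)) {
        d <- gm$dosage[i, j]
        m <- gm$ploidy[j]
        if (is.na(d)) { cells[j] <- paste0(paste(rep(".", m), collapse = "/"),
                                           ":.:.:.,."); next }
        gt <- paste(c(rep("0", m - d), rep("1", d)), collapse = "/")
        depth <- dp[i, j]
        alt_r <- stats::rbinom(1, depth, d / m)
        if (d == m) alt_r <- depth
        if (d == 0) alt_r <- 0L
        cells[j] <- sprintf("%s:%d:%d:%d,%d", gt, depth,
                            min(99L, 3L * depth), depth - alt_r, alt_r)
      }
      recs[i] <- paste(c(gm$loci$chrom[i], gm$loci$pos[i], ".",
                         gm$loci$ref[i], gm$loci$alt[i], ".", "PASS", ".",
                         "GT:DP:GQ:AD", cells), collapse = "\t")
    }
    lines <- c(header, interleave_invariants(gm, recs, chrom_lengths,
                                             invariant_blocks))
    writeLines(lines, path)
  })
  invisible(path)
}

# order SNP records per chromosome and insert invariant END blocks in gaps
interleave_invariants <- function(gm, recs, chrom_lengths, blocks) {
  ns <- length(gm$samples)
  inv_cells <- paste(rep("0/0:30:90:30,0", ns), collapse = "\t")
  out <- character(0)
  for (ch in names(chrom_lengths)) {
    idx <- which(gm$loci$chrom == ch)
    idx <- idx[order(gm$loci$pos[idx])]
    pos <- gm$loci$pos[idx]
    if (blocks) {
      bounds <- c(0L, pos, chrom_lengths[[ch]] + 1L)
      for (g in seq_len(length(bounds) - 1)) {
        s <- bounds[g] + 1L; e <- bounds[g + 1] - 1L
        if (e >= s)
          out <- c(out, paste(c(ch, s, ".", "A", ".", ".", "PASS",
                                sprintf("END=%d", e), "GT:DP:GQ:AD", inv_cells),
                              collapse = "\t"))
        if (g <= length(pos)) out <- c(out, recs[idx[g]])
      }
    } else {
      out <- c(out, recs[idx])
    }
  }
  out
}
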