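#' Pipeline configuration
#'
#' Paths and per-stage parameters for [run_pipeline()]. Stage interfaces
#' are files on disk so that stages are independently re-runnable.
#'
#' @param vcf multi-sample VCF path.
#' @param out_dir output directory.
#' @param depth_dir optional directory of per-sample depth TSVs
#'   (`<sample>.depth.tsv`).
#' @param cds optional CDS BED path.
#' @param chrom_lengths optional chromosome-length TSV path.
#' @param seed master seed recorded in every output.
#' @param stages character vector of stages to run, in order, among
#'   "filter", "zygosity", "ploidy", "cnv", "diversity", "rarefaction",
#'   "structure".
#' @param filter a [filter_config()].
#' @param ploidy_criterion criterion for [call_ploidy()].
#' @param n_pairs pairs sampled for the pairwise distribution.
#' @param pi_window,pi_step sliding-window pi settings.
#' @param rarefaction_grid number of grid points.
#' @param maf_min,ld_window,ld_step,ld_r2 structure pruning settings.
#' @param k ancestry components for [admixture_em()].
#' @param ancestry_threshold clade-assignment threshold.
#' @param superclades optional named list grouping components.
#' @param cnv_delta,cnv_min_windows segmentation settings.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, out_dir, depth_dir = NULL, cds = NULL,
                            chrom_lengths = NULL, seed = 1,
                            stages = c("filter", "zygosity", "ploidy", "cnv",
                                       "diversity", "rarefaction", "structure"),
                            filter = filter_config(),
                            ploidy_criterion = "r2",
                            n_pairs = 200, pi_window = 10000, pi_step = 1000,
                            rarefaction_grid = 30,
                            maf_min = 0.05, ld_window = 50, ld_step = 1,
                            ld_r2 = 0.5, k = 3, ancestry_threshold = 0.6,
                            superclades = NULL,
                            cnv_delta = 0.25, cnv_min_windows = 2) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full downstream analysis pipeline
#'
#' Executes the configured stages in order — filtering, zygosity and
#' ploidy, CNV/aneuploidy, diversity, rarefaction/saturation, population
#' structure — each stage consuming the previous stage's results, and
#' writes a JSON report of the headline numbers plus per-stage TSV files
#' under `out_dir`. A stage failure aborts with the failing stage named;
#' files already written are retained.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the report list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed,
                 package_version = as.character(utils::packageVersion("popsaturate")))
  state <- new.env()
  for (stage in cfg$stages) {
    res <- tryCatch(run_stage(stage, cfg, state, report),
                    error = function(e)
                      stop("pipeline stage '", stage, "' failed: ",
                           conditionMessage(e), call. = FALSE))
    report <- res
  }
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

run_stage <- function(stage, cfg, state, report) {
  switch(stage,
    filter = {
      vs <- read_multisample_vcf(cfg$vcf)
      filtered <- filter_matrix(vs, cfg$filter)
      state$vs <- vs
      state$filtered <- filtered
      write_filter_outputs(filtered, file.path(cfg$out_dir, "filtered"))
      report$filter <- list(
        n_samples = length(filtered$matrix$samples),
        n_excluded_samples = nrow(filtered$excluded_samples),
        n_snps = nrow(filtered$snp_sites),
        n_indels = nrow(filtered$indel_sites),
        callable_total = ledger_total(filtered$ledger),
        snp_fraction_of_callable = nrow(filtered$snp_sites) /
          ledger_total(filtered$ledger))
      report
    },
    zygosity = {
      gm <- state$filtered$matrix
      zt <- zygosity_table(gm, ledger_total(state$filtered$ledger))
      state$zygosity <- zt
      utils::write.table(zt, file.path(cfg$out_dir, "zygosity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$zygosity <- list(
        n_heterozygous = sum(zt$zygosity == "heterozygous"),
        n_homozygous = sum(zt$zygosity == "homozygous"),
        homozygous_fraction = mean(zt$zygosity == "homozygous"))
      report
    },
    ploidy = {
      zt <- state$zygosity
      calls <- lapply(seq_along(zt$sample), function(i) {
        if (zt$zygosity[i] == "homozygous")
          return(list(sample = zt$sample[i], ploidy = "unknown", n_sites = 0L))
        bf <- extract_base_frequencies(state$vs, zt$sample[i])
        pc <- call_ploidy(bf, criterion = cfg$ploidy_criterion, seed = cfg$seed)
        list(sample = zt$sample[i], ploidy = pc$ploidy, n_sites = pc$n_sites)
      })
      pt <- data.frame(sample = vapply(calls, `[[`, character(1), "sample"),
                       ploidy = vapply(calls, `[[`, character(1), "ploidy"),
                       n_sites = vapply(calls, function(x) as.integer(x$n_sites),
                                        integer(1)),
                       stringsAsFactors = FALSE)
      state$ploidy <- pt
      utils::write.table(pt, file.path(cfg$out_dir, "ploidy.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$ploidy <- as.list(table(pt$ploidy))
      report
    },
    cnv = {
      if (is.null(cfg$depth_dir) || is.null(cfg$chrom_lengths)) {
        report$cnv <- "skipped (no depth input)"
        return(report)
      }
      lens <- utils::read.table(cfg$chrom_lengths, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
      cds <- if (!is.null(cfg$cds)) {
        b <- utils::read.table(cfg$cds, header = FALSE, sep = "\t",
                               stringsAsFactors = FALSE)
        names(b) <- c("chrom", "start", "end", "name")[seq_len(ncol(b))]
        b
      }
      files <- list.files(cfg$depth_dir, pattern = "\\.depth\\.tsv$",
                          full.names = TRUE)
      an_all <- list(); cnv_all <- list()
      for (f in files) {
        s <- sub("\\.depth\\.tsv$", "", basename(f))
        track <- normalize_depth(read_depth_profile(f, sample = s))
        regions <- segment_cnv(track, delta = cfg$cnv_delta,
                               min_windows = cfg$cnv_min_windows)
        an <- call_aneuploidy(regions, lens)
        an$sample <- s
        an_all[[s]] <- an
        if (nrow(regions)) { regions$sample <- s; cnv_all[[s]] <- regions }
        if (!is.null(cds)) {
          med <- cds_median_rd(cds, regions)
          utils::write.table(med, file.path(cfg$out_dir,
                                            paste0("cds_rd.", s, ".tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
      an <- do.call(rbind, an_all)
      utils::write.table(an, file.path(cfg$out_dir, "aneuploidy.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (length(cnv_all))
        utils::write.table(do.call(rbind, cnv_all),
                           file.path(cfg$out_dir, "cnv_regions.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      state$aneuploidy <- an
      report$cnv <- list(
        n_samples = length(files),
        n_aneuploid_chromosomes = sum(an$aneuploid),
        samples_with_aneuploidy = length(unique(an$sample[an$aneuploid])))
      report
    },
    diversity = {
      gm <- state$filtered$matrix
      ct <- ledger_total(state$filtered$ledger)
      pw <- pairwise_distribution(gm, n_pairs = cfg$n_pairs, seed = cfg$seed,
                                  callable_total = ct)
      utils::write.table(pw$pairs, file.path(cfg$out_dir, "pairwise.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      lens <- chrom_lengths_from_state(cfg, state)
      pi_track <- windowed_pi(gm, lens, window = cfg$pi_window,
                              step = cfg$pi_step)
      utils::write.table(as.data.frame(pi_track),
                         file.path(cfg$out_dir, "pi_windows.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      rc <- NULL
      if (!is.null(state$ploidy) && !is.null(state$zygosity)) {
        known <- state$ploidy$ploidy %in% c("1", "2", "3", "4")
        if (sum(known) >= 3) {
          pl <- as.numeric(state$ploidy$ploidy[known])
          hf <- state$zygosity$het_fraction[known]
          if (stats::sd(pl) > 0 && stats::sd(hf) > 0)
            rc <- rank_correlation(pl, hf)
        }
      }
      report$diversity <- list(
        mean_pairwise_snps = pw$mean, sd_pairwise_snps = pw$sd,
        max_pairwise_snps = pw$max,
        mean_pairwise_fraction = pw$mean_fraction,
        max_pairwise_fraction = pw$max_fraction,
        median_pi = median_pi(pi_track),
        ploidy_het_spearman = if (is.null(rc)) NA else rc$rho)
      report
    },
    rarefaction = {
      gm <- state$filtered$matrix
      cc <- carrier_counts(gm)
      all_curve <- rarefaction_curve(cc, grid = cfg$rarefaction_grid,
                                     min_carriers = 1)
      ns_curve <- rarefaction_curve(cc, grid = cfg$rarefaction_grid,
                                    min_carriers = 2)
      utils::write.table(
        data.frame(n = all_curve$n, y_all = all_curve$y, y_nonsingleton = ns_curve$y),
        file.path(cfg$out_dir, "rarefaction.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      pw_fit <- fit_power_law(all_curve)
      mm_fit <- fit_michaelis_menten(ns_curve)
      observed_ns <- sum(cc$c_k[-1])
      cov <- if (isTRUE(mm_fit$converged))
        coverage_fraction(mm_fit, observed_ns, cc$N)
      report$rarefaction <- list(
        n_variants = sum(cc$c_k), n_singletons = cc$c_k[1],
        n_non_singleton = observed_ns,
        power_law = as.list(pw_fit$params),
        mm = as.list(mm_fit$params),
        mm_asymptote = mm_fit$asymptote,
        coverage_fraction = if (is.null(cov)) NA else cov$fraction)
      report
    },
    structure = {
      gm <- state$filtered$matrix
      pruned <- ld_prune(filter_biallelic_maf(gm, cfg$maf_min),
                         window = cfg$ld_window, step = cfg$ld_step,
                         r2_max = cfg$ld_r2)
      D <- ibs_distance(pruned)
      tree <- neighbor_joining(D)
      ape::write.tree(tree, file.path(cfg$out_dir, "nj_tree.nwk"))
      fit <- admixture_em(pruned, K = cfg$k, seed = cfg$seed)
      utils::write.table(cbind(sample = rownames(fit$Q), round(fit$Q, 6)),
                         file.path(cfg$out_dir, "ancestry_q.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      asg <- assign_clades(fit, threshold = cfg$ancestry_threshold)
      if (!is.null(cfg$superclades))
        asg <- group_superclades(asg, cfg$superclades)
      utils::write.table(asg, file.path(cfg$out_dir, "clades.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$structure <- list(
        n_pruned_loci = n_loci(pruned), k = cfg$k,
        loglik = fit$loglik,
        n_assigned = sum(asg$assigned),
        n_admixed = sum(!asg$assigned),
        clade_sizes = as.list(table(asg$component)))
      report
    },
    stop("unknown stage: ", stage))
}

chrom_lengths_from_state <- function(cfg, state) {
  if (!is.null(cfg$chrom_lengths)) {
    lens <- utils::read.table(cfg$chrom_lengths, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    return(stats::setNames(lens[[2]], lens[[1]]))
  }
  # fall back to the observed extent of the data
  loci <- state$filtered$matrix$loci
  vapply(split(loci$pos, loci$chrom), max, numeric(1))
}
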