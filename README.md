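# popsaturate

Downstream population-genomics analysis for large multi-sample
resequencing panels of microbial eukaryotes — the kind of dataset produced
by surveys of thousands of *Saccharomyces cerevisiae* isolates. The
package takes a jointly genotyped multi-sample VCF (plus optional
per-window depth data) and carries the analysis from variant filtering to
the headline population statistics:

- **Variant filtering** — per-call DP/GQ masking, strict per-sample and
  per-site missingness rules, separation of SNPs, InDels and complex
  loci, an exact excess-heterozygosity test (the Levene/Haldane
  conditional distribution of the heterozygote count), and a
  *callable-site ledger* (invariant positions + retained SNP loci) that
  normalises every rate statistic.
- **Zygosity and ploidy** — samples with more than 500 heterozygous SNPs
  are heterozygous; ploidy (2n–4n) is inferred from the alternate-allele
  read fractions at heterozygous sites using fixed-mean Gaussian mixture
  models (means at {1/2}, {1/3, 2/3}, {1/4, 1/2, 3/4}) compared by three
  criteria: the log-likelihood gap to a free-mean mixture, the histogram
  sum of squared residuals, and the histogram R².
- **CNV and aneuploidy** — 1-kb window depths normalised to a genome-wide
  center, threshold-merge segmentation into CNV regions, per-CDS median
  normalised depth (positions outside CNV regions count as exactly 1),
  and an aneuploidy call when strictly more than half a chromosome's
  length is in CNV.
- **Diversity** — pairwise SNP counts between random isolate pairs,
  per-site and sliding-window nucleotide diversity
  π = (n/(n−1))(1 − Σ p_a²) over 10-kb windows sliding by 1 kb, and the
  ploidy–heterozygosity rank correlation.
- **Rarefaction and saturation** — exact expected rarefaction curves from
  the carrier-count spectrum (P(≥1 carrier) = 1 − C(N−k,n)/C(N,n);
  non-singleton status evaluated *within* each subsample), power-law
  fits y = a·xᵇ − c (no finite asymptote) and Michaelis–Menten fits
  y = Vmax·x/(K + x), whose asymptote Vmax estimates the species-total
  non-singleton variant count and hence the **fraction of species
  diversity captured** by the panel.
- **Population structure** — MAF and LD pruning (plink-style
  `indep-pairwise`), identity-by-state distances, neighbor-joining trees,
  an EM estimator of the admixture model (binomial likelihood over K
  ancestry components), and clade assignment by the strict >60% ancestry
  rule with optional superclade grouping.
- **Synthetic populations** — a Balding–Nichols clade-structured
  generator (mixed ploidy, homozygous regimes, admixture, CNV and
  aneuploidy truth, binomial allelic read counts) with full truth tables,
  so the whole pipeline is testable without external data.

## Worked example

Simulate a 3-clade population of 66 isolates, write it to disk, read it
back through the VCF interface and compute the saturation statistics:

```r
library(popsaturate)

cfg  <- sim_config(k_clades = 3, n_per_clade = 20, n_admixed = 6, n_loci = 2000)
sim  <- simulate_population(cfg, seed = 42)
paths <- write_population(sim, "pop", seed = 42)

vs <- read_multisample_vcf(paths[["vcf"]])
vs
#> variant_set: 4003 sites x 66 samples
#>    invariant=2003  snp=2000  indel=0  complex=0

fl <- filter_matrix(vs, filter_config(exc_het_mode = "off"))
ledger_total(fl$ledger)
#> [1] 3399785

table(zygosity_table(fl$matrix, ledger_total(fl$ledger))$zygosity)
#> heterozygous   homozygous
#>           32           34

pairwise_distribution(fl$matrix, n_pairs = 200, seed = 1,
                      callable_total = ledger_total(fl$ledger))
#> pairwise SNP differences over 200 pairs: mean 909.6 +/- 200.7, max 1354
#>   as fraction of callable sites: mean 0.03%, max 0.04%

cc <- carrier_counts(fl$matrix)
cc
#> carrier_counts: N = 66 isolates; 1771 variants of which 18 singletons

fit <- fit_michaelis_menten(rarefaction_curve(cc, grid = 30, min_carriers = 2))
cov <- coverage_fraction(fit, sum(cc$c_k[-1]), cc$N)
sprintf("diversity captured: %.1f%%", 100 * cov$fraction)
#> [1] "diversity captured: 95.1%"
```

The numbers read as follows: of 3,399,785 callable sites, the panel
segregates 1,771 variants, two random isolates differ at ~910 SNP sites
(0.03% of callable sites), and the Michaelis–Menten asymptote of the
non-singleton rarefaction curve (Vmax ≈ 1,843) implies the 66 isolates
already capture ~95% of the species' non-singleton diversity — the same
saturation logic used for real panels, at toy scale.

An end-to-end driver (`run_pipeline()`) chains all stages from files on
disk and writes per-stage TSVs plus a JSON report; a thin command-line
wrapper is installed at `inst/scripts/popsaturate.R`.

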