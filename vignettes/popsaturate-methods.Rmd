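---
title: "Models and methods behind popsaturate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popsaturate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models, the tunable parameters and
the design choices behind each stage of the pipeline, and what the
synthetic-population tests do and do not demonstrate about real data.

## Filtering and the callable-site ledger

Every rate statistic in a resequencing panel (heterozygosity, pairwise
divergence, π) is a count divided by the number of *callable sites*:
invariant positions plus retained SNP loci. The ledger is maintained
per chromosome during filtering, and gVCF-style non-variant blocks
(INFO `END`) contribute their full span. Complex loci — records whose
alternate alleles mix single-base and length-changing variants — are
excluded from both the SNP and InDel outputs and never enter the ledger,
because neither variant class can be scored cleanly there.

Quality thresholds are inclusive on the retained side (`DP >= 10`,
`GQ >= 20`); calls lacking the tag fail the corresponding check when its
threshold is positive, a deliberately conservative reading for data
without the annotation. Missingness rules are strict retention rules:
a sample is kept only when its missing fraction is *below* 20%, a site
only below 1%, so a value exactly at the threshold is excluded. Sample
exclusion is computed before site exclusion — removing a bad sample can
rescue sites that would otherwise fail the per-site rule — and the test
suite pins this order on a fixture where it changes the outcome.

### The exact excess-heterozygosity test

For a biallelic site with diploid genotype counts (n_AA, n_AB, n_BB),
the number of heterozygotes conditional on the allele counts follows the
Levene/Haldane distribution,
P(h) ∝ n! / (n_AA'! h! n_BB'!) · 2^h,
over the heterozygote counts h compatible with the allele counts. We
report the one-sided tail P(het ≥ observed): small values signal
heterozygote excess (typical of collapsed paralogs), values near 1
signal heterozygote deficiency (typical of selfing). The published
threshold ("ExcHet > 0.99") does not state which side is removed, so
`filter_config()` exposes three modes. The default, `remove_above`,
drops sites whose tail probability exceeds 0.99. Note a practical
consequence: in small, highly selfed cohorts, sites where every carrier
is homozygous have tail probability 1 and are removed; with cohorts of
thousands this affects only sites segregating exclusively among
homozygotes. Analysts of selfing species may prefer `remove_below`
(drop only significant heterozygote *excess*) or `off`; the truth-recovery
tests of the rarefaction and structure modules run with the test off so
that they measure those modules, not the filter.

## Ploidy from allelic read fractions

At a heterozygous site of a p-ploid genome carrying d alternate copies,
the alternate-read fraction concentrates around d/p. The three ploidy
hypotheses are Gaussian mixtures with means fixed at {1/2}, {1/3, 2/3}
and {1/4, 1/2, 3/4}; only the mixture weights and one shared standard
deviation are free, fitted by EM (log-likelihood monotone, shared-sd
floor 1e-3 against degenerate spikes). A free-mean three-component
mixture serves as the reference model; its EM is started from ten seeded
random initialisations *plus* the three fixed-model solutions, which
guarantees the nesting inequality logL_free ≥ logL_fixed in finite
samples.

Three selection criteria are provided: minimal logL_free − logL_fixed,
minimal histogram sum of squared residuals, and maximal histogram R²
(100 bins over the retention interval, model mass per bin renormalised
over the interval). Site selection uses coverage ≥ 10 and an open
retention interval (0.10, 0.90) — extreme fractions are dominated by
mapping artefacts — and at least 100 usable sites; all three are
configuration parameters.

**Parsimony ties.** The fixed models are partially nested: the
tetraploid mixture contains the diploid as a weight-degenerate case, so
for truly diploid data it can never fit worse, and a strict
argmin/argmax would resolve meaningless machine-level differences in
favour of the higher ploidy. Score differences that carry no evidence
are therefore treated as ties and resolved toward the lower ploidy: for
the log-likelihood criterion the tie scale is the likelihood-ratio
significance bound for the two extra parameters (qchisq(0.95, 2)/2 ≈ 3
log-likelihood units); for the histogram criteria a relative tolerance
of 1e-3, three orders of magnitude below genuine model gaps (misfitting
the true ploidy changes the histogram scores severalfold). Homozygous
samples have almost no heterozygous sites, fall below the site minimum
and are called `unknown`; sequencing data alone cannot distinguish a
haploid from a homozygous diploid, so no 1n call is ever emitted.

## CNV and aneuploidy

Window depths are normalised by a genome-wide center, by default the
median of all 1-kb windows. The median is robust to focal CNVs but can
be dragged by heavily aneuploid genomes (if >25–35% of windows sit at an
elevated copy ratio, normalised depths shrink toward the center and
runs fall below the detection threshold); the `mode` option (peak of a
density-smoothed depth histogram) is provided for such genomes.

Segmentation is a deliberate simplification: windows with |RD − 1| >
0.25 are CNV windows, and runs of at least two consecutive CNV windows
merge into regions carrying the mean RD of their members. The
downstream rules need nothing more than regions with a normalised
depth: per-CDS copy number is the median over all CDS positions of a
position-level track that is exactly 1 outside regions and the region
RD inside (computed on the run-length structure, exactly equal to the
per-base median), and a chromosome is aneuploid when strictly more than
half its length is in CNV — gains and losses both count, and exactly
half does not. No GC correction is applied at this stage; depth input
is expected to be GC-normalised upstream if needed. Normalised depth is
deliberately left continuous rather than rounded to integer copy
number.

## Diversity statistics

The per-site estimator is the unbiased sample heterozygosity over
observed allele copies, π = (n/(n−1))(1 − Σ p_a²), with missing calls
reducing n and mixed-ploidy samples contributing their own allele-copy
numbers. Windowed π (10-kb windows, 1-kb step) divides the summed
per-site values by the window's callable positions; when only window
length is available a `callable_fraction` scales the denominator, since
using raw length over masked regions deflates π. Pairwise divergence
counts sites whose dosages differ — a heterozygous versus homozygous
genotype at a site counts as one difference — which matches a
site-count reading of panel-scale pairwise distributions.

## Rarefaction and saturation

The carrier-count spectrum c_k (variants carried by exactly k of N
isolates) is a sufficient statistic for exact rarefaction. For a
variant with k carriers and a subsample of n isolates,

- P(observed) = 1 − C(N−k, n)/C(N, n),
- P(non-singleton in the subsample) = P(observed) − k·C(N−k, n−1)/C(N, n),

and the expected curve sums these over the spectrum (computed with
log-binomials for numerical stability; verified against exhaustive
subset enumeration for N ≤ 12). Non-singleton status is evaluated
*within the subsample* — the standard rarefaction semantics, pinned by a
regression test — not by pre-filtering full-panel singletons. The
default grid is 50 geometrically spaced sizes from 2 to N, and the
exact expectation is preferred over Monte Carlo.

The all-variant curve follows a power law y = a·xᵇ − c (fit by
Levenberg–Marquardt with a log-log initialisation and jittered
restarts), which has no finite asymptote: the total variant count
diverges, so no coverage fraction exists for it and
`coverage_fraction()` refuses power-law fits. The non-singleton curve
saturates and is fit by a Michaelis–Menten curve y = Vmax·x/(K + x)
(double-reciprocal initialisation plus fallback starts); Vmax estimates
the species-total non-singleton count, and the fraction captured is the
observed non-singleton count over Vmax by default. The published
arithmetic is ambiguous about whether the numerator is the observed
count or the fitted value at N, so both modes are exposed
(`numerator_mode`); the fitted-at-N mode equals N/(K+N) algebraically.

## Population structure

Structure inference runs on biallelic loci with minor allele frequency
strictly above 5%, LD-pruned plink-style (windows of 50 loci advanced by
1, removing the later locus of any pair with r² > 0.5, repeated to a
fixed point). Distances are 1 − IBS allele sharing; among the several
SNP distances in common use this is the simplest that respects dosage,
and the neighbor-joining tree (Saitou–Nei, negative branches clamped to
zero) is exact on additive distances regardless of the metric choice.

Ancestry is estimated by EM on the classic admixture likelihood:
dosage g_il ~ Binomial(m_i, Σ_k q_ik f_kl), with m_i the sample's
allele copies (polyploids and haploids are down-coded to their declared
copy number, matching the binomial form). The EM updates preserve the
Q simplex without projection and are monotone in the log-likelihood;
component frequencies are clamped to [1e-6, 1−1e-6]; two seeded
restarts are run (the likelihood surface for well-separated clades is
benign) with a relative log-likelihood stopping rule. This estimator
stands in for variational structure inference: the downstream rule
consumes only Q. The number of components K is a parameter; automatic
selection of K is out of scope. Samples are assigned to their majority
component only when its proportion strictly exceeds 60%; everything
else is reported admixed. Superclade grouping is a plain configuration
mapping, and the manual curation steps used on real panels (outlier
removal on the tree, merging or splitting clades by ecology) are
deliberately not automated — the pipeline emits the tree, the Q matrix
and the assignments for human refinement.

## The synthetic population generator

The generator emulates the features the pipeline must detect, not a
full coalescent: per-clade allele frequencies follow the
Balding–Nichols model f_kl ~ Beta(p(1−F)/F, (1−p)(1−F)/F) around a
uniform ancestral frequency (so E[f] = p and Var[f] = F·p(1−p));
admixed individuals draw Dirichlet ancestry; genotypes are binomial in
the mixed frequency; a homozygous regime (default 42% of samples, the
fraction observed in large yeast panels) draws all allele copies as one
allele, emulating selfed isolates; ploidies default to 6% haploid, 74%
diploid, 20% polyploid. The toy genome is four chromosomes of
1,500/1,000/600/300 kb, echoing at reduced scale the short-chromosome
bias of real aneuploidies. Window depths are simulated at read-count
resolution — negative-binomial reads per window with mean
coverage × copy-ratio × window/read-length, scaled back to a mean
depth — because per-base negative-binomial noise would give 1-kb window
means a ~30% coefficient of variation, far from the ~10% observed in
short-read data; the dispersion default (size 100) reproduces that
~10% CV at 30×. Genotype quality in the written VCF is a deterministic
function of depth (min(99, 3·DP)), a synthetic convention.

What passing the synthetic tests shows: that the estimators recover the
generating parameters under their own model assumptions at realistic
noise levels. What it does not show: robustness to mapping artefacts,
reference bias, GC waves, contamination, or recombination-driven LD
structure — none of which the generator produces.

### Problem sizes used by the tests

The test and acceptance runs use reduced problem sizes chosen to
exercise the asymptotic behaviour of each estimator: 150 labelled
samples (50 per ploidy, 2,000 sites at 100×) for the criterion
benchmark; 150 samples × 5,000 loci (K = 3, F = 0.2) for ancestry
recovery; a 10-clade × 15-isolate panel over 20,000 loci with rare-ish
ancestral frequencies (U(0.01, 0.3), F = 0.5) for saturation recovery,
where every locus eventually reaches two carriers so the species
non-singleton pool is exactly the locus count and the
Michaelis–Menten extrapolation can be scored against known truth. A
neutral-like 1/k carrier spectrum, by contrast, is *not*
Michaelis–Menten-shaped, and the extrapolation under-estimates such a
pool by ~19 percentage points — the saturation logic depends on
clade-structured, within-clade-common variation, which is also what
makes it appropriate for clade-structured species panels.

## Known limitations

- The ExcHet direction on selfing cohorts (above) is a filter-policy
  choice, not a statistical inevitability; both directions are exposed.
- The threshold-merge segmenter has no breakpoint precision beyond the
  1-kb window and no significance model; it under-calls short or
  low-amplitude CNVs by construction.
- Ploidies above 4n are not modelled; 1n calls require external
  evidence.
- The admixture EM maximises likelihood without priors; for very small
  panels or tightly admixed populations, variational or Bayesian
  estimators with regularisation will be better behaved.
- Coverage fractions inherit every assumption of the Michaelis–Menten
  form; adding a divergent population to a panel legitimately lowers
  the captured fraction after refitting.
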