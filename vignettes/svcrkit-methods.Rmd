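---
title: "Sparse cohort representation and rare-variant association QC: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse cohort representation and rare-variant association QC: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svcrkit)
```

# What this package computes

Biobank-scale exome resources are built from per-sample gVCFs: files that
cover every targeted base either with a variant record or with a *reference
block* — a run of homozygous-reference positions summarized by a start, an
`END`, and a quality band. A conventional project VCF (pVCF) merge densifies
these into an all-sites-by-all-samples table and scales quadratically in
practice; the Scalable Variant Call Representation (SVCR) instead keeps each
sample's records sparse and stores, per entry, a *local allele* index map
(`LA`) into the row's merged allele list, renaming `GT`/`AD`/`PL` to
`LGT`/`LAD`/`LPL`. Storage is then exactly linear in the summed per-sample
record count, merging never rewrites genotype arrays, and the dense view can
be materialized on the fly when an analysis needs it.

`svcrkit` implements this representation and the quality-control and
calibration machinery that surrounds it in a large exome association
resource, at sizes that run on a desk:

* **SVCR core** — gVCF conversion with 7-bin GQ compression of reference
  blocks (bins 0/10/20/30/40/50/60, floor-to-bin, capped at 60), a
  deterministic allele-merge, a branch-factor-`N` hierarchical merge, a
  densification pass, and a lossless per-sample export.
* **Genotype/variant QC** — the `adj` genotype filter, hard site filters, the
  random-forest variant classifier with balanced truth sets built from trio
  transmission, and two hard exclusions.
* **Sample QC** — interval screening, sex-karyotype imputation from
  normalized X/Y ploidies, hard filters, stratified MAD outlier flags, and
  greedy maximal-independent-set pruning of related samples.
* **Association calibration** — GRM-correlated random phenotypes, score
  tests, genomic-control lambda, expected-allele-count and lambda filters,
  empirical significance thresholds, and correlated-phenotype pruning.
* **Enrichment and power** — CAF-matched resampling enrichment and the
  `2pq a^2` variance-explained / power floor.

# The representation and its algebra

An SVCR dataset has one row per locus appearing in any input gVCF — including
monomorphic rows where reference blocks begin — and one sparse entry per
original record. The invariants enforced by `validate_svcr()` are:

* `LA[1] = 0` and `LA` strictly increasing;
* `|LAD| = |LA|`; `|LPL|` equals the number of unphased genotypes over
  `|LA|` alleles at the entry's ploidy (diploid throughout the generator;
  haploid entries are supported for the `adj` filter's haploid branch);
* every `LGT` index addresses a slot of `LA`.

**Allele collation.** Merged alternates are the union of input alternates
sorted by a deterministic ordering: plain bytewise lexicographic order for
sequence alleles, with symbolic alleles collating last (`*` before
`<NON_REF>`). Any reproducible total order would do; bytewise comparison is
platform- and locale-independent. Because `<NON_REF>` appears in every
variant record it is carried through the representation as the final
alternate and dropped on densification.

**Reference conflicts.** Two variant records at one locus must agree on the
reference string, or the merge aborts naming the locus. A monomorphic row
(block start) only witnesses the single reference base, so when it meets an
indel row whose REF extends that base, the longer REF wins after a
leading-base consistency check. This is the one place the package relaxes a
strict string-equality rule, and it is forced by not carrying a reference
genome.

**Non-monotone maps.** When the merged collation reorders a sample's
alternates, the remapped `LA` is sorted back into increasing order and
`LGT`/`LAD`/`LPL` are permuted along, with `LPL` re-indexed through the
standard VCF genotype-index formula `j(j+1)/2 + k`. The round-trip
(expansion to global order and projection back) is exact and is
property-tested. The synthetic generator emits record alternates already in
canonical order, so this path is exercised by constructed fixtures.

**Hierarchical merge.** Groups of at most `N` datasets (default branch
factor 100) are merged per round until one remains;
`merge_rounds(S, N) = ceiling(log_N(S))`, so a million samples take three
rounds at the default. The result is entry-identical to a flat merge under
any bracketing, which the tests assert directly.

**Densification.** For each requested row, a defined variant entry is
relabeled to global indices; otherwise the sample's most recent reference
block *on the same contig* fills a homozygous-reference call exactly when its
`END` spans the locus; otherwise the call is missing. No block state crosses
contigs. `DP` of a filled call is the block's minimum depth and `GQ` its bin
label — the only summaries the binned block retains.

**Losslessness.** GQ binning is deliberately lossy once, at conversion:
blocks are floored to bins and contiguous same-bin blocks are fused (keeping
the run's minimum `MIN_DP`). From the binned file onward the representation
is lossless: `svcr_to_gvcf()` reproduces each sample's binned records
byte-for-byte on the modeled fields (CHROM, POS, REF, ALT, END, GT, AD, DP,
GQ, MIN_DP, PL), which the acceptance suite checks across twenty seeded
cohorts.

# The QC rulebook

All thresholds live in `default_config()` and each is exercised by a
boundary test:

| rule | default | boundary behavior |
|---|---|---|
| `adj` depth | DP ≥ 10 (5 haploid) | inclusive |
| `adj` quality | GQ ≥ 20 | inclusive |
| `adj` het allele balance | > 0.2 per carried alt | strict |
| excess heterozygosity | F < −0.3 flagged | strict |
| hard filters | QD < 2, FS > 60, MQ < 30 | strict |
| RF pass probability | 0.061 SNV / 0.064 indel | inclusive |
| interval QC | 85% of samples at 20×, 50 bp pad | inclusive |
| sample call rate / coverage | 0.99 / 20× | inclusive |
| outliers | 4 raw MADs | strict |
| relatedness | kinship > 0.1 edges | strict |
| expected allele count | ≥ 50 | inclusive |
| lambda floors | ≥ 0.75 (genes and phenotypes) | inclusive |
| phenotype correlation | r² > 0.5 edges | strict |
| burden groups | MAF ≤ 0.01, ≥ 2 variants | inclusive |

Notes on the less obvious choices:

* **Quality by depth** is computed as the sum of carriers' phred-scaled
  hom-ref likelihoods divided by the carriers' summed depth — the verbal
  definition of the feature — rather than the `QUAL/DP` convention of
  common callers. The two differ; the package follows the former and the
  choice is isolated in `quality_by_depth()`.
* **MAD is unscaled** (no 1.4826 consistency factor): four raw median
  absolute deviations. With the factor the filter would be ~1.48× looser;
  the literal reading is used and documented so flags are interpretable.
* **Allele balance p-value** is the standard exact two-sided binomial test
  at 0.5 (sum of outcomes no more probable than observed), maximized over
  heterozygotes.
* **Greedy MIS, not exact.** Maximum independent set is NP-hard; the package
  uses greedy max-degree removal with ties broken by dropping the
  lower-priority vertex (priority = mean depth for samples, case count for
  phenotypes), followed by a re-admission sweep so the result is always
  maximal. Exact enumeration serves only as a test oracle on small graphs.
* **Rank-sum style read-level features** (read position, mapping quality
  rank sums) cannot be derived from genotype-level synthetic data. They are
  accepted as precomputed site annotations when supplied and dropped from
  the random forest otherwise; in the pipeline, FS and MQ are synthetic
  annotations drawn with heavy enough tails that a hard-filter
  false-positive pool always exists.

# Random phenotypes and threshold calibration

Phenotypes are simulated as `y = sqrt(h2) g + sqrt(1−h2) e` where `g` is
multivariate normal with covariance the (sparse) GRM — sampled through a
Cholesky factor with a `1e-8` diagonal jitter for near-singular matrices —
and `e` is i.i.d. standard normal. Binary traits dichotomize a
heritability-1 liability at the *empirical* `(1−π)` quantile, so the case
count is exactly `floor(πn)`; the difference from the theoretical normal
quantile is O(1/n) and the choice makes the prevalence invariant exactly
testable.

The score tests are deliberately plain single-level tests (the mixed-model
machinery of biobank pipelines is ingestible as external summary statistics
but not reimplemented): for continuous traits the genotype is residualized
on the covariates and the usual large-sample coefficient test follows from
the null fit — algebraically the full least-squares fit; for binary traits
the efficient score from the logistic null model. Their calibration (type-I
error within three binomial standard errors at α = 0.05/0.01, genomic
lambda in [0.9, 1.1] at 2,000 samples × 2,000 null variants) is an
acceptance criterion.

Lambda GC is the median association chi-square over the 1-df null median
(`qchisq(0.5, 1) ≈ 0.4549`), computed from two-sided p-values via the
quantile transform.

The empirical threshold rule: each null phenotype's minimum p estimates the
inverse of the effective number of tests; the median of these minima `p~`
gives `effective tests = 1/p~` and the experiment-wise threshold
`0.05 × p~`, i.e. 0.05 expected false positives per phenotype. Applied to
published median minima of 5e-6 (SKAT-O), 1.3e-5 (burden) and 1.6e-7
(single-variant) this yields 2.5e-7, 6.5e-7 and 8e-9. The package reports
the arithmetic result; a burden threshold quoted as 6.7e-7 elsewhere is
consistent with a rounded median input.

The expected allele count of a summary statistic is CAF × n_cases for gene
groups and MAF × n_cases for variants, with the count of phenotyped
individuals replacing n_cases for continuous traits; records under 50 are
removed, as are records with SE = 0, genes with coverage < 20 or
synonymous-class lambda < 0.75, and phenotypes with lambda < 0.75. The gate
is idempotent and logs per-rule removal counts.

# Matched enrichment and power

Units (genes or variants) are binned by cumulative allele frequency into
half-open bins of width 0.01. Each of 1,000 resamples draws, per target
unit, a background unit with replacement from the same bin, recording the
proportion with ≥ 1 association and the mean association count. The
empirical one-sided p uses `(r+1)/(n_sets+1)` smoothing so it is never
zero; the 2×2 table (target vs matched background × hit vs no-hit) gets a
Fisher exact test, the sample odds ratio `ad/bc` (the estimator choice is
configurable via the table; the conditional MLE is not used), and Wilson
95% intervals. A target bin with no background is an error naming the bin;
no special top-bin lumping is applied.

Calibration note: the proportion statistic is discrete with atoms of width
`1/|target|`. At the set sizes the procedure is meant for (hundreds of
units) its empirical p is uniform to within Kolmogorov–Smirnov resolution,
which the acceptance suite verifies at 400 target units over 200
replicates; at very small target sets the `≥`-with-smoothing convention is
visibly conservative, which is the standard behavior of resampling p-values
and is left as is.

Power: the variance explained by a purely additive biallelic variant is
`2 p (1−p) a²`. `min_detectable_varexp(n, alpha, power)` returns the
smallest variance fraction for which a 1-df chi-square test with
noncentrality `n·v` reaches the target power, solved by bisection; the
target power is exposed as a parameter rather than assumed (80% is a
conventional choice, and at n = 394,841 and α = 2.5e-7 gives ≈ 0.009% of
variance, rising toward ~0.02% for more stringent power/threshold
assumptions).

# The synthetic generator: what it emulates and what it does not

`generate_cohort()` produces, per sample, a gVCF that tiles each contig with
alternating reference blocks (raw GQ; binning happens at conversion, as in
the real pipeline's post-processing) and variant records carrying the
sample's own discovered alleles plus `<NON_REF>`, with `AD`/`PL`/`GQ` from a
symmetric read-error model (reads multinomial over local alleles, error
rate 1e-3) around a Poisson depth (default mean 30×, typical of exome
coverage). Cohort sites carry true alternate-allele frequencies drawn from
a Beta distribution — default shape (0.2, 2), a rare-skewed spectrum chosen
as a convention since no parametric site-frequency model is prescribed for
real exomes — and genotypes are Hardy–Weinberg draws for founders with
Mendelian transmission (configurable de novo rate, default 0) for trio
offspring. The reference base at a position is a fixed function of the
position, so all samples agree on the pseudo-reference without storing one.

What this does *not* emulate: linkage disequilibrium, mutation-rate sequence
context, batch/platform structure, read-level artifacts (hence no real
strand-bias or rank-sum statistics), population stratification, or
relatedness beyond declared trios. Passing tests therefore demonstrate the
correctness of the representation algebra and the filtering/calibration
arithmetic on data with the right *shape*, not robustness to the
pathologies of real sequencing data.

Defaults used by the desk-scale pipeline (`default_config()`): 30 samples
including 4 trios, two contigs of 30 kb and 20 kb, per-base polymorphism
rate 0.004, 40 genes, 24 random phenotypes at heritabilities
0.1/0.2/0.5/1, 1,000 enrichment resamples. The test suite uses cohorts of
3–15 samples over 2–5 kb contigs and calibration runs of 2,000 samples ×
2,000 variants; these sizes were chosen so the full suite completes in
about a minute while leaving every procedure statistically identifiable.

# Numerical and degenerate-input choices

* GQ binning rejects negative GQ; bins are closed below.
* Monomorphic sites have undefined inbreeding F (`NA`) and are never
  flagged for excess heterozygosity.
* Zero-variance genotypes are skipped with a flag, not errored, so a
  phenotype sweep never aborts mid-run.
* `lambda_gc` of an empty p-vector is `NA`; all-p = 1 gives exactly 0.
* MIS tie-breaks: equal degree → lower priority removed first → smaller
  vertex id; deterministic for a fixed input.
* Phenotype correlations mean-impute missing values for the cross-product
  step only; association tests drop missing observations instead.
* Pipeline stage failures abort with the stage name; every artifact is
  checksummed into the manifest, and two runs with equal config and seed
  are byte-identical.

# Known limitations

* Multi-allelic sites are merged correctly, but spanning-deletion (`*`)
  alleles are only carried through collation — the generator never emits
  them, so that path is fixture-tested only.
* The burden test's group MAF ceiling of 0.01 is unusable at very small
  cohorts (a singleton already exceeds it); the pipeline falls back to
  gene-aggregated single-variant units for its enrichment demonstration in
  that regime.
* SKAT-O and mixed-model tests are out of scope; `skato_external` summary
  statistics can be ingested through the same record schema, and every
  downstream filter applies to them unchanged.
* The exported pVCF models GT/AD/DP/GQ/PL only; INFO-field annotation
  propagation is not implemented.
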