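# svcrkit

Sparse variant-call representation and rare-variant association QC at desk
scale.

Joint-calling hundreds of thousands of exomes breaks the conventional
project-VCF model: densifying per-sample gVCFs into an all-sites ×
all-samples table scales super-linearly and throws away the reference-block
structure the single-sample files already have. The **Scalable Variant Call
Representation (SVCR)** keeps each sample's records sparse and attaches to
every entry a *local allele* map `LA` into the row's merged allele list
(renaming `GT`/`AD`/`PL` to `LGT`/`LAD`/`LPL`), so storage is strictly
linear in the summed record count, merging only rewrites integer index
maps, and the dense matrix is materialized on the fly when needed.

`svcrkit` is an R implementation of that representation and of the
quality-control and calibration machinery of a large exome association
resource, exercised end-to-end on synthetic cohorts:

* **SVCR core** — gVCF → SVCR conversion with 7-bin reference-block GQ
  compression (bins 0–60), deterministic allele merging, hierarchical
  merging (`ceiling(log_N S)` rounds at branch factor `N`, default 100),
  on-the-fly densification, lossless per-sample export, and pVCF export.
* **Genotype & variant QC** — the `adj` filter (DP ≥ 10, or 5 haploid;
  GQ ≥ 20; het allele balance > 0.2), inbreeding-coefficient and
  QD/FS/MQ hard filters, binomial allele-balance features, balanced
  truth-set assembly from trio transmission, and a random-forest
  classifier with class cutoffs 0.061 (SNV) / 0.064 (indel).
* **Sample QC** — interval QC (85% of samples at 20×, 50 bp padding),
  sex-karyotype imputation from normalized X/Y ploidies, hard filters
  (XX/XY, call rate ≥ 0.99, coverage ≥ 20×), 4-MAD stratified outlier
  flags, and greedy maximal-independent-set pruning of related samples
  (kinship > 0.1).
* **Association calibration** — GRM-correlated random phenotypes
  (`y = √h²·g + √(1−h²)·ε`), linear/logistic score tests, genomic-control
  λ (median χ² / 0.4549), expected-allele-count (≥ 50) and λ (≥ 0.75)
  filters, empirical significance thresholds (0.05 × median minimum null
  p), and correlated-phenotype pruning (r² > 0.5).
* **Enrichment & power** — cumulative-allele-frequency-matched resampling
  enrichment (1,000 matched sets, Fisher exact + sample OR + Wilson CIs)
  and the `2pq·a²` variance-explained / power floor.
* **Synthetic data** — a seeded generator for gVCF cohorts with reference
  blocks, trios, Beta-distributed allele-frequency spectra, pedigree GRMs,
  gene/class annotations and phenotypes, byte-identical under a fixed seed.

## Worked example

```r
library(svcrkit)

# 1. a synthetic cohort: 8 samples (2 trios), one 20 kb contig
co <- generate_cohort(
  cohort_spec(n_samples = 8, n_trios = 2, contigs = c(chr1 = 20000L),
              variant_rate = 0.005, seed = 7),
  tempdir())

# 2. convert each gVCF and merge hierarchically
cohort <- hierarchical_merge(lapply(co$gvcf, gvcf_to_svcr),
                             branch_factor = 4)
cohort
#> SVCR dataset: 8 samples, 436 rows, 678 stored entries
attr(cohort, "rounds")
#> [1] 2

# 3. densify the variant rows and export a pVCF
dm <- densify(cohort)
dm
#> Dense matrix: 8 samples x 50 rows
export_pvcf(dm, "cohort.vcf")

# 4. the empirical threshold rule on three null phenotypes' minimum p
empirical_thresholds(c(4e-6, 5e-6, 7e-6))
#> $median_min_p    5e-06
#> $effective_tests 2e+05
#> $threshold       2.5e-07

# 5. detectability floor for a quantitative trait at 80% power
100 * min_detectable_varexp(394841, alpha = 2.5e-7, power = 0.8)
#> [1] 0.0091   # percent of phenotypic variance
```

The 436 rows exceed the 50 variant rows because the sparse representation
materializes a monomorphic row wherever a reference block begins; the 678
stored entries are exactly the sum of the samples' record counts after GQ
binning — merging never changes that number. The threshold `2.5e-07` is
0.05 × the median minimum p, i.e. 0.05 expected false positives per
phenotype.

The full pipeline (generate → merge/densify → QC → associate → calibrate →
enrich) runs from one validated config:

```r
cfg <- validate_config()        # every QC threshold at its published default
man <- run_end_to_end(cfg)      # writes artifacts + checksum manifest
```

or from a shell via the thin wrapper `inst/scripts/svcrkit`:

```sh
Rscript inst/scripts/svcrkit pipeline run --config run.yaml
```

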