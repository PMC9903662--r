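# Programmatic fixtures shared across test files.

make_block <- function(contig, pos, end, gq, dp = 30L, min_dp = dp,
                       ref = "A") {
  data.table::data.table(
    contig = contig, pos = as.integer(pos), ref = ref,
    alts = list("<NON_REF>"), kind = "ref_block", end = as.integer(end),
    gt = "0/0", ad = list(NULL), dp = as.integer(dp), gq = as.integer(gq),
    min_dp = as.integer(min_dp), pl = list(NULL))
}

make_variant <- function(contig, pos, ref, alts, gt, ad, dp = sum(ad),
                         gq = 99L, pl = NULL) {
  alts <- c(alts, "<NON_REF>")
  n_all <- length(alts) + 1L
  if (is.null(pl)) pl <- seq_len(n_all * (n_all + 1L) / 2L) * 10L - 10L
  data.table::data.table(
    contig = contig, pos = as.integer(pos), ref = ref, alts = list(alts),
    kind = "variant", end = NA_integer_, gt = gt,
    ad = list(as.integer(ad)), dp = as.integer(dp), gq = as.integer(gq),
    min_dp = NA_integer_, pl = list(as.integer(pl)))
}

single_sample_svcr <- function(records, sample, contigs = "chr1",
                               contig_lengths = 10000L) {
  gvcf_to_svcr(list(records = records, sample = sample, contigs = contigs,
                    contig_lengths = contig_lengths))
}

tiny_cohort <- function(n_samples = 6, n_trios = 2, len = 5000L,
                        rate = 0.01, seed = 7, dir = tempfile("cohort"),
                        ...) {
  generate_cohort(
    cohort_spec(n_samples = n_samples, n_trios = n_trios,
                contigs = c(chr1 = len), variant_rate = rate, seed = seed,
                ...),
    dir)
}

# dosage matrix of independent variants under Hardy-Weinberg equilibrium
hwe_dose_matrix <- function(n_samples, mafs, seed = 1) {
  set.seed(seed)
  G <- sapply(mafs, function(p) rbinom(n_samples, 2, p))
  colnames(G) <- sprintf("v%04d", seq_along(mafs))
  G
}
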