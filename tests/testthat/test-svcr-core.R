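test_that("reference-block GQ binning floors to the seven bins and caps at 60", {
  expect_identical(bin_reference_gq(c(0L, 37L, 99L, 60L, 9L)),
                   c(0L, 30L, 60L, 60L, 0L))
  expect_error(bin_reference_gq(-1L), "non-negative")
  # floor-to-bin over the full range
  for (gq in 0:120) {
    expect_identical(bin_reference_gq(gq), min((gq %/% 10L) * 10L, 60L))
  }
})

test_that("gVCF conversion preserves record count and uses identity LA", {
  rec <- rbind(
    make_block("chr1", 1, 100, 41),
    make_variant("chr1", 101, "A", "T", "0/1", c(7L, 5L, 0L),
                 dp = 12L, pl = c(99L, 0L, 88L, 120L, 130L, 140L)),
    make_block("chr1", 102, 200, 25),
    make_variant("chr1", 201, "G", "C", "1/1", c(0L, 9L, 0L), dp = 9L),
    make_block("chr1", 202, 300, 55))
  ds <- single_sample_svcr(rec, "s1")
  expect_equal(nrow(ds$rows), 5L)
  expect_equal(n_entries(ds), 5L)
  validate_svcr(ds)
  ve <- ds$entries[ds$entries$kind == "variant"][1]
  expect_identical(ve$la[[1]], 0:2)  # identity over A, T, <NON_REF>
  expect_identical(ve$gt, "0/1")
  expect_identical(ve$ad[[1]], c(7L, 5L, 0L))
  # binned reference blocks carry the bin label
  be <- ds$entries[ds$entries$kind == "ref_block"]
  expect_identical(be$gq, c(40L, 20L, 50L))
})

test_that("adjacent same-bin reference blocks are merged after binning", {
  rec <- rbind(
    make_block("chr1", 1, 50, 41, dp = 30, min_dp = 28),
    make_block("chr1", 51, 120, 47, dp = 33, min_dp = 25),
    make_variant("chr1", 121, "A", "T", "0/1", c(5L, 5L, 0L)),
    make_block("chr1", 122, 200, 47))
  ds <- single_sample_svcr(rec, "s1")
  blocks <- ds$entries[ds$entries$kind == "ref_block"]
  expect_equal(nrow(blocks), 2L)  # 41+47 merged into one bin-40 block
  expect_identical(blocks$gq[1], 40L)
  expect_identical(blocks$end[1], 120L)
  expect_identical(blocks$min_dp[1], 25L)  # min across merged run
  expect_identical(blocks$pos[2], 122L)    # variant breaks contiguity
})

test_that("unsorted or overlapping gVCF input is rejected with the locus", {
  rec <- rbind(make_block("chr1", 100, 200, 40),
               make_block("chr1", 1, 99, 40))
  expect_error(single_sample_svcr(rec, "s1"), "chr1:1")
  rec2 <- rbind(make_variant("chr1", 10, "ACG", "A", "0/1", c(5L, 5L, 0L)),
                make_variant("chr1", 11, "C", "T", "0/1", c(5L, 5L, 0L)))
  expect_error(single_sample_svcr(rec2, "s1"), "overlap")
})

test_that("allele merging sorts the union deterministically and maps indices", {
  m <- merge_alleles(list(list(ref = "A", alts = "T"),
                          list(ref = "A", alts = "C")))
  expect_identical(m$alts, c("C", "T"))
  expect_identical(m$maps[[1]], c(0L, 2L))
  expect_identical(m$maps[[2]], c(0L, 1L))
  # single input: identity
  one <- merge_alleles(list(list(ref = "A", alts = c("C", "T"))))
  expect_identical(one$maps[[1]], 0:2)
  # idempotence on equal inputs
  two <- merge_alleles(list(list(ref = "A", alts = c("T", "<NON_REF>")),
                            list(ref = "A", alts = c("T", "<NON_REF>"))))
  expect_identical(two$alts, c("T", "<NON_REF>"))
  # symbolic alleles always collate last
  sym <- merge_alleles(list(list(ref = "A", alts = c("<NON_REF>", "T", "*"))))
  expect_identical(sym$alts, c("T", "*", "<NON_REF>"))
  expect_error(
    merge_alleles(list(list(ref = "AC", alts = "A"),
                       list(ref = "AG", alts = "A"))),
    "conflicting reference")
})

test_that("merging joins loci, keeps sparsity, and leaves absent entries missing", {
  a <- single_sample_svcr(rbind(
    make_block("chr1", 1, 300, 32)), "sampleA")
  b <- single_sample_svcr(rbind(
    make_block("chr1", 1, 149, 40),
    make_variant("chr1", 150, "A", "T", "0/1", c(6L, 6L, 0L)),
    make_block("chr1", 151, 300, 40)), "sampleB")
  m <- merge_svcr(list(a, b))
  expect_identical(m$samples, c("sampleA", "sampleB"))
  # row at 150 exists; sampleA has no entry there (sparse)
  e150 <- m$entries[m$entries$pos == 150L]
  expect_identical(e150$sample, "sampleB")
  expect_equal(n_entries(m), n_entries(a) + n_entries(b))
  expect_error(merge_svcr(list(a, a)), "duplicate sample")
})

test_that("two carriers of the same allele share one row with identical LA", {
  mk <- function(s) single_sample_svcr(rbind(
    make_variant("chr1", 10, "A", "T", "0/1", c(4L, 4L, 0L)),
    make_block("chr1", 11, 100, 50)), s)
  m <- merge_svcr(list(mk("s1"), mk("s2")))
  expect_equal(sum(m$rows$pos == 10L), 1L)
  e <- m$entries[m$entries$pos == 10L]
  expect_equal(nrow(e), 2L)
  expect_identical(e$la[[1]], e$la[[2]])
})

test_that("LA maps are rewritten through the merged allele order", {
  # s1 carries T, s2 carries C at the same locus; C collates before T
  s1 <- single_sample_svcr(rbind(
    make_variant("chr1", 10, "A", "T", "0/1", c(4L, 4L, 0L))), "s1")
  s2 <- single_sample_svcr(rbind(
    make_variant("chr1", 10, "A", "C", "0/1", c(4L, 4L, 0L))), "s2")
  m <- merge_svcr(list(s1, s2))
  expect_identical(m$rows$alts[[1]], c("C", "T", "<NON_REF>"))
  e <- m$entries
  expect_identical(e$la[[match("s1", e$sample)]], c(0L, 2L, 3L))
  expect_identical(e$la[[match("s2", e$sample)]], c(0L, 1L, 3L))
  validate_svcr(m)
})

test_that("hierarchical merge counts rounds and equals the flat merge", {
  expect_identical(merge_rounds(1e6, 100), 3L)
  expect_identical(merge_rounds(100, 100), 1L)
  expect_identical(merge_rounds(1, 100), 0L)
  expect_error(merge_rounds(10, 1), ">= 2")
  for (n in c(2L, 10L, 100L)) {
    for (s in c(2L, 3L, 9L, 10L, 11L, 99L, 100L, 101L, 1234L, 10^(2:6))) {
      expect_identical(merge_rounds(s, n), oracle_rounds(s, n))
    }
  }
  co <- tiny_cohort(n_samples = 7, n_trios = 0, seed = 11)
  ss <- lapply(co$gvcf, gvcf_to_svcr)
  h <- hierarchical_merge(ss, branch_factor = 2)
  expect_identical(attr(h, "rounds"), 3L)  # ceil(log2(7))
  flat <- merge_svcr(ss)
  expect_identical(h$rows, flat$rows)
  expect_identical(h$entries, flat$entries)
  expect_error(hierarchical_merge(ss, branch_factor = 1), ">= 2")
})

test_that("any merge bracketing yields an identical dataset", {
  co <- tiny_cohort(n_samples = 6, n_trios = 0, seed = 13)
  ss <- lapply(co$gvcf, gvcf_to_svcr)
  m1 <- merge_svcr(ss)
  m2 <- merge_svcr(list(merge_svcr(ss[1:2]), merge_svcr(ss[3:6])))
  m3 <- merge_svcr(list(merge_svcr(ss[1:5]), ss[[6]]))
  expect_identical(m1$entries, m2$entries)
  expect_identical(m1$entries, m3$entries)
  expect_identical(m1$rows, m2$rows)
})

test_that("densification fills from the most recent spanning block only", {
  a <- single_sample_svcr(rbind(
    make_block("chr1", 1, 99, 20, min_dp = 18),
    make_block("chr1", 100, 200, 32, min_dp = 22)), "sampleA")
  b <- single_sample_svcr(rbind(
    make_variant("chr1", 150, "A", "T", "0/1", c(6L, 6L, 0L)),
    make_variant("chr1", 250, "C", "G", "1/1", c(0L, 8L, 0L))), "sampleB")
  dm <- densify(merge_svcr(list(a, b)))
  ca <- dm$calls[dm$calls$sample == "sampleA"]
  # at 150 the bin-30 block spans: hom-ref fill with the block's GQ bin
  expect_identical(ca$gt[ca$pos == 150L], "0/0")
  expect_identical(ca$gq[ca$pos == 150L], 30L)
  expect_identical(ca$dp[ca$pos == 150L], 22L)
  # at 250 the last block ended at 200: missing
  expect_true(is.na(ca$gt[ca$pos == 250L]))
  # no state across contigs
  b2 <- single_sample_svcr(
    make_variant("chr2", 50, "A", "T", "0/1", c(6L, 6L, 0L)),
    "sampleB", contigs = c("chr1", "chr2"))
  a2 <- gvcf_to_svcr(list(records = make_block("chr1", 1, 1000, 40),
                          sample = "sampleA", contigs = c("chr1", "chr2"),
                          contig_lengths = c(10000L, 10000L)))
  dm2 <- densify(merge_svcr(list(a2, b2)))
  expect_true(is.na(dm2$calls$gt[dm2$calls$sample == "sampleA" &
                                   dm2$calls$pos == 50L]))
})

test_that("densify of a single-sample dataset is an identity relabeling", {
  rec <- rbind(
    make_block("chr1", 1, 9, 40),
    make_variant("chr1", 10, "A", c("C", "T"), "1/2",
                 c(0L, 5L, 6L, 0L), dp = 11L,
                 pl = c(200L, 60L, 0L, 70L, 10L, 20L, 210L, 80L, 90L, 220L)),
    make_block("chr1", 14, 100, 40))
  ds <- single_sample_svcr(rec, "s1")
  dm <- densify(ds)
  cl <- dm$calls[!is.na(dm$calls$gt)]
  expect_identical(cl$gt, "1/2")
  expect_identical(cl$ad[[1]], c(0L, 5L, 6L))  # <NON_REF> slot dropped
  # PL entries over real alleles survive with their values
  expect_identical(cl$pl[[1]], c(200L, 60L, 0L, 70L, 10L, 20L))
})

test_that("densified merge equals the brute-force joint matrix oracle", {
  co <- tiny_cohort(n_samples = 8, n_trios = 2, len = 4000L, rate = 0.012,
                    seed = 23)
  m <- hierarchical_merge(lapply(co$gvcf, gvcf_to_svcr), branch_factor = 3)
  dm <- densify(m)
  oracle <- oracle_joint_matrix(co$gvcf)
  got <- dm$calls[, c("contig", "pos", "sample", "gt")]
  key <- function(d) paste(d$contig, d$pos, d$sample)
  oracle_gt <- oracle$gt[match(key(got), key(oracle))]
  expect_equal(nrow(got), nrow(oracle))
  expect_identical(ifelse(is.na(got$gt), NA_character_, got$gt), oracle_gt)
})

test_that("per-sample export after merging is lossless on modeled fields", {
  co <- tiny_cohort(n_samples = 5, n_trios = 1, seed = 31)
  m <- hierarchical_merge(lapply(co$gvcf, gvcf_to_svcr), branch_factor = 2)
  for (s in co$samples) {
    rt <- svcrkit:::format_gvcf_records(svcr_to_gvcf(m, s))
    orig <- read_gvcf(co$gvcf[[s]])
    binned <- svcrkit:::format_gvcf_records(
      svcrkit:::compress_gvcf_blocks(orig$records, orig$contigs))
    expect_identical(rt, binned)
  }
  # empty column: a sample with zero records
  empty <- gvcf_to_svcr(list(records = svcrkit:::empty_gvcf_records(),
                             sample = "sEmpty", contigs = "chr1",
                             contig_lengths = 5000L))
  m2 <- merge_svcr(list(m, empty))
  expect_equal(nrow(svcr_to_gvcf(m2, "sEmpty")), 0L)
})

test_that("LPL survives expansion to global order and projection back", {
  # a non-monotone local->global map exercises the genotype-index permutation
  la <- c(0L, 2L, 1L, 3L)
  pl <- c(50L, 10L, 0L, 30L, 20L, 60L, 70L, 80L, 90L, 100L)
  cc <- svcrkit:::canonicalize_entry(la, "1/2", c(9L, 4L, 3L, 0L), pl)
  expect_identical(cc$la, c(0L, 1L, 2L, 3L))
  expect_identical(cc$ad, c(9L, 3L, 4L, 0L))
  # applying the inverse permutation recovers the original PL
  back <- svcrkit:::canonicalize_entry(cc$la[order(c(1, 3, 2, 4))], "1/2",
                                       cc$ad[c(1, 3, 2, 4)],
                                       svcrkit:::pl_permute(cc$pl, c(1L, 3L, 2L, 4L)))
  expect_identical(back$pl, cc$pl)
  expect_identical(svcrkit:::pl_permute(cc$pl, c(1L, 3L, 2L, 4L)),
                   pl)
})

test_that("pVCF export writes one line per variant locus and parses back", {
  a <- single_sample_svcr(rbind(
    make_block("chr1", 1, 149, 40),
    make_variant("chr1", 150, "A", "T", "0/1", c(6L, 6L, 0L))), "s1")
  b <- single_sample_svcr(rbind(
    make_variant("chr1", 150, "A", "T", "1/1", c(0L, 9L, 0L)),
    make_variant("chr1", 300, "C", "G", "0/1", c(5L, 5L, 0L))), "s2")
  dm <- densify(merge_svcr(list(a, b)))
  path <- withr::local_tempfile(fileext = ".vcf")
  export_pvcf(dm, path)
  body <- readLines(path)
  body <- body[!startsWith(body, "#")]
  expect_length(body, 2L)
  # s1 has no coverage at 300: exported as ./.
  f300 <- strsplit(body[2], "\t", fixed = TRUE)[[1]]
  expect_match(f300[10], "^\\./\\.")
  back <- read_pvcf(path)
  expect_identical(back$rows$pos, dm$rows$pos)
  key <- function(d) paste(d$contig, d$pos, d$sample)
  expect_identical(back$calls$gt[match(key(dm$calls), key(back$calls))],
                   dm$calls$gt)
})

test_that("exported pVCF is readable by an independent VCF parser", {
  skip_if_not_installed("vcfR")
  co <- tiny_cohort(n_samples = 4, n_trios = 0, seed = 41)
  dm <- densify(merge_svcr(lapply(co$gvcf, gvcf_to_svcr)))
  path <- withr::local_tempfile(fileext = ".vcf")
  export_pvcf(dm, path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  expect_equal(nrow(v@fix), nrow(dm$rows))
  gts <- vcfR::extract.gt(v)
  s1 <- co$samples[1]
  want <- dm$calls$gt[dm$calls$sample == s1]
  got <- unname(gts[, s1])
  expect_identical(is.na(got), is.na(want))
  expect_identical(got[!is.na(got)], want[!is.na(want)])
})
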