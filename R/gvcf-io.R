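#' @importFrom data.table data.table as.data.table setkey setkeyv setorder rbindlist := .N .SD setnames copy fifelse
NULL

# Internal gVCF dialect (VCF v4.2):
#  - reference blocks:  REF = single base, ALT = <NON_REF>, INFO END=<end>,
#    FORMAT GT:DP:GQ:MIN_DP
#  - variant records:   ALT = real alternates followed by <NON_REF>, INFO ".",
#    FORMAT GT:AD:DP:GQ:PL
# Files are 1-based inclusive; all in-memory intervals in this package use the
# same 1-based inclusive convention for gVCF records (END is inclusive).

NON_REF <- "<NON_REF>"

#' Construct an empty gVCF record table
#'
#' Returns a zero-row `data.table` with the columns used throughout the package
#' for single-sample gVCF records: `contig`, `pos`, `ref`, `alts` (list column,
#' including the trailing `<NON_REF>` for variant records), `kind`
#' (`"ref_block"` or `"variant"`), `end` (reference blocks only, 1-based
#' inclusive), `gt`, `ad` (list of integer), `dp`, `gq`, `min_dp`, `pl`
#' (list of integer).
#'
#' @return A zero-row `data.table`.
#' @keywords internal
empty_gvcf_records <- function() {
  data.table(
    contig = character(), pos = integer(), ref = character(),
    alts = list(), kind = character(), end = integer(),
    gt = character(), ad = list(), dp = integer(), gq = integer(),
    min_dp = integer(), pl = list()
  )
}

gvcf_header_lines <- function(sample, contigs, contig_lengths) {
  c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##ALT=<ID=NON_REF,Description=\"Represents any possible alternative allele not already represented\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of reference block (inclusive)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=MIN_DP,Number=1,Type=Integer,Description=\"Minimum depth within reference block\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
    sprintf("##contig=<ID=%s,length=%d>", contigs, contig_lengths),
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
}

format_gvcf_records <- function(rec) {
  if (nrow(rec) == 0L) return(character())
  out <- character(nrow(rec))
  is_blk <- rec$kind == "ref_block"
  if (any(is_blk)) {
    b <- rec[is_blk]
    out[is_blk] <- sprintf(
      "%s\t%d\t.\t%s\t<NON_REF>\t.\t.\tEND=%d\tGT:DP:GQ:MIN_DP\t%s:%d:%d:%d",
      b$contig, b$pos, b$ref, b$end, b$gt, b$dp, b$gq, b$min_dp
    )
  }
  if (any(!is_blk)) {
    v <- rec[!is_blk]
    alt_str <- vapply(v$alts, paste, "", collapse = ",")
    ad_str <- vapply(v$ad, paste, "", collapse = ",")
    pl_str <- vapply(v$pl, paste, "", collapse = ",")
    out[!is_blk] <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT:AD:DP:GQ:PL\t%s:%s:%d:%d:%s",
      v$contig, v$pos, v$ref, alt_str, v$gt, ad_str, v$dp, v$gq, pl_str
    )
  }
  out
}

#' Write a single-sample gVCF
#'
#' @param rec Record table as produced by [read_gvcf()] or the synthetic
#'   generator (see [empty_gvcf_records()] for the column contract).
#' @param sample Sample id placed in the header genotype column.
#' @param contigs Character vector of contig names, in declared order.
#' @param contig_lengths Integer vector of contig lengths (bp).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gvcf <- function(rec, sample, contigs, contig_lengths, path) {
  lines <- c(gvcf_header_lines(sample, contigs, contig_lengths),
             format_gvcf_records(rec))
  writeLines(lines, path)
  invisible(path)
}

parse_int_list <- function(x) lapply(strsplit(x, ",", fixed = TRUE), as.integer)

#' Read a single-sample gVCF
#'
#' Parses the fields modeled by the package (CHROM, POS, REF, ALT, END, GT, AD,
#' DP, GQ, MIN_DP, PL). Returns the record table plus the sample id and contig
#' declarations from the header.
#'
#' @param path Path to a gVCF file written in the package dialect.
#' @return A list with `records` (data.table), `sample`, `contigs`,
#'   `contig_lengths`.
#' @export
read_gvcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  chrom_line <- hdr[startsWith(hdr, "#CHROM")]
  if (length(chrom_line) != 1L) stop("missing #CHROM header line in ", path)
  sample <- utils::tail(strsplit(chrom_line, "\t", fixed = TRUE)[[1]], 1L)
  ctg <- hdr[startsWith(hdr, "##contig=")]
  contigs <- sub(".*ID=([^,>]+).*", "\\1", ctg)
  contig_lengths <- as.integer(sub(".*length=([0-9]+).*", "\\1", ctg))

  if (length(body) == 0L) {
    return(list(records = empty_gvcf_records(), sample = sample,
                contigs = contigs, contig_lengths = contig_lengths))
  }
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  rec <- data.table(contig = f[[1]], pos = as.integer(f[[2]]), ref = f[[4]])
  rec[, alts := strsplit(f[[5]], ",", fixed = TRUE)]
  info <- f[[8]]
  is_blk <- startsWith(info, "END=")
  rec[, kind := fifelse(is_blk, "ref_block", "variant")]
  rec[, end := fifelse(is_blk, suppressWarnings(as.integer(sub("END=", "", info))), NA_integer_)]
  gtf <- data.table::tstrsplit(f[[10]], ":", fixed = TRUE)
  # blocks: GT:DP:GQ:MIN_DP ; variants: GT:AD:DP:GQ:PL
  rec[, gt := gtf[[1]]]
  rec[, dp := as.integer(fifelse(is_blk, gtf[[2]], gtf[[3]]))]
  rec[, gq := as.integer(fifelse(is_blk, gtf[[3]], gtf[[4]]))]
  rec[, min_dp := fifelse(is_blk, suppressWarnings(as.integer(gtf[[4]])), NA_integer_)]
  ad <- vector("list", nrow(rec)); pl <- vector("list", nrow(rec))
  iv <- which(!is_blk)
  if (length(iv)) {
    ad[iv] <- parse_int_list(gtf[[2]][iv])
    pl[iv] <- parse_int_list(gtf[[5]][iv])
  }
  rec[, ad := ad]
  rec[, pl := pl]
  rec[]
  list(records = rec, sample = sample, contigs = contigs,
       contig_lengths = contig_lengths)
}

# genotype string helpers ------------------------------------------------

gt_indices <- function(gt) {
  if (is.na(gt) || gt == "." || gt == "./.") return(NA_integer_)
  as.integer(strsplit(gt, "[/|]")[[1]])
}

gt_string <- function(idx, phased = FALSE) {
  if (length(idx) == 1L && is.na(idx[1])) return("./.")
  paste(idx, collapse = if (phased) "|" else "/")
}
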