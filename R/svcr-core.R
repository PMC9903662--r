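# Scalable Variant Call Representation (SVCR): a sparse locus-by-sample matrix
# of gVCF data. Entries keep per-sample ("local") allele indices via an LA map
# into the row's merged allele list, so merging N datasets never rewrites
# genotype arrays -- only the integer LA maps. Storage is linear in the sum of
# per-sample gVCF record counts.

GQ_BINS <- c(0L, 10L, 20L, 30L, 40L, 50L, 60L)

#' Bin a reference-block genotype quality
#'
#' Compresses reference-block GQ values to the seven canonical bins
#' 0, 10, 20, 30, 40, 50, 60: the largest bin not exceeding the value,
#' capped at 60.
#'
#' @param gq Integer vector of non-negative GQ values.
#' @return Integer vector of binned values.
#' @examples
#' bin_reference_gq(c(0, 37, 99))  # 0, 30, 60
#' @export
bin_reference_gq <- function(gq) {
  if (any(is.na(gq)) || any(gq < 0)) stop("GQ must be non-negative")
  pmin((as.integer(gq) %/% 10L) * 10L, 60L)
}

# deterministic allele collation: real alternates in bytewise lexicographic
# order, then the spanning-deletion allele "*", then <NON_REF> last.
order_alts <- function(alts) {
  real <- setdiff(alts, c("*", NON_REF))
  c(real[order(real, method = "radix")], intersect(c("*", NON_REF), alts))
}

# number of unphased genotypes over n alleles at the given ploidy
n_genotypes <- function(n_alleles, ploidy = 2L) {
  if (ploidy == 1L) n_alleles else n_alleles * (n_alleles + 1L) / 2L
}

# 1-based index of diploid genotype (j, k), 0-based allele indices, j >= k
gidx2 <- function(j, k) j * (j + 1L) / 2L + k + 1L

# Permute a PL array under a reordering of the local alleles. `perm` is the
# 1-based permutation such that new local slot t corresponds to old slot
# perm[t].
pl_permute <- function(pl, perm, ploidy = 2L) {
  n <- length(perm)
  if (ploidy == 1L) return(pl[perm])
  out <- integer(n_genotypes(n))
  for (j in seq_len(n) - 1L) for (k in 0:j) {
    oj <- perm[j + 1L] - 1L; ok <- perm[k + 1L] - 1L
    out[gidx2(j, k)] <- pl[gidx2(max(oj, ok), min(oj, ok))]
  }
  out
}

svcr_entry_cols <- c("contig", "pos", "sample", "kind", "la", "gt", "ad",
                     "dp", "gq", "min_dp", "pl", "end")

new_svcr <- function(samples, contigs, rows, entries) {
  setorder(rows, contig_rank, pos)
  rows[, contig_rank := NULL]
  structure(list(samples = samples, contigs = contigs,
                 rows = rows, entries = entries),
            class = "svcr")
}

#' @export
print.svcr <- function(x, ...) {
  cat(sprintf("SVCR dataset: %d samples, %d rows, %d stored entries\n",
              length(x$samples), nrow(x$rows), nrow(x$entries)))
  invisible(x)
}

#' Number of stored (dense) entries in an SVCR dataset
#'
#' Merging preserves this count, which is the package's linear-storage
#' invariant: the total equals the sum of per-sample gVCF record counts after
#' block compression.
#'
#' @param ds An `svcr` object.
#' @return Integer count.
#' @export
n_entries <- function(ds) nrow(ds$entries)

#' Validate the structural invariants of an SVCR dataset
#'
#' Checks row ordering/uniqueness and the per-entry invariants: `LA[1] = 0`
#' and strictly increasing, `|LAD| = |LA|`, `|LPL|` equal to the number of
#' genotypes over `|LA|` alleles at the entry's ploidy, and every genotype
#' index below `|LA|`.
#'
#' @param ds An `svcr` object.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_svcr <- function(ds) {
  rows <- ds$rows
  key <- paste(rows$contig, rows$pos)
  if (anyDuplicated(key)) stop("duplicate row loci")
  rk <- match(rows$contig, ds$contigs)
  if (any(is.na(rk))) stop("row contig not declared")
  if (is.unsorted(order(rk, rows$pos))) stop("rows not locus-sorted")
  ent <- ds$entries
  if (nrow(ent)) {
    for (i in seq_len(nrow(ent))) {
      la <- ent$la[[i]]
      if (la[1] != 0L) stop("LA[1] != 0 at entry ", i)
      if (is.unsorted(la, strictly = TRUE)) stop("LA not strictly increasing at entry ", i)
      if (ent$kind[i] == "variant") {
        gti <- gt_indices(ent$gt[i])
        ploidy <- length(gti)
        if (any(gti >= length(la))) stop("LGT index out of LA range at entry ", i)
        if (length(ent$ad[[i]]) != length(la)) stop("|LAD| != |LA| at entry ", i)
        if (length(ent$pl[[i]]) != n_genotypes(length(la), ploidy))
          stop("|LPL| inconsistent with |LA| at entry ", i)
      }
    }
    if (!all(ent$sample %in% ds$samples)) stop("entry sample not in dataset")
  }
  invisible(TRUE)
}

# Bin reference-block GQs and merge contiguous same-bin blocks. Operates on a
# single-sample gVCF record table; returns the compressed record table on
# which losslessness is defined.
compress_gvcf_blocks <- function(rec, contigs) {
  if (nrow(rec) == 0L) return(rec)
  rec <- copy(rec)
  validate_gvcf_sorted(rec, contigs)
  blk <- rec$kind == "ref_block"
  rec[blk == TRUE, gq := bin_reference_gq(gq)]
  # group contiguous same-bin blocks: a record starts a new group unless it is
  # a block directly abutting a previous block with the same bin
  n <- nrow(rec)
  new_grp <- rep(TRUE, n)
  if (n > 1L) {
    prev <- seq_len(n - 1L); cur <- prev + 1L
    abut <- blk[cur] & blk[prev] &
      rec$contig[cur] == rec$contig[prev] &
      rec$pos[cur] == rec$end[prev] + 1L &
      rec$gq[cur] == rec$gq[prev]
    new_grp[cur] <- !abut
  }
  grp <- cumsum(new_grp)
  if (max(grp) == n) return(rec)
  first <- which(new_grp)
  out <- rec[first]
  last <- c(first[-1] - 1L, n)
  for (g in which(last > first)) {  # merged block runs
    data.table::set(out, g, "end", rec$end[last[g]])
    data.table::set(out, g, "min_dp", min(rec$min_dp[first[g]:last[g]]))
  }
  out[]
}

validate_gvcf_sorted <- function(rec, contigs) {
  rk <- match(rec$contig, contigs)
  if (any(is.na(rk))) stop("record contig not declared: ",
                           rec$contig[which(is.na(rk))[1]])
  o <- order(rk, rec$pos)
  if (!identical(o, seq_len(nrow(rec)))) {
    bad <- which(o != seq_len(nrow(rec)))[1]
    stop("gVCF records not locus-sorted at ", rec$contig[bad], ":", rec$pos[bad])
  }
  # spans: blocks cover pos..end; variants cover pos..pos+nchar(ref)-1
  span_end <- ifelse(rec$kind == "ref_block", rec$end,
                     rec$pos + nchar(rec$ref) - 1L)
  same <- rec$contig[-1] == rec$contig[-nrow(rec)]
  if (nrow(rec) > 1L && any(same & rec$pos[-1] <= span_end[-nrow(rec)])) {
    bad <- which(same & rec$pos[-1] <= span_end[-nrow(rec)])[1] + 1L
    stop("overlapping gVCF records at ", rec$contig[bad], ":", rec$pos[bad])
  }
  invisible(TRUE)
}

#' Convert a single-sample gVCF to a single-column SVCR dataset
#'
#' Applies reference-block GQ binning (merging contiguous same-bin blocks),
#' then performs the trivial reorganization into the sparse representation:
#' one row per record (monomorphic rows where reference blocks begin), one
#' dense entry per row, `LA` the identity map over the record's own alleles.
#'
#' @param x Either a path to a gVCF file or a list as returned by
#'   [read_gvcf()].
#' @return An `svcr` object with one column.
#' @export
gvcf_to_svcr <- function(x) {
  if (is.character(x)) x <- read_gvcf(x)
  rec <- compress_gvcf_blocks(x$records, x$contigs)
  nr <- nrow(rec)
  if (nr == 0L) {
    rows <- data.table(contig = character(), pos = integer(),
                       ref = character(), alts = list(),
                       contig_rank = integer())
    return(new_svcr(samples = x$sample, contigs = x$contigs, rows = rows,
                    entries = empty_entries()))
  }
  is_blk <- rec$kind == "ref_block"
  rows <- data.table(
    contig = rec$contig, pos = rec$pos, ref = rec$ref,
    alts = lapply(seq_len(nr), function(i)
      if (is_blk[i]) character() else rec$alts[[i]])
  )
  rows[, contig_rank := match(contig, x$contigs)]
  entries <- data.table(
    contig = rec$contig, pos = rec$pos, sample = rep(x$sample, nr),
    kind = rec$kind,
    la = lapply(seq_len(nr), function(i)
      if (is_blk[i]) 0L else 0:length(rec$alts[[i]])),
    gt = rec$gt, ad = rec$ad, dp = rec$dp, gq = rec$gq,
    min_dp = rec$min_dp, pl = rec$pl, end = rec$end
  )
  new_svcr(samples = x$sample, contigs = x$contigs, rows = rows,
           entries = entries)
}

empty_entries <- function() {
  data.table(contig = character(), pos = integer(), sample = character(),
             kind = character(), la = list(), gt = character(), ad = list(),
             dp = integer(), gq = integer(), min_dp = integer(), pl = list(),
             end = integer())
}

#' Merge allele lists at one locus
#'
#' Computes the union of alternate alleles across inputs, sorted by the
#' package's deterministic collation (lexicographic, symbolic alleles `*` and
#' `<NON_REF>` last), together with the map from each input's allele indices
#' to merged indices.
#'
#' Reference strings must agree across inputs that carry alternate alleles; a
#' monomorphic input (a row materialized where a reference block begins)
#' contributes only its single reference base, which must be a prefix of the
#' merged reference.
#'
#' @param allele_sets List of `list(ref =, alts =)` pairs, one per input.
#' @return `list(ref, alts, maps)` where `maps[[i]]` sends 0-based input
#'   allele index `j` to merged index `maps[[i]][j + 1]`.
#' @export
merge_alleles <- function(allele_sets) {
  refs <- vapply(allele_sets, `[[`, "", "ref")
  n_alt <- vapply(allele_sets, function(s) length(s$alts), 0L)
  var_refs <- unique(refs[n_alt > 0L])
  if (length(var_refs) > 1L)
    stop("conflicting reference alleles: ", paste(var_refs, collapse = " vs "))
  ref <- if (length(var_refs)) var_refs else {
    u <- unique(refs)
    if (length(u) > 1L) stop("conflicting reference alleles: ",
                             paste(u, collapse = " vs "))
    u
  }
  if (any(substr(refs, 1L, 1L) != substr(ref, 1L, 1L)))
    stop("reference alleles disagree on leading base")
  alts <- order_alts(unique(unlist(lapply(allele_sets, `[[`, "alts"))))
  maps <- lapply(allele_sets, function(s)
    c(0L, match(s$alts, alts)))
  list(ref = ref, alts = alts, maps = maps)
}

# Rewrite one entry's local arrays so LA is strictly increasing; gt/ad/pl are
# permuted consistently (standard VCF genotype-index ordering for PL).
canonicalize_entry <- function(la, gt, ad, pl) {
  perm <- order(la)
  if (identical(perm, seq_along(la)))
    return(list(la = la, gt = gt, ad = ad, pl = pl))
  inv <- match(seq_along(la), perm)  # old slot t -> new slot inv[t]
  gti <- gt_indices(gt)
  new_gt <- gt_string(sort(inv[gti + 1L] - 1L, decreasing = FALSE))
  list(la = la[perm], gt = new_gt, ad = ad[perm],
       pl = pl_permute(pl, perm, ploidy = length(gti)))
}

#' Merge SVCR datasets
#'
#' Performs the outer join on loci: merged rows carry the union of loci, the
#' deterministically sorted allele union per locus ([merge_alleles()]), and
#' every input entry with its `LA` rewritten through the input's allele index
#' map. Entries remain absent (sparse) where an input had no record at a
#' locus, so the stored entry count is unchanged by merging.
#'
#' @param dss List of `svcr` objects with disjoint sample sets.
#' @return The merged `svcr` object.
#' @export
merge_svcr <- function(dss) {
  stopifnot(length(dss) >= 1L)
  if (length(dss) == 1L) return(dss[[1]])
  samples <- unlist(lapply(dss, `[[`, "samples"))
  if (anyDuplicated(samples))
    stop("duplicate sample id across inputs: ",
         samples[anyDuplicated(samples)])
  contigs <- Reduce(function(a, b) c(a, setdiff(b, a)),
                    lapply(dss, `[[`, "contigs"))

  all_rows <- rbindlist(lapply(seq_along(dss), function(i) {
    r <- copy(dss[[i]]$rows); r[, input := i]; r
  }))
  setkey(all_rows, contig, pos)
  merged <- all_rows[, {
    ma <- tryCatch(
      merge_alleles(lapply(seq_len(.N), function(j)
        list(ref = ref[j], alts = alts[[j]]))),
      error = function(e) stop("at ", .BY$contig, ":", .BY$pos, ": ",
                               conditionMessage(e), call. = FALSE))
    list(ref = ma$ref, alts = list(ma$alts),
         input = list(input), maps = list(ma$maps))
  }, by = .(contig, pos)]

  # per-input locus -> allele map table
  map_tbl <- merged[, {
    ins <- input[[1]]
    list(input = ins, map = maps[[1]])
  }, by = .(contig, pos)]

  ents <- rbindlist(lapply(seq_along(dss), function(i) {
    e <- copy(dss[[i]]$entries); e[, input := i]; e
  }))
  if (nrow(ents)) {
    ents <- merge(ents, map_tbl, by = c("contig", "pos", "input"), sort = FALSE)
    for (r in seq_len(nrow(ents))) {
      m <- ents$map[[r]]
      la2 <- m[ents$la[[r]] + 1L]
      if (is.unsorted(la2, strictly = TRUE)) {
        cc <- canonicalize_entry(la2, ents$gt[r], ents$ad[[r]], ents$pl[[r]])
        data.table::set(ents, r, "la", list(list(cc$la)))
        data.table::set(ents, r, "gt", cc$gt)
        data.table::set(ents, r, "ad", list(list(cc$ad)))
        data.table::set(ents, r, "pl", list(list(cc$pl)))
      } else {
        data.table::set(ents, r, "la", list(list(la2)))
      }
    }
    ents[, c("input", "map") := NULL]
  } else {
    ents <- empty_entries()
  }
  rows <- merged[, .(contig, pos, ref, alts)]
  rows[, contig_rank := match(contig, contigs)]
  ents[, .rk := match(contig, contigs)]
  setorder(ents, .rk, pos, sample)
  ents[, .rk := NULL]
  new_svcr(samples = samples, contigs = contigs, rows = rows, entries = ents)
}

#' Number of hierarchical merge rounds
#'
#' `ceiling(log_N(S))` computed by integer iteration: the number of rounds a
#' branch-factor-`N` hierarchical merge needs to reduce `S` inputs to one.
#'
#' @param n_inputs Number of single-sample inputs (`S >= 1`).
#' @param branch_factor Branch factor (`N >= 2`).
#' @return Integer number of rounds (0 for a single input).
#' @examples
#' merge_rounds(1e6, 100)  # 3
#' @export
merge_rounds <- function(n_inputs, branch_factor = 100L) {
  stopifnot(n_inputs >= 1L)
  if (branch_factor < 2L) stop("branch factor must be >= 2")
  r <- 0L; s <- n_inputs
  while (s > 1L) {
    s <- ceiling(s / branch_factor)
    r <- r + 1L
  }
  r
}

#' Hierarchical merge of SVCR datasets
#'
#' Repeatedly merges groups of at most `branch_factor` datasets until a single
#' SVCR remains. The result is entry-identical to a flat [merge_svcr()] over
#' all inputs; the number of executed rounds (`ceiling(log_N(S))`) is attached
#' as attribute `"rounds"`.
#'
#' @param dss List of `svcr` objects.
#' @param branch_factor Maximum number of datasets merged per group
#'   (default 100).
#' @return Merged `svcr` with attribute `"rounds"`.
#' @export
hierarchical_merge <- function(dss, branch_factor = 100L) {
  if (branch_factor < 2L) stop("branch factor must be >= 2")
  stopifnot(length(dss) >= 1L)
  rounds <- 0L
  while (length(dss) > 1L) {
    grp <- split(dss, ceiling(seq_along(dss) / branch_factor))
    dss <- lapply(grp, merge_svcr)
    rounds <- rounds + 1L
  }
  out <- dss[[1]]
  attr(out, "rounds") <- rounds
  out
}

# global allele list of a row: ref plus alternates (including symbolic)
row_alleles <- function(ref, alts) c(ref, alts)

real_alt_count <- function(alts) length(setdiff(alts, c("*", NON_REF)))

#' Densify an SVCR dataset
#'
#' Produces a dense per-sample call matrix at the requested loci (by default
#' every row carrying at least one real alternate allele). For each row and
#' sample, a defined variant entry is converted to global allele indices via
#' its `LA` map; otherwise the sample's most recent reference block on the
#' same contig fills a homozygous-reference call if (and only if) its `END`
#' spans the locus; otherwise the call is missing. No reference-block state is
#' carried across contigs. The symbolic `<NON_REF>` allele is dropped from the
#' dense allele lists; `AD`/`PL` slots involving alleles absent from a
#' sample's record are `NA`.
#'
#' @param ds An `svcr` object.
#' @param loci Optional `data.frame`/`data.table` with columns `contig`, `pos`
#'   restricting the output rows.
#' @return A `dense_matrix` object: `samples`, `contigs`, `rows` (with real
#'   alternates only) and `calls` (one row per locus and sample; missing calls
#'   have `gt = NA`).
#' @export
densify <- function(ds, loci = NULL) {
  rows <- copy(ds$rows)
  rows[, n_real := vapply(alts, real_alt_count, 0L)]
  targets <- if (is.null(loci)) rows[n_real > 0L] else {
    loci <- as.data.table(loci)[, .(contig, pos)]
    merge(rows, loci, by = c("contig", "pos"), sort = FALSE)
  }
  targets[, rk := match(contig, ds$contigs)]
  setorder(targets, rk, pos)

  out_rows <- targets[, .(contig, pos, ref,
                          alts = lapply(alts, function(a)
                            setdiff(a, c("*", NON_REF))))]
  ents <- ds$entries
  var_e <- ents[kind == "variant"]
  blk_e <- ents[kind == "ref_block"]

  calls <- vector("list", length(ds$samples))
  for (si in seq_along(ds$samples)) {
    s <- ds$samples[si]
    sv <- var_e[sample == s]
    sb <- blk_e[sample == s]
    cl <- data.table(contig = targets$contig, pos = targets$pos,
                     sample = s, gt = NA_character_, ad = list(NULL),
                     dp = NA_integer_, gq = NA_integer_, pl = list(NULL))
    # fill from reference blocks (per contig, most recent block spanning pos)
    for (ctg in unique(cl$contig)) {
      tp <- which(cl$contig == ctg)
      bb <- sb[contig == ctg]
      if (nrow(bb) == 0L) next
      idx <- findInterval(cl$pos[tp], bb$pos)
      ok <- idx >= 1L & bb$end[pmax(idx, 1L)] >= cl$pos[tp]
      hit <- tp[ok]; bi <- idx[ok]
      if (length(hit)) {
        data.table::set(cl, hit, "gt", "0/0")
        data.table::set(cl, hit, "dp", bb$min_dp[bi])
        data.table::set(cl, hit, "gq", bb$gq[bi])
      }
    }
    # overwrite with defined variant entries
    if (nrow(sv)) {
      key_t <- paste(targets$contig, targets$pos)
      key_v <- paste(sv$contig, sv$pos)
      hit <- match(key_v, key_t)
      for (j in which(!is.na(hit))) {
        ti <- hit[j]
        alleles <- row_alleles(targets$ref[ti], targets$alts[[ti]])
        real <- setdiff(targets$alts[[ti]], c("*", NON_REF))
        n_real <- 1L + length(real)
        la <- sv$la[[j]]
        gti <- gt_indices(sv$gt[j])
        g_global <- la[gti + 1L]
        ad_g <- rep(NA_integer_, n_real)
        keep <- which(la < n_real)  # global indices of real alleles are 0..n_real-1
        ad_g[la[keep] + 1L] <- sv$ad[[j]][keep]
        ploidy <- length(gti)
        pl_g <- rep(NA_integer_, n_genotypes(n_real, ploidy))
        if (ploidy == 2L) {
          for (a in keep) for (b in keep[keep <= a]) {
            pl_g[gidx2(la[a], la[b])] <- sv$pl[[j]][gidx2(a - 1L, b - 1L)]
          }
        } else {
          pl_g[la[keep] + 1L] <- sv$pl[[j]][keep]
        }
        data.table::set(cl, ti, "gt", gt_string(g_global))
        data.table::set(cl, ti, "ad", list(list(ad_g)))
        data.table::set(cl, ti, "dp", sv$dp[j])
        data.table::set(cl, ti, "gq", sv$gq[j])
        data.table::set(cl, ti, "pl", list(list(pl_g)))
      }
    }
    calls[[si]] <- cl
  }
  structure(list(samples = ds$samples, contigs = ds$contigs,
                 rows = out_rows, calls = rbindlist(calls)),
            class = "dense_matrix")
}

#' @export
print.dense_matrix <- function(x, ...) {
  cat(sprintf("Dense matrix: %d samples x %d rows\n",
              length(x$samples), nrow(x$rows)))
  invisible(x)
}

#' Reconstruct a sample's gVCF records from an SVCR dataset
#'
#' Reverses the SVCR transformation for one column: reference-block entries
#' become reference-block records and variant entries recover their original
#' alleles through `LA`. On the modeled fields this reproduces the sample's
#' GQ-binned, block-merged input gVCF exactly (the representation is lossless
#' from the binned file onward).
#'
#' @param ds An `svcr` object.
#' @param sample Sample id (must be one of `ds$samples`).
#' @return A gVCF record `data.table` (see [empty_gvcf_records()]).
#' @export
svcr_to_gvcf <- function(ds, sample) {
  if (!sample %in% ds$samples) stop("unknown sample: ", sample)
  sm <- sample
  e <- ds$entries[ds$entries$sample == sm]
  if (nrow(e) == 0L) return(empty_gvcf_records())
  rows <- ds$rows
  ri <- match(paste(e$contig, e$pos), paste(rows$contig, rows$pos))
  n <- nrow(e)
  is_blk <- e$kind == "ref_block"
  ref_out <- character(n)
  alts_out <- vector("list", n)
  for (j in seq_len(n)) {
    r <- ri[j]
    if (is_blk[j]) {
      ref_out[j] <- substr(rows$ref[r], 1L, 1L)
      alts_out[[j]] <- NON_REF
    } else {
      alleles <- row_alleles(rows$ref[r], rows$alts[[r]])
      la <- e$la[[j]]
      if (any(la + 1L > length(alleles)))
        stop("corrupt entry: LA references allele absent from row at ",
             e$contig[j], ":", e$pos[j])
      ref_out[j] <- alleles[1L]
      alts_out[[j]] <- alleles[la[-1L] + 1L]
    }
  }
  rec <- data.table(
    contig = e$contig, pos = e$pos, ref = ref_out, alts = alts_out,
    kind = e$kind, end = e$end, gt = e$gt,
    ad = lapply(seq_len(n), function(j) if (is_blk[j]) NULL else e$ad[[j]]),
    dp = e$dp, gq = e$gq,
    min_dp = fifelse(is_blk, e$min_dp, NA_integer_),
    pl = lapply(seq_len(n), function(j) if (is_blk[j]) NULL else e$pl[[j]])
  )
  rec[, rk := match(contig, ds$contigs)]
  setorder(rec, rk, pos)
  rec[, rk := NULL]
  rec[]
}

#' Export a dense matrix as a multi-sample VCF (pVCF)
#'
#' Writes one data line per variant locus with `GT`, `AD`, `DP`, `GQ`, `PL` in
#' global allele indices; missing calls appear as `./.` and unavailable
#' subfields as `.`.
#'
#' @param dm A `dense_matrix` from [densify()].
#' @param path Output file path.
#' @param contig_lengths Optional named integer vector of contig lengths for
#'   the header.
#' @return `path`, invisibly.
#' @export
export_pvcf <- function(dm, path, contig_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">"
  )
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), contig_lengths))
  } else {
    hdr <- c(hdr, sprintf("##contig=<ID=%s>", dm$contigs))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", dm$samples), collapse = "\t"))
  fmt_list <- function(x) if (is.null(x) || all(is.na(x))) "." else
    paste(ifelse(is.na(x), ".", as.character(x)), collapse = ",")
  calls <- copy(dm$calls)
  calls[, cell := "./.:.:.:.:."]
  def <- which(!is.na(calls$gt))
  if (length(def)) {
    cells <- vapply(def, function(j)
      sprintf("%s:%s:%s:%s:%s", calls$gt[j], fmt_list(calls$ad[[j]]),
              if (is.na(calls$dp[j])) "." else calls$dp[j],
              if (is.na(calls$gq[j])) "." else calls$gq[j],
              fmt_list(calls$pl[[j]])), "")
    data.table::set(calls, def, "cell", cells)
  }
  wide <- data.table::dcast(calls, contig + pos ~ sample,
                            value.var = "cell", fill = "./.:.:.:.:.")
  ord <- match(paste(dm$rows$contig, dm$rows$pos),
               paste(wide$contig, wide$pos))
  cell_mat <- as.matrix(wide[ord, dm$samples, with = FALSE])
  lines <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT:AD:DP:GQ:PL\t%s",
    dm$rows$contig, dm$rows$pos, dm$rows$ref,
    vapply(dm$rows$alts, paste, "", collapse = ","),
    apply(cell_mat, 1L, paste, collapse = "\t"))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a pVCF written by [export_pvcf()] back into a dense matrix
#'
#' @param path Path to the VCF.
#' @return A `dense_matrix` object.
#' @export
read_pvcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  chrom <- strsplit(hdr[startsWith(hdr, "#CHROM")], "\t", fixed = TRUE)[[1]]
  samples <- chrom[-(1:9)]
  contigs <- sub(".*ID=([^,>]+).*", "\\1",
                 hdr[startsWith(hdr, "##contig=")])
  parse_sub <- function(x) if (x == ".") NULL else
    as.integer(ifelse(strsplit(x, ",", fixed = TRUE)[[1]] == ".", NA, strsplit(x, ",", fixed = TRUE)[[1]]))
  rows_l <- list(); calls_l <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    rows_l[[length(rows_l) + 1L]] <- data.table(
      contig = f[1], pos = as.integer(f[2]), ref = f[4],
      alts = list(strsplit(f[5], ",", fixed = TRUE)[[1]]))
    for (si in seq_along(samples)) {
      g <- strsplit(f[9L + si], ":", fixed = TRUE)[[1]]
      calls_l[[length(calls_l) + 1L]] <- data.table(
        contig = f[1], pos = as.integer(f[2]), sample = samples[si],
        gt = if (g[1] %in% c("./.", ".")) NA_character_ else g[1],
        ad = list(parse_sub(g[2])),
        dp = if (g[3] == ".") NA_integer_ else as.integer(g[3]),
        gq = if (g[4] == ".") NA_integer_ else as.integer(g[4]),
        pl = list(parse_sub(g[5])))
    }
  }
  structure(list(samples = samples, contigs = contigs,
                 rows = rbindlist(rows_l), calls = rbindlist(calls_l)),
            class = "dense_matrix")
}
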