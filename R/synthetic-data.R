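# Synthetic cohort generator: multi-sample gVCF cohorts with reference blocks
# and trios, truth genotypes, capture intervals, pedigree-derived sparse GRMs,
# and gene/class annotations. Everything is driven by a single seeded RNG
# stream, so identical specs yield byte-identical files.

BASES <- c("A", "C", "G", "T")

# deterministic pseudo-reference: the base at a position is a fixed function
# of the position, so every sample (and every reference block start) agrees on
# the reference sequence without storing one
ref_base <- function(pos) BASES[((pos * 7L + 3L) %% 4L) + 1L]

#' Specify a synthetic exome cohort
#'
#' @param n_samples Total number of samples (trio members included).
#' @param n_trios Number of parent-parent-offspring trios; the first
#'   `3 * n_trios` samples are organized as trios. Must satisfy
#'   `3 * n_trios <= n_samples`.
#' @param contigs Named integer vector of contig lengths in bp.
#' @param variant_rate Per-base probability that a site is polymorphic in the
#'   cohort, in `[0, 1]`.
#' @param af_shape Length-2 shape parameters of the Beta distribution the true
#'   alternate-allele frequencies are drawn from. The default `(0.2, 2)` gives
#'   the rare-skewed spectrum typical of exome cohorts.
#' @param mean_depth Mean sequencing depth (Poisson model).
#' @param error_rate Per-read base error rate used for the symmetric
#'   genotype-likelihood model behind AD/PL/GQ.
#' @param de_novo_rate Per-transmission probability that an offspring allele is
#'   replaced by a random site allele.
#' @param seed Integer seed; mandatory for reproducibility.
#' @return A validated `cohort_spec` object.
#' @export
cohort_spec <- function(n_samples, n_trios = 0L,
                        contigs = c(chr1 = 100000L),
                        variant_rate = 0.005,
                        af_shape = c(0.2, 2),
                        mean_depth = 30,
                        error_rate = 1e-3,
                        de_novo_rate = 0,
                        seed = 1L) {
  spec <- structure(list(
    n_samples = as.integer(n_samples), n_trios = as.integer(n_trios),
    contigs = contigs, variant_rate = variant_rate, af_shape = af_shape,
    mean_depth = mean_depth, error_rate = error_rate,
    de_novo_rate = de_novo_rate, seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_samples < 1L) stop("n_samples must be >= 1")
  if (spec$n_trios < 0L) stop("n_trios must be >= 0")
  if (3L * spec$n_trios > spec$n_samples)
    stop("3 * n_trios must not exceed n_samples (",
         3L * spec$n_trios, " > ", spec$n_samples, ")")
  if (length(spec$contigs) < 1L || any(spec$contigs < 1L))
    stop("contig lengths must be >= 1")
  if (is.null(names(spec$contigs)) || any(names(spec$contigs) == ""))
    stop("contigs must be a named vector of lengths")
  for (fld in c("variant_rate", "de_novo_rate")) {
    v <- spec[[fld]]
    if (v < 0 || v > 1) stop(fld, " must lie in [0, 1], got ", v)
  }
  if (spec$mean_depth <= 0) stop("mean_depth must be positive")
  if (length(spec$af_shape) != 2L || any(spec$af_shape <= 0))
    stop("af_shape must be two positive Beta shape parameters")
  invisible(TRUE)
}

# draw the cohort's polymorphic sites for one contig
draw_sites <- function(contig, len, spec) {
  n_sites <- stats::rbinom(1L, max(len - 10L, 0L), spec$variant_rate)
  if (n_sites == 0L)
    return(data.table(contig = character(), pos = integer(),
                      ref = character(), alts = list(), af = list()))
  pos <- sort(sample.int(max(len - 10L, 1L), n_sites)) + 2L
  keep <- c(TRUE, diff(pos) > 6L)  # spacing so record spans never collide
  pos <- pos[keep]
  n <- length(pos)
  type <- sample(c("snv", "ins", "del"), n, replace = TRUE,
                 prob = c(0.8, 0.1, 0.1))
  n_alt <- sample(1:2, n, replace = TRUE, prob = c(0.85, 0.15))
  refs <- character(n); alts <- vector("list", n); afs <- vector("list", n)
  for (i in seq_len(n)) {
    base <- ref_base(pos[i])
    a <- switch(type[i],
      snv = sample(setdiff(BASES, base), n_alt[i]),
      ins = unique(vapply(seq_len(n_alt[i]), function(k)
        paste0(base, paste(sample(BASES, k, replace = TRUE), collapse = "")),
        "")),
      del = {
        sizes <- sort(sample(1:3, n_alt[i]))
        full <- paste(ref_base(pos[i] + 0:max(sizes)), collapse = "")
        refs[i] <- full
        substr(rep(full, length(sizes)), 1L, nchar(full) - sizes)
      })
    if (type[i] != "del") refs[i] <- base
    a <- unique(a)
    a <- order_alts(a)
    f <- stats::rbeta(length(a), spec$af_shape[1], spec$af_shape[2])
    if (sum(f) > 0.9) f <- 0.9 * f / sum(f)
    alts[[i]] <- a; afs[[i]] <- f
  }
  data.table(contig = contig, pos = pos, ref = refs, alts = alts, af = afs)
}

draw_genotypes <- function(sites, spec) {
  n_s <- spec$n_samples
  n_v <- nrow(sites)
  a1 <- matrix(0L, n_v, n_s); a2 <- matrix(0L, n_v, n_s)
  trio_child <- if (spec$n_trios > 0L) 3L * seq_len(spec$n_trios) else integer()
  founders <- setdiff(seq_len(n_s), trio_child)
  for (i in seq_len(n_v)) {
    p <- c(1 - sum(sites$af[[i]]), sites$af[[i]])
    draws <- sample.int(length(p), 2L * length(founders), replace = TRUE,
                        prob = p) - 1L
    a1[i, founders] <- draws[seq_along(founders)]
    a2[i, founders] <- draws[length(founders) + seq_along(founders)]
  }
  # trio t: samples (3t-2, 3t-1, 3t) = father, mother, child
  for (t in seq_len(spec$n_trios)) {
    fa <- 3L * t - 2L; mo <- 3L * t - 1L; ch <- 3L * t
    pick_f <- stats::runif(n_v) < 0.5
    pick_m <- stats::runif(n_v) < 0.5
    a1[, ch] <- ifelse(pick_f, a1[, fa], a2[, fa])
    a2[, ch] <- ifelse(pick_m, a1[, mo], a2[, mo])
    if (spec$de_novo_rate > 0) {
      for (i in which(stats::runif(n_v) < spec$de_novo_rate)) {
        n_all <- length(sites$alts[[i]]) + 1L
        slot <- sample(1:2, 1L)
        if (slot == 1L) a1[i, ch] <- sample.int(n_all, 1L) - 1L
        else a2[i, ch] <- sample.int(n_all, 1L) - 1L
      }
    }
  }
  list(a1 = a1, a2 = a2)
}

# PL/GQ/AD model: reads are multinomial over the record's local alleles with a
# symmetric error rate; likelihoods use the same model, so PL is internally
# consistent with AD.
simulate_variant_call <- function(alleles_local, gt_local, spec) {
  n_all <- length(alleles_local) + 1L  # + <NON_REF>
  e <- spec$error_rate
  dp <- max(1L, stats::rpois(1L, spec$mean_depth))
  dose <- tabulate(gt_local + 1L, nbins = n_all)
  p_read <- dose / 2 * (1 - n_all * e) + e
  p_read[n_all] <- e  # <NON_REF>
  p_read <- p_read / sum(p_read)
  ad <- as.integer(stats::rmultinom(1L, dp, p_read))
  # unphased genotype likelihoods in VCF order: (j, k) with j >= k
  ll <- numeric(n_genotypes(n_all))
  for (j in 0:(n_all - 1L)) for (k in 0:j) {
    d <- tabulate(c(j, k) + 1L, nbins = n_all)
    pk <- d / 2 * (1 - n_all * e) + e
    pk <- pk / sum(pk)
    ll[gidx2(j, k)] <- sum(ad * log(pk))
  }
  pl <- round(-10 * (ll - max(ll)))
  gq <- min(99, sort(pl)[2])
  list(dp = dp, ad = ad, pl = as.integer(pl), gq = as.integer(gq))
}

emit_blocks <- function(contig, from, to, spec) {
  out <- list()
  cur <- from
  while (cur <= to) {
    len <- min(to - cur + 1L, 1L + stats::rpois(1L, 300L))
    gq <- as.integer(max(0, min(99, round(stats::rnorm(1L, 50, 15)))))
    dp <- stats::rpois(1L, spec$mean_depth)
    min_dp <- max(0L, dp - stats::rpois(1L, 2L))
    out[[length(out) + 1L]] <- data.table(
      contig = contig, pos = cur, ref = ref_base(cur),
      alts = list(NON_REF), kind = "ref_block",
      end = cur + len - 1L, gt = "0/0", ad = list(NULL), dp = dp,
      gq = gq, min_dp = min_dp, pl = list(NULL))
    cur <- cur + len
  }
  rbindlist(out)
}

#' Generate a synthetic gVCF cohort
#'
#' Writes one gVCF per sample (reference blocks with END/GQ/DP/MIN_DP
#' alternating with variant records carrying the sample's discovered alleles
#' plus `<NON_REF>`), a 6-column pedigree, a BED capture-interval file and a
#' truth table of genotype doses and true allele frequencies. Trio offspring
#' genotypes are Mendelian transmissions from their parents at the spec's
#' de novo rate. Output is byte-identical for identical specs.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @return A list: `spec`, `samples`, `gvcf` (named file paths), `ped_path`,
#'   `bed_path`, `truth_path`, `sites` (per-site table with true AFs),
#'   `variants` (per-alternate table keyed `contig:pos:ref:alt`), `dose`
#'   (variants x samples integer matrix), and the raw allele matrices
#'   `a1`/`a2`.
#' @export
generate_cohort <- function(spec, dir) {
  validate_cohort_spec(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  contigs <- names(spec$contigs)

  sites <- rbindlist(lapply(contigs, function(ctg)
    draw_sites(ctg, spec$contigs[[ctg]], spec)))
  geno <- draw_genotypes(sites, spec)

  gvcf_paths <- character(spec$n_samples)
  for (si in seq_len(spec$n_samples)) {
    recs <- list()
    for (ctg in contigs) {
      len <- spec$contigs[[ctg]]
      idx <- which(sites$contig == ctg)
      carried <- idx[geno$a1[idx, si] > 0L | geno$a2[idx, si] > 0L]
      cur <- 1L
      for (i in carried) {
        if (sites$pos[i] > cur)
          recs[[length(recs) + 1L]] <-
            emit_blocks(ctg, cur, sites$pos[i] - 1L, spec)
        g <- sort(c(geno$a1[i, si], geno$a2[i, si]))
        carried_alts <- sort(unique(g[g > 0L]))
        local_alts <- sites$alts[[i]][carried_alts]
        gt_local <- match(g, c(0L, carried_alts)) - 1L
        call <- simulate_variant_call(c(sites$ref[i], local_alts), gt_local,
                                      spec)
        recs[[length(recs) + 1L]] <- data.table(
          contig = ctg, pos = sites$pos[i], ref = sites$ref[i],
          alts = list(c(local_alts, NON_REF)), kind = "variant",
          end = NA_integer_, gt = gt_string(gt_local), ad = list(call$ad),
          dp = call$dp, gq = call$gq, min_dp = NA_integer_,
          pl = list(call$pl))
        cur <- sites$pos[i] + nchar(sites$ref[i])
      }
      if (cur <= len)
        recs[[length(recs) + 1L]] <- emit_blocks(ctg, cur, len, spec)
    }
    rec <- if (length(recs)) rbindlist(recs) else empty_gvcf_records()
    gvcf_paths[si] <- file.path(dir, paste0(samples[si], ".g.vcf"))
    write_gvcf(rec, samples[si], contigs, unname(spec$contigs),
               gvcf_paths[si])
  }
  names(gvcf_paths) <- samples

  # pedigree (6-column PED)
  ped <- data.table(fam = "F0", id = samples, father = "0", mother = "0",
                    sex = 0L, phenotype = 0L)
  sexes <- sample(1:2, spec$n_samples, replace = TRUE)
  ped[, sex := sexes]
  for (t in seq_len(spec$n_trios)) {
    fa <- 3L * t - 2L; mo <- 3L * t - 1L; ch <- 3L * t
    data.table::set(ped, c(fa, mo, ch), "fam", sprintf("F%03d", t))
    data.table::set(ped, fa, "sex", 1L)
    data.table::set(ped, mo, "sex", 2L)
    data.table::set(ped, ch, "father", samples[fa])
    data.table::set(ped, ch, "mother", samples[mo])
  }
  ped_path <- file.path(dir, "cohort.ped")
  utils::write.table(ped, ped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # capture intervals: 500 bp tiles over each contig (BED: 0-based half-open)
  bed <- rbindlist(lapply(contigs, function(ctg) {
    starts <- seq(0L, spec$contigs[[ctg]] - 1L, by = 500L)
    data.table(contig = ctg, start = starts,
               end = pmin(starts + 500L, spec$contigs[[ctg]]))
  }))
  bed_path <- file.path(dir, "capture.bed")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # truth: per-alternate dose matrix and true AFs
  variants <- sites[, {
    n_alt <- vapply(alts, length, 0L)
    data.table(site_id = rep(seq_len(.N), n_alt),
               contig = rep(contig, n_alt), pos = rep(pos, n_alt),
               ref = rep(ref, n_alt),
               alt = unlist(alts),
               alt_idx = unlist(lapply(n_alt, seq_len)),
               af_true = unlist(af))
  }]
  if (nrow(variants)) {
    variants[, key := paste(contig, pos, ref, alt, sep = ":")]
    dose <- matrix(0L, nrow(variants), spec$n_samples,
                   dimnames = list(variants$key, samples))
    for (v in seq_len(nrow(variants))) {
      i <- variants$site_id[v]; j <- variants$alt_idx[v]
      dose[v, ] <- (geno$a1[i, ] == j) + (geno$a2[i, ] == j)
    }
  } else {
    variants[, key := character()]
    dose <- matrix(0L, 0L, spec$n_samples, dimnames = list(NULL, samples))
  }
  truth_path <- file.path(dir, "truth_genotypes.tsv")
  truth_out <- data.table(variant = rownames(dose),
                          af_true = variants$af_true)
  truth_out <- cbind(truth_out, as.data.table(dose))
  utils::write.table(truth_out, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(spec = spec, samples = samples, gvcf = gvcf_paths,
       ped_path = ped_path, bed_path = bed_path, truth_path = truth_path,
       ped = ped, bed = bed, sites = sites, variants = variants,
       dose = dose, a1 = geno$a1, a2 = geno$a2)
}

#' Annotate cohort variants with genes and functional classes
#'
#' Emulates the downstream product of consequence annotation: each variant is
#' assigned to exactly one gene (contiguous blocks along the genome) and one
#' functional class, with empirical allele frequencies computed from the truth
#' genotype matrix and a synthetic mean site coverage. Class proportions
#' default to rare pLoF being scarcer than missense.
#'
#' @param cohort Result of [generate_cohort()].
#' @param genes Number of genes to partition the variants into (positive).
#' @param seed Integer seed.
#' @param class_props Named proportions for `pLoF`, `missense|LC`,
#'   `synonymous`.
#' @return A `data.table` with `variant`, `gene`, `class`, `af`, `coverage`.
#' @export
generate_annotations <- function(cohort, genes, seed = 1L,
                                 class_props = c("pLoF" = 0.1,
                                                 "missense|LC" = 0.55,
                                                 "synonymous" = 0.35)) {
  if (genes <= 0L) stop("genes must be positive")
  if (nrow(cohort$variants) == 0L) stop("cohort has no variants")
  set.seed(seed)
  n_v <- nrow(cohort$variants)
  genes <- min(as.integer(genes), n_v)
  sizes <- diff(round(seq(0, n_v, length.out = genes + 1L)))
  gene_id <- sprintf("GENE%04d", rep(seq_len(genes), sizes))
  cls <- sample(names(class_props), n_v, replace = TRUE,
                prob = class_props)
  af <- unname(rowSums(cohort$dose) / (2L * ncol(cohort$dose)))
  data.table(variant = cohort$variants$key, gene = gene_id, class = cls,
             af = af, coverage = pmax(1, round(stats::rnorm(n_v, 30, 5), 1)))
}

#' Build a sparse pedigree-based genetic relatedness matrix
#'
#' Diagonal 1, parent-offspring and full-sibling entries 0.5, all other
#' entries absent (sparse). The additive relationship matrix of a valid
#' pedigree is symmetric positive semi-definite.
#'
#' @param ped Pedigree `data.table` with columns `id`, `father`, `mother`
#'   (as written by [generate_cohort()]).
#' @return A `grm` object: list of `samples` and a sparse symmetric `Matrix`.
#' @export
pedigree_grm <- function(ped) {
  n <- nrow(ped)
  ids <- ped$id
  i <- integer(); j <- integer(); x <- numeric()
  for (r in seq_len(n)) {
    for (p in c(ped$father[r], ped$mother[r])) {
      if (p != "0") {
        pi <- match(p, ids)
        i <- c(i, r); j <- c(j, pi); x <- c(x, 0.5)
      }
    }
  }
  # full siblings: same non-founder parents
  key <- paste(ped$father, ped$mother)
  for (k in unique(key[ped$father != "0"])) {
    sibs <- which(key == k)
    if (length(sibs) > 1L) {
      cmb <- utils::combn(sibs, 2L)
      i <- c(i, cmb[1, ]); j <- c(j, cmb[2, ]); x <- c(x, rep(0.5, ncol(cmb)))
    }
  }
  m <- Matrix::sparseMatrix(i = c(seq_len(n), i, j),
                            j = c(seq_len(n), j, i),
                            x = c(rep(1, n), x, x), dims = c(n, n))
  grm <- structure(list(samples = ids, matrix = Matrix::forceSymmetric(m)),
                   class = "grm")
  validate_grm(grm)
  grm
}

#' Validate a GRM: symmetry and positive semi-definiteness
#'
#' PSD is checked by an attempted Cholesky factorization with a small diagonal
#' jitter.
#'
#' @param grm A `grm` object.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_grm <- function(grm) {
  m <- grm$matrix
  if (nrow(m) != ncol(m) || !Matrix::isSymmetric(m))
    stop("GRM must be symmetric")
  ok <- tryCatch(suppressWarnings({
    Matrix::chol(m + Matrix::Diagonal(nrow(m)) * 1e-8)
    TRUE
  }), error = function(e) FALSE)
  if (!ok) stop("GRM is not positive semi-definite (factorization failed)")
  invisible(TRUE)
}

#' Generate random phenotypes for a cohort
#'
#' Thin wrapper over [simulate_random_phenotypes()] that records per-phenotype
#' metadata (heritability, prevalence, seed).
#'
#' @param grm A `grm` object.
#' @param n_pheno Number of phenotypes to simulate.
#' @param heritabilities Heritabilities in `[0, 1]`, recycled across
#'   continuous phenotypes.
#' @param prevalences Prevalences in `(0, 0.5]` for binary phenotypes
#'   (empty for continuous-only).
#' @param seed Integer seed.
#' @return A `phenotype_matrix` (see [simulate_random_phenotypes()]).
#' @export
generate_phenotype_inputs <- function(grm, n_pheno, heritabilities = 1,
                                      prevalences = numeric(), seed = 1L) {
  simulate_random_phenotypes(grm, n_pheno, h2 = heritabilities,
                             prevalence = prevalences, seed = seed)
}
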