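# End-to-end desk-scale orchestration: generate -> convert/merge/densify ->
# genotype/variant/sample QC -> association + calibration -> enrichment,
# under a single validated config with mandatory seeds and a checksum
# manifest.

#' Default run configuration
#'
#' Every QC threshold defaults to the canonical published value: adj
#' DP >= 10 (5 haploid) / GQ >= 20 / AB > 0.2; inbreeding F < -0.3; hard
#' filters QD < 2 / FS > 60 / MQ < 30; RF cutoffs 0.061 (SNV) and 0.064
#' (indel); interval QC 85% of samples at 20x with 50 bp padding; call rate
#' 0.99; coverage 20x; 4 MADs; kinship 0.1; expected AC >= 50; lambda
#' cutoffs 0.75; phenotype correlation r^2 > 0.5; burden maxMAF 0.01 with a
#' minimum of two variants per group; merge branch factor 100.
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = file.path(tempdir(), "svcrkit-run"),
    synthetic = list(
      n_samples = 30L, n_trios = 4L,
      contigs = list(chr1 = 30000L, chr2 = 20000L),
      variant_rate = 0.004, af_shape = c(0.2, 2), mean_depth = 30,
      error_rate = 1e-3, de_novo_rate = 0, genes = 40L
    ),
    svcr = list(branch_factor = 100L),
    genotype_qc = list(min_dp = 10L, min_dp_haploid = 5L, min_gq = 20L,
                       min_ab = 0.2),
    variant_qc = list(qd_min = 2, fs_max = 60, mq_min = 30,
                      inbreeding_min = -0.3, rf_cutoff_snv = 0.061,
                      rf_cutoff_indel = 0.064, rf_ntree = 150L),
    sample_qc = list(interval_frac = 0.85, interval_min_cov = 20,
                     interval_pad = 50L, call_rate_min = 0.99,
                     coverage_min = 20, n_mads = 4, kinship_cutoff = 0.1),
    association = list(n_phenotypes = 24L, heritabilities = c(0.1, 0.2, 0.5, 1),
                       prevalences = numeric(), max_maf = 0.01,
                       min_group_variants = 2L, expected_ac_min = 50,
                       lambda_cutoff = 0.75, r2_cutoff = 0.5,
                       alpha_per_phenotype = 0.05),
    enrichment = list(bin_width = 0.01, n_sets = 1000L, n_target = 12L)
  )
}

check_bound <- function(errs, cfg, path, lo = -Inf, hi = Inf, len = NULL) {
  v <- cfg
  for (k in strsplit(path, ".", fixed = TRUE)[[1]]) v <- v[[k]]
  if (is.null(v)) return(c(errs, paste0(path, ": missing")))
  if (!is.null(len) && length(v) != len)
    return(c(errs, paste0(path, ": wrong length")))
  if (!is.numeric(unlist(v)))
    return(c(errs, paste0(path, ": must be numeric")))
  if (any(unlist(v) < lo) || any(unlist(v) > hi))
    return(c(errs, sprintf("%s: must lie in [%g, %g]", path, lo, hi)))
  errs
}

#' Validate a run configuration
#'
#' Merges a raw (possibly partial) config -- a nested list or a YAML file
#' path -- over [default_config()], rejects unknown keys, and checks types
#' and bounds for every field, aggregating all errors.
#'
#' @param raw `NULL` (defaults only), a nested list, or a YAML file path.
#' @return A validated `run_config` object, or an error listing every
#'   violated field.
#' @export
validate_config <- function(raw = NULL) {
  if (is.character(raw)) raw <- yaml::read_yaml(raw)
  if (is.null(raw)) raw <- list()
  def <- default_config()
  errs <- character()
  merge_lists <- function(d, r, prefix = "") {
    unknown <- setdiff(names(r), names(d))
    if (length(unknown))
      errs <<- c(errs, paste0("unknown key: ", prefix, unknown))
    for (k in intersect(names(r), names(d))) {
      if (is.list(d[[k]]) && !is.null(names(d[[k]]))) {
        d[[k]] <- merge_lists(d[[k]], as.list(r[[k]]),
                              paste0(prefix, k, "."))
      } else {
        d[[k]] <- r[[k]]
      }
    }
    d
  }
  cfg <- merge_lists(def, raw)
  errs <- check_bound(errs, cfg, "seed")
  errs <- check_bound(errs, cfg, "synthetic.n_samples", lo = 1)
  errs <- check_bound(errs, cfg, "synthetic.n_trios", lo = 0)
  errs <- check_bound(errs, cfg, "synthetic.variant_rate", lo = 0, hi = 1)
  errs <- check_bound(errs, cfg, "synthetic.mean_depth", lo = 1e-9)
  errs <- check_bound(errs, cfg, "synthetic.genes", lo = 1)
  errs <- check_bound(errs, cfg, "svcr.branch_factor", lo = 2)
  errs <- check_bound(errs, cfg, "genotype_qc.min_dp", lo = 0)
  errs <- check_bound(errs, cfg, "genotype_qc.min_dp_haploid", lo = 0)
  errs <- check_bound(errs, cfg, "genotype_qc.min_gq", lo = 0)
  errs <- check_bound(errs, cfg, "genotype_qc.min_ab", lo = 0, hi = 1)
  errs <- check_bound(errs, cfg, "variant_qc.rf_cutoff_snv", lo = 0, hi = 1)
  errs <- check_bound(errs, cfg, "variant_qc.rf_cutoff_indel", lo = 0, hi = 1)
  errs <- check_bound(errs, cfg, "sample_qc.interval_frac", lo = 0, hi = 1)
  errs <- check_bound(errs, cfg, "sample_qc.call_rate_min", lo = 0, hi = 1)
  errs <- check_bound(errs, cfg, "association.max_maf", lo = 0, hi = 0.5)
  errs <- check_bound(errs, cfg, "association.r2_cutoff", lo = 0, hi = 1)
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  structure(cfg, class = "run_config")
}

md5_of <- function(paths) unname(tools::md5sum(paths))

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# dose of each (row, alt) from a dense matrix's genotype strings
dense_dose_matrix <- function(dm) {
  rows <- dm$rows
  keys <- list(); doses <- list()
  calls <- dm$calls
  gt_idx <- lapply(calls$gt, function(g)
    if (is.na(g)) NA_integer_ else gt_indices(g))
  call_key <- paste(calls$contig, calls$pos)
  for (i in seq_len(nrow(rows))) {
    ci <- which(call_key == paste(rows$contig[i], rows$pos[i]))
    ci <- ci[match(dm$samples, calls$sample[ci])]
    for (j in seq_along(rows$alts[[i]])) {
      d <- vapply(gt_idx[ci], function(g)
        if (length(g) == 1L && is.na(g[1])) NA_integer_ else sum(g == j),
        0L)
      keys[[length(keys) + 1L]] <- paste(rows$contig[i], rows$pos[i],
                                         rows$ref[i], rows$alts[[i]][j],
                                         sep = ":")
      doses[[length(doses) + 1L]] <- d
    }
  }
  m <- do.call(rbind, doses)
  rownames(m) <- unlist(keys)
  colnames(m) <- dm$samples
  m
}

#' Run the end-to-end desk-scale pipeline
#'
#' Executes every stage in dependency order: cohort generation, SVCR
#' conversion + hierarchical merge + densification + pVCF export, genotype
#' adj QC, variant QC (site features, balanced training sets, random forest,
#' hard exclusions), sample QC (interval QC, sex karyotypes, hard filters,
#' MAD outliers, relatedness pruning), random-phenotype association tests,
#' summary-statistic calibration (lambda, expected AC, empirical
#' thresholds, phenotype pruning) and CAF-matched enrichment. Writes every
#' artifact under `cfg$output_dir` and returns a manifest with per-file MD5
#' checksums plus an audit log of counts removed by each QC rule.
#'
#' @param cfg A `run_config` from [validate_config()].
#' @return The manifest (list), invisibly also written as JSON.
#' @export
run_end_to_end <- function(cfg = validate_config()) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  audit <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- stage 1: synthetic cohort -------------------------------------------
  cohort <- stage("generate", {
    sp <- cfg$synthetic
    spec <- cohort_spec(sp$n_samples, sp$n_trios,
                        contigs = unlist(sp$contigs),
                        variant_rate = sp$variant_rate,
                        af_shape = sp$af_shape, mean_depth = sp$mean_depth,
                        error_rate = sp$error_rate,
                        de_novo_rate = sp$de_novo_rate, seed = cfg$seed)
    generate_cohort(spec, file.path(out, "gvcf"))
  })
  anno <- stage("annotate", generate_annotations(
    cohort, genes = cfg$synthetic$genes, seed = cfg$seed + 1L))
  anno_path <- write_tsv(anno, file.path(out, "annotations.tsv"))

  # -- stage 2: SVCR conversion, merge, densify, export --------------------
  svcr <- stage("svcr", {
    singles <- lapply(cohort$gvcf, gvcf_to_svcr)
    hierarchical_merge(singles, branch_factor = cfg$svcr$branch_factor)
  })
  dm <- stage("densify", densify(svcr))
  pvcf_path <- stage("export", export_pvcf(
    dm, file.path(out, "cohort.pvcf.vcf"),
    contig_lengths = unlist(cfg$synthetic$contigs)))
  audit$svcr <- list(samples = length(svcr$samples), rows = nrow(svcr$rows),
                     entries = n_entries(svcr),
                     merge_rounds = attr(svcr, "rounds"))

  # -- stage 3: genotype QC (adj) ------------------------------------------
  dose <- stage("dose", dense_dose_matrix(dm))
  adj <- stage("genotype_qc", {
    calls <- dm$calls
    pass <- logical(nrow(calls)); nonref <- logical(nrow(calls))
    for (i in seq_len(nrow(calls))) {
      g <- calls$gt[i]
      if (is.na(g)) next
      gi <- gt_indices(g)
      nonref[i] <- any(gi > 0L)
      pass[i] <- isTRUE(adj_filter(calls$dp[i], calls$gq[i], gi,
                                   calls$ad[[i]]))
    }
    data.table(contig = calls$contig, pos = calls$pos,
               sample = calls$sample, adj_pass = pass, nonref = nonref)
  })
  audit$genotype_qc <- list(n_calls = nrow(adj),
                            n_adj_fail = sum(!adj$adj_pass & !is.na(adj$adj_pass)))

  # -- stage 4: variant QC --------------------------------------------------
  vqc <- stage("variant_qc", {
    calls <- dm$calls
    call_key <- paste(calls$contig, calls$pos)
    set.seed(cfg$seed + 2L)
    n_v <- nrow(dose)
    vparts <- data.table::tstrsplit(rownames(dose), ":", fixed = TRUE)
    vtab <- data.table(variant = rownames(dose), contig = vparts[[1]],
                       pos = as.integer(vparts[[2]]), ref = vparts[[3]],
                       alt = vparts[[4]])
    vtab[, is_snv := nchar(ref) == 1L & nchar(alt) == 1L]
    stats_l <- lapply(seq_len(n_v), function(v) {
      ci <- which(call_key == paste(vtab$contig[v], vtab$pos[v]))
      d <- dose[v, calls$sample[ci]]
      carriers <- ci[!is.na(d) & d > 0L]
      qd <- quality_by_depth(
        vapply(carriers, function(i) {
          pl <- calls$pl[[i]]
          if (is.null(pl) || is.na(pl[1])) 0 else pl[1]
        }, 0),
        calls$dp[carriers])
      hets <- carriers[dose[v, calls$sample[carriers]] == 1L]
      ab <- max_ab_binomial_p(lapply(hets, function(i) {
        ad <- calls$ad[[i]]
        a_idx <- match(vtab$alt[v],
                       dm$rows$alts[[match(paste(vtab$contig[v], vtab$pos[v]),
                                           paste(dm$rows$contig, dm$rows$pos))]])
        c(ad[1], ad[a_idx + 1L])
      }))
      f <- tryCatch(inbreeding_coefficient(dose[v, ]), error = function(e) NA_real_)
      data.table(qd = qd, max_ab_p = ab, inbreeding_f = f)
    })
    st <- cbind(vtab, rbindlist(stats_l))
    # FS and MQ are synthetic site annotations (no read-level data exists);
    # the FS tail is heavy enough that a hard-filter FP pool always exists,
    # and the two lowest-QD sites are forced over the FS bound as a floor
    st[, fs := round(stats::rexp(n_v, rate = 1 / 20), 3)]
    st[, mq := round(pmin(60, 60 - stats::rexp(n_v, rate = 1 / 5)), 3)]
    worst <- order(st$qd)[seq_len(min(2L, n_v))]
    st[worst, fs := 90]
    st[, n_alleles := .N + 1L, by = .(contig, pos)]
    st[, allele_type := fifelse(is_snv, "snv", "indel")]
    st
  })
  has_adj_nonref <- stage("adj_nonref", {
    calls_key <- paste(adj$contig, adj$pos, adj$sample)
    v <- vapply(seq_len(nrow(dose)), function(i) {
      ctg <- vqc$contig[i]; p <- vqc$pos[i]
      d <- dose[i, ]
      carr <- names(d)[!is.na(d) & d > 0L]
      any(adj$adj_pass[match(paste(ctg, p, carr), calls_key)], na.rm = TRUE)
    }, TRUE)
    stats::setNames(v, rownames(dose))
  })
  labels <- stage("training_sets", {
    common <- rownames(dose)[rowMeans(dose, na.rm = TRUE) / 2 > 0.001]
    set.seed(cfg$seed + 3L)
    ext <- if (length(common)) sample(common, max(1L, length(common) %/% 3L))
      else character()
    assemble_training_sets(dose, cohort$ped, vqc, external_tp = ext,
                           seed = cfg$seed + 4L)
  })
  rf_res <- stage("rf", {
    feats <- vqc[, .(variant, is_snv, qd, fs, mq, max_ab_p, n_alleles,
                     allele_type)]
    train_apply_rf(feats, labels,
                   snv_cutoff = cfg$variant_qc$rf_cutoff_snv,
                   indel_cutoff = cfg$variant_qc$rf_cutoff_indel,
                   inbreeding = stats::setNames(vqc$inbreeding_f, vqc$variant),
                   has_adj_nonref = has_adj_nonref,
                   seed = cfg$seed + 5L, ntree = cfg$variant_qc$rf_ntree)
  })
  vqc_path <- write_tsv(rf_res, file.path(out, "variant_qc.tsv"))
  audit$variant_qc <- list(n_variants = nrow(rf_res),
                           n_pass = sum(rf_res$pass),
                           n_training = nrow(labels))

  # -- stage 5: sample QC ---------------------------------------------------
  sqc <- stage("sample_qc", {
    sq <- cfg$sample_qc
    set.seed(cfg$seed + 6L)
    samples <- cohort$samples
    ents <- svcr$entries
    cov_mat <- sapply(samples, function(s) {
      e <- ents[sample == s]
      spans <- fifelse(e$kind == "ref_block", e$end, e$pos) - e$pos + 1L
      vapply(seq_len(nrow(cohort$bed)), function(bi) {
        sel <- e$contig == cohort$bed$contig[bi] &
          e$pos <= cohort$bed$end[bi] &
          fifelse(e$kind == "ref_block", e$end, e$pos) >= cohort$bed$start[bi] + 1L
        dpv <- fifelse(e$kind == "ref_block", e$min_dp, e$dp)[sel]
        if (!length(dpv)) NA_real_ else mean(dpv)
      }, 0)
    })
    cov_mat[is.na(cov_mat)] <- mean(cov_mat, na.rm = TRUE)
    iv <- interval_qc(cohort$bed, cov_mat, frac = sq$interval_frac,
                      min_cov = sq$interval_min_cov, pad = sq$interval_pad)
    ped_sex <- cohort$ped$sex
    x_pl <- ifelse(ped_sex == 1L, 1, 2) + stats::rnorm(length(samples), 0, 0.03)
    y_pl <- ifelse(ped_sex == 1L, 1, 0.01) + abs(stats::rnorm(length(samples), 0, 0.02))
    kt <- impute_sex_karyotype(x_pl, y_pl)
    calls <- dm$calls
    call_rate <- vapply(samples, function(s)
      mean(!is.na(calls$gt[calls$sample == s])), 0)
    mean_cov <- colMeans(cov_mat)
    hard <- sample_hard_filters(kt, call_rate, mean_cov)
    met <- data.table(
      sample = samples, stratum = "pop1|batch1",
      n_snvs = colSums(dose[vqc$is_snv, , drop = FALSE] > 0, na.rm = TRUE),
      n_insertions = colSums(dose[nchar(vqc$alt) > nchar(vqc$ref), , drop = FALSE] > 0, na.rm = TRUE),
      n_deletions = colSums(dose[nchar(vqc$alt) < nchar(vqc$ref), , drop = FALSE] > 0, na.rm = TRUE),
      r_het_hom = {
        het <- colSums(dose == 1L, na.rm = TRUE)
        hom <- pmax(colSums(dose == 2L, na.rm = TRUE), 1L)
        het / hom
      })
    flags <- mad_outlier_flags(met, n_mads = sq$n_mads)
    outl <- mad_outliers(flags)
    kin <- cohort$ped[father != "0",
                      .(a = c(id, id), b = c(father, mother), kinship = 0.25)]
    kin_edges <- kin[kinship > sq$kinship_cutoff, .(a, b)]
    kept <- maximal_independent_set(samples, kin_edges, priority = mean_cov)
    pass <- hard$pass & !outl$outlier[match(samples, outl$sample)] &
      samples %in% kept
    list(intervals = iv, karyotype = kt, hard = hard, metrics = met,
         flags = flags, outliers = outl, kept_unrelated = kept,
         sample_pass = stats::setNames(pass, samples),
         coverage = cov_mat)
  })
  sqc_tab <- data.table(sample = cohort$samples,
                        karyotype = sqc$karyotype,
                        hard_pass = sqc$hard$pass,
                        outlier = sqc$outliers$outlier[
                          match(cohort$samples, sqc$outliers$sample)],
                        unrelated = cohort$samples %in% sqc$kept_unrelated,
                        pass = sqc$sample_pass)
  sqc_path <- write_tsv(sqc_tab, file.path(out, "sample_qc.tsv"))
  audit$sample_qc <- list(
    n_samples = length(cohort$samples),
    n_hard_fail = sum(!sqc$hard$pass),
    n_outliers = sum(sqc$outliers$outlier),
    n_related_removed = length(cohort$samples) - length(sqc$kept_unrelated),
    n_pass = sum(sqc$sample_pass))

  # -- stage 6: association + calibration ----------------------------------
  assoc <- stage("association", {
    ac <- cfg$association
    keep_s <- names(sqc$sample_pass)[sqc$sample_pass]
    keep_v <- rf_res$variant[rf_res$pass]
    G <- t(dose[keep_v, keep_s, drop = FALSE])
    G[is.na(G)] <- 0L
    grm <- pedigree_grm(cohort$ped[id %in% keep_s])
    pm <- simulate_random_phenotypes(grm, n = ac$n_phenotypes,
                                     h2 = ac$heritabilities,
                                     prevalence = ac$prevalences,
                                     seed = cfg$seed + 7L)
    set.seed(cfg$seed + 8L)
    X <- cbind(age = stats::rnorm(length(keep_s), 55, 8),
               sex = as.numeric(cohort$ped$sex[match(keep_s, cohort$ped$id)] == 1L))
    anno_k <- anno[variant %in% keep_v]
    recs <- list()
    for (j in seq_len(ncol(pm$values))) {
      ph <- pm$meta$phenotype[j]
      tt <- pm$meta$trait_type[j]
      y <- pm$values[match(keep_s, pm$samples), j]
      sv <- single_variant_score_test(G, y, X, trait_type = tt)
      af <- colMeans(G) / 2
      recs[[length(recs) + 1L]] <- data.table(
        phenotype = ph, unit = sv$variant,
        gene = anno_k$gene[match(sv$variant, anno_k$variant)],
        class = anno_k$class[match(sv$variant, anno_k$variant)],
        test = "single_variant", p = sv$p, beta = sv$beta, se = sv$se,
        freq = af[match(sv$variant, colnames(G))],
        n_eff = if (tt == "binary") pm$meta$n_cases[j] else pm$meta$n_defined[j])
      for (gc in split(anno_k, by = c("gene", "class"))) {
        if (nrow(gc) < ac$min_group_variants) next
        gv <- intersect(gc$variant, colnames(G))
        if (length(gv) < ac$min_group_variants) next
        bt <- burden_test(G[, gv, drop = FALSE], y, X, trait_type = tt,
                          max_maf = ac$max_maf)
        if (bt$excluded) next
        recs[[length(recs) + 1L]] <- data.table(
          phenotype = ph, unit = paste0(gc$gene[1], "|", gc$class[1]),
          gene = gc$gene[1], class = gc$class[1], test = "burden",
          p = bt$p, beta = bt$beta, se = bt$se,
          freq = sum(gc$af), n_eff = if (tt == "binary") pm$meta$n_cases[j]
            else pm$meta$n_defined[j])
      }
    }
    list(records = rbindlist(recs), pm = pm, keep_s = keep_s)
  })
  calib <- stage("calibration", {
    ac <- cfg$association
    recs <- assoc$records
    ph_lambda <- vapply(split(recs[test == "single_variant"], by = "phenotype"),
                        function(d) lambda_gc(d$p), 0)
    names(ph_lambda) <- sub("^.*=", "", names(ph_lambda))
    gene_syn <- recs[test == "burden" & class == "synonymous",
                     .(lambda_synonymous = lambda_gc(p)), by = gene]
    gene_cov <- anno[, .(coverage = mean(coverage)), by = gene]
    gene_tab <- merge(gene_cov, gene_syn, by = "gene", all.x = TRUE)
    gated <- qc_gate(recs, gene_tab, ph_lambda,
                     lambda_cutoff = ac$lambda_cutoff,
                     expected_ac_threshold = ac$expected_ac_min)
    min_p <- recs[!is.na(p), .(min_p = min(p)), by = .(phenotype, test)]
    thr <- lapply(split(min_p, by = "test"), function(d)
      empirical_thresholds(d$min_p))
    pruned <- prune_correlated_phenotypes(assoc$pm, r2_cutoff = ac$r2_cutoff)
    list(gene_table = gene_tab, phenotype_lambda = ph_lambda,
         gated = gated, thresholds = thr, pruned = pruned)
  })
  stats_path <- write_tsv(assoc$records, file.path(out, "summary_stats.tsv"))
  gated_path <- write_tsv(calib$gated, file.path(out, "summary_stats_qc.tsv"))
  thr_path <- file.path(out, "thresholds.json")
  jsonlite::write_json(lapply(calib$thresholds, function(t)
    list(median_min_p = t$median_min_p, effective_tests = t$effective_tests,
         threshold = t$threshold)), thr_path, auto_unbox = TRUE, digits = NA)
  audit$calibration <- c(as.list(attr(calib$gated, "audit")),
                         list(n_phenotypes_kept = length(calib$pruned$keep)))

  # -- stage 7: enrichment --------------------------------------------------
  enr <- stage("enrichment", {
    ec <- cfg$enrichment
    # prefer gene burden units; at very small n the group MAF ceiling can
    # exclude every group, in which case gene-level single-variant units are
    # used instead
    use_test <- if (nrow(assoc$records[test == "burden"]) >= 10L) "burden"
      else "single_variant"
    thr_b <- calib$thresholds[[use_test]]$threshold
    pool <- calib$gated[test == use_test & !is.na(gene)]
    if (nrow(pool) < 10L) pool <- assoc$records[test == use_test & !is.na(gene)]
    units <- pool[, .(n_assoc = sum(p < thr_b, na.rm = TRUE),
                      caf = sum(freq[!duplicated(unit)])),
                  by = .(gene)]
    setnames(units, "gene", "unit")
    set.seed(cfg$seed + 9L)
    # draw the demo target only from CAF bins with at least two units, so
    # every target bin retains background after the split
    bins <- svcrkit:::caf_bin(units$caf, ec$bin_width)
    # at most half of each bin may enter the target, so its background
    # remains occupied
    resample <- function(x, n) x[sample.int(length(x), n)]
    eligible <- unlist(lapply(split(seq_len(nrow(units)), bins), function(ix)
      if (length(ix) >= 2L) resample(ix, length(ix) %/% 2L) else integer()))
    tgt_idx <- resample(eligible, min(ec$n_target, length(eligible)))
    target <- units[tgt_idx]
    background <- units[-tgt_idx]
    nd <- caf_matched_null(target, background, bin_width = ec$bin_width,
                           n_sets = ec$n_sets, seed = cfg$seed + 10L)
    enrichment_test(target, nd)
  })
  enr_path <- file.path(out, "enrichment.json")
  jsonlite::write_json(list(
    n_target = enr$n_target, prop_hit = enr$prop_hit,
    empirical_p = enr$empirical_p, fisher_p = enr$fisher_p,
    odds_ratio = enr$odds_ratio), enr_path, auto_unbox = TRUE, digits = NA)

  # -- manifest -------------------------------------------------------------
  files <- c(unname(cohort$gvcf), cohort$ped_path, cohort$bed_path,
             cohort$truth_path, anno_path, pvcf_path, vqc_path, sqc_path,
             stats_path, gated_path, thr_path, enr_path)
  manifest <- list(
    config = unclass(cfg),
    files = data.table(path = files, md5 = md5_of(files)),
    audit = audit
  )
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(list(
    files = manifest$files, audit = audit), manifest_path,
    auto_unbox = TRUE, digits = NA)
  manifest$manifest_path <- manifest_path
  invisible(manifest)
}
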