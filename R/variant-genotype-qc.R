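# Genotype-level "adj" filtering, variant hard filters, site-level features
# and random-forest variant classification with balanced truth training sets.

#' Genotype-level "adj" filter
#'
#' A genotype passes if depth >= 10 (>= 5 for haploid calls), genotype
#' quality >= 20, and -- for heterozygous genotypes -- the allele balance of
#' every carried alternate allele exceeds 0.2 (alternate depth over total AD).
#'
#' @param dp Read depth.
#' @param gq Genotype quality.
#' @param gt_alleles Integer vector of called allele indices (global,
#'   0 = reference); length 1 for haploid, 2 for diploid calls.
#' @param ad Integer vector of allelic depths in global allele order
#'   (`ad[1]` = reference); may be `NULL` for non-het genotypes.
#' @return `TRUE`/`FALSE`, with attribute `"reason"` naming the first failed
#'   criterion on failure.
#' @export
adj_filter <- function(dp, gq, gt_alleles, ad = NULL) {
  fail <- function(reason) structure(FALSE, reason = reason)
  ploidy <- length(gt_alleles)
  min_dp <- if (ploidy == 1L) 5L else 10L
  if (is.na(dp) || dp < min_dp) return(fail("depth"))
  if (is.na(gq) || gq < 20L) return(fail("genotype_quality"))
  is_het <- ploidy == 2L && gt_alleles[1] != gt_alleles[2]
  if (is_het) {
    if (is.null(ad) || all(is.na(ad))) return(fail("missing_AD"))
    tot <- sum(ad, na.rm = TRUE)
    if (tot == 0L) return(fail("missing_AD"))
    for (a in setdiff(gt_alleles, 0L)) {
      if (is.na(ad[a + 1L]) || ad[a + 1L] / tot <= 0.2)
        return(fail("allele_balance"))
    }
  }
  TRUE
}

#' Inbreeding coefficient of a biallelic site
#'
#' `F = 1 - observed het / expected het` with
#' `expected het = 2 p (1 - p) n_called`, `p` the alternate-allele frequency
#' among called diploid genotypes. Sites with `F < -0.3` show excess
#' heterozygosity and are flagged by the hard filters. Monomorphic sites have
#' undefined `F` (`NA`) and are never flagged.
#'
#' @param doses Integer vector of alternate-allele doses (0/1/2), `NA` for
#'   missing calls.
#' @return Numeric `F` (or `NA` if expected heterozygosity is 0).
#' @export
inbreeding_coefficient <- function(doses) {
  doses <- doses[!is.na(doses)]
  if (length(doses) == 0L) stop("at least one called genotype required")
  n <- length(doses)
  p <- sum(doses) / (2 * n)
  exp_het <- 2 * p * (1 - p) * n
  if (exp_het == 0) return(NA_real_)
  obs_het <- sum(doses == 1L)
  1 - obs_het / exp_het
}

#' Variant hard-filter label
#'
#' The false-positive training label of the variant classifier: a site fails
#' if quality-by-depth `QD < 2`, Fisher strand bias `FS > 60`, or root mean
#' square mapping quality `MQ < 30`.
#'
#' @param qd,fs,mq Site statistics (any `NA` excludes the site).
#' @return `TRUE` if the site passes all three, `FALSE` if it fails, `NA` if
#'   a statistic is missing.
#' @export
hard_filter_label <- function(qd, fs, mq) {
  ifelse(is.na(qd) | is.na(fs) | is.na(mq), NA,
         !(qd < 2 | fs > 60 | mq < 30))
}

#' Maximum binomial allele-balance p-value across heterozygotes
#'
#' For each heterozygote the two-sided exact binomial probability of its
#' alternate read count given `ref + alt` trials at success probability 0.5
#' (summing all outcomes at most as probable as the observed one); the site
#' feature is the maximum across heterozygotes.
#'
#' @param ad_pairs List of length-2 integer vectors `(ref_depth, alt_depth)`.
#' @return Numeric p-value in `(0, 1]`, or `NA` with zero heterozygotes.
#' @export
max_ab_binomial_p <- function(ad_pairs) {
  if (length(ad_pairs) == 0L) return(NA_real_)
  p <- vapply(ad_pairs, function(ad) {
    n <- sum(ad)
    if (n == 0L) return(1)
    stats::binom.test(ad[2], n, p = 0.5)$p.value
  }, 0)
  max(p)
}

#' Quality by depth from carrier genotype likelihoods
#'
#' The sum of carriers' phred-scaled homozygous-reference likelihoods (the
#' evidence against the reference genotype) divided by the summed depth of
#' those carriers.
#'
#' @param pl_homref Phred-scaled hom-ref PL values of the carriers.
#' @param dp Depths of the carriers.
#' @return Numeric QD (NA with no carriers).
#' @export
quality_by_depth <- function(pl_homref, dp) {
  if (length(pl_homref) == 0L || sum(dp, na.rm = TRUE) == 0) return(NA_real_)
  sum(pl_homref, na.rm = TRUE) / sum(dp, na.rm = TRUE)
}

#' Assemble balanced truth training sets for the variant classifier
#'
#' True positives are transmitted singletons (variants carried by exactly two
#' individuals who form a parent-offspring pair), sibling singletons
#' (carriers are exactly a sibling pair), and any externally supplied truth
#' variants (e.g. concordant common array variants). False positives are
#' hard-filter failures, randomly downsampled without replacement to the
#' true-positive count.
#'
#' @param dose Variants x samples integer dose matrix (rownames = variant
#'   keys).
#' @param ped Pedigree `data.table` with `id`, `father`, `mother`.
#' @param site_stats `data.table` with `variant`, `qd`, `fs`, `mq`.
#' @param external_tp Optional character vector of variant keys (e.g.
#'   array-concordant common variants, AF > 0.1\% and > 90\% non-reference
#'   concordance, assembled upstream).
#' @param seed Seed for the downsampling draw.
#' @return `data.table` with `variant`, `label`
#'   (`true_positive`/`false_positive`) and `source`.
#' @export
assemble_training_sets <- function(dose, ped, site_stats,
                                   external_tp = character(), seed = 1L) {
  if (!all(colnames(dose) %in% ped$id))
    stop("pedigree does not cover all samples")
  samples <- colnames(dose)
  father <- ped$father[match(samples, ped$id)]
  mother <- ped$mother[match(samples, ped$id)]
  sib_key <- ifelse(father == "0" & mother == "0", NA_character_,
                    paste(father, mother))
  tp <- list()
  carriers_n <- rowSums(dose > 0L)
  two <- which(carriers_n == 2L)
  for (v in two) {
    cs <- samples[dose[v, ] > 0L]
    po <- father[match(cs[1], samples)] == cs[2] ||
      mother[match(cs[1], samples)] == cs[2] ||
      father[match(cs[2], samples)] == cs[1] ||
      mother[match(cs[2], samples)] == cs[1]
    if (isTRUE(po)) {
      tp[[length(tp) + 1L]] <- data.table(variant = rownames(dose)[v],
                                          source = "transmitted_singleton")
    } else {
      k1 <- sib_key[match(cs[1], samples)]
      if (!is.na(k1) && identical(k1, sib_key[match(cs[2], samples)]))
        tp[[length(tp) + 1L]] <- data.table(variant = rownames(dose)[v],
                                            source = "sibling_singleton")
    }
  }
  if (length(external_tp))
    tp[[length(tp) + 1L]] <- data.table(variant = external_tp,
                                        source = "concordant_array")
  tp <- if (length(tp)) unique(rbindlist(tp), by = "variant") else
    data.table(variant = character(), source = character())
  if (nrow(tp) == 0L) stop("empty true-positive set: cannot balance training")

  hf <- hard_filter_label(site_stats$qd, site_stats$fs, site_stats$mq)
  fp_all <- setdiff(site_stats$variant[!is.na(hf) & !hf], tp$variant)
  set.seed(seed)
  fp <- if (length(fp_all) > nrow(tp)) sample(fp_all, nrow(tp)) else fp_all
  rbind(
    data.table(variant = tp$variant, label = "true_positive",
               source = tp$source),
    data.table(variant = fp, label = "false_positive",
               source = "hard_filter_fail")
  )
}

#' Train and apply the random-forest variant classifier
#'
#' Fits a random forest on the site feature table using the balanced training
#' labels, scores every variant with its true-positive probability, and
#' passes a variant if that probability meets the class-specific cutoff
#' (default 0.061 for SNVs, 0.064 for indels). Two hard exclusions are applied
#' on top: an inbreeding coefficient below -0.3, and the absence of any
#' adj-passing non-reference genotype.
#'
#' @param features `data.table` with a `variant` key column, an `is_snv`
#'   logical column, and numeric/factor feature columns (missing rank-sum
#'   style features may be all-`NA` and are dropped).
#' @param labels Training labels from [assemble_training_sets()].
#' @param snv_cutoff,indel_cutoff TP-probability cutoffs.
#' @param inbreeding Optional named numeric of per-variant `F` values.
#' @param has_adj_nonref Optional named logical: does any sample carry an
#'   adj-passing non-reference genotype?
#' @param seed RF seed.
#' @param ntree Number of trees.
#' @return `data.table` with `variant`, `tp_prob`, `rf_pass`, `pass` and
#'   `reason`.
#' @export
train_apply_rf <- function(features, labels, snv_cutoff = 0.061,
                           indel_cutoff = 0.064, inbreeding = NULL,
                           has_adj_nonref = NULL, seed = 1L, ntree = 200L) {
  if (length(unique(labels$label)) < 2L)
    stop("training labels must contain both classes")
  feat_cols <- setdiff(names(features), c("variant", "is_snv"))
  keep <- feat_cols[vapply(feat_cols, function(cn)
    !all(is.na(features[[cn]])), TRUE)]
  x <- as.data.frame(features[, keep, with = FALSE])
  for (cn in names(x)) {
    if (is.character(x[[cn]])) x[[cn]] <- factor(x[[cn]])
    if (is.numeric(x[[cn]]) && anyNA(x[[cn]]))
      x[[cn]][is.na(x[[cn]])] <- stats::median(x[[cn]], na.rm = TRUE)
  }
  tr_idx <- match(labels$variant, features$variant)
  if (anyNA(tr_idx)) stop("training label for unknown variant")
  y <- factor(labels$label, levels = c("false_positive", "true_positive"))
  set.seed(seed)
  rf <- randomForest::randomForest(x = x[tr_idx, , drop = FALSE], y = y,
                                   ntree = ntree)
  prob <- stats::predict(rf, x, type = "prob")[, "true_positive"]
  cutoff <- ifelse(features$is_snv, snv_cutoff, indel_cutoff)
  out <- data.table(variant = features$variant, tp_prob = as.numeric(prob),
                    rf_pass = as.numeric(prob) >= cutoff)
  out[, pass := rf_pass]
  out[, reason := fifelse(rf_pass, NA_character_, "rf_score")]
  if (!is.null(inbreeding)) {
    f <- inbreeding[out$variant]
    bad <- !is.na(f) & f < -0.3
    out[bad, `:=`(pass = FALSE, reason = "inbreeding_coefficient")]
  }
  if (!is.null(has_adj_nonref)) {
    bad <- !isTRUE_vec(has_adj_nonref[out$variant])
    out[bad, `:=`(pass = FALSE, reason = "no_adj_nonref_genotype")]
  }
  out[]
}

isTRUE_vec <- function(x) !is.na(x) & x
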