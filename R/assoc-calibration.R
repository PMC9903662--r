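# Random-phenotype simulation against a sparse GRM, lightweight score tests,
# genomic-control lambda, expected-allele-count and calibration filters,
# empirical significance thresholds, and correlated-phenotype pruning.

#' Simulate GRM-correlated random phenotypes
#'
#' The genetic component is multivariate normal with covariance equal to the
#' GRM (sampled through a Cholesky factorization with a 1e-8 diagonal
#' jitter); the phenotype is
#' `y = sqrt(h2) * g + sqrt(1 - h2) * e` with i.i.d. standard-normal noise.
#' Binary phenotypes dichotomize a heritability-1 liability at the empirical
#' `(1 - prevalence)` quantile, so the case count is exactly
#' `floor(prevalence * n)`.
#'
#' @param grm A `grm` object (see [pedigree_grm()]), or `NULL` for an
#'   identity GRM of size `n_samples`.
#' @param n Number of phenotypes.
#' @param h2 Heritabilities in `[0, 1]`, recycled over the continuous
#'   phenotypes.
#' @param prevalence Prevalences in `(0, 0.5]`; one binary phenotype is
#'   appended per element (heritability 1).
#' @param seed Integer seed.
#' @param n_samples Required when `grm` is `NULL`.
#' @return A `phenotype_matrix`: list with `values` (samples x phenotypes
#'   matrix), `meta` (`data.table`: `phenotype`, `trait_type`, `h2`,
#'   `prevalence`, `n_cases`, `n_defined`), `samples`.
#' @export
simulate_random_phenotypes <- function(grm, n, h2 = 1,
                                       prevalence = numeric(), seed = 1L,
                                       n_samples = NULL) {
  if (any(h2 < 0 | h2 > 1)) stop("heritabilities must lie in [0, 1]")
  if (length(prevalence) && any(prevalence <= 0 | prevalence > 0.5))
    stop("prevalences must lie in (0, 0.5]")
  if (is.null(grm)) {
    if (is.null(n_samples)) stop("n_samples required without a GRM")
    ns <- n_samples
    L <- NULL
    samples <- sprintf("S%03d", seq_len(ns))
  } else {
    validate_grm(grm)
    ns <- length(grm$samples)
    samples <- grm$samples
    L <- tryCatch(
      Matrix::chol(grm$matrix + Matrix::Diagonal(ns) * 1e-8),
      error = function(e) stop("GRM is not positive semi-definite: ",
                               conditionMessage(e)))
  }
  set.seed(seed)
  n_bin <- length(prevalence)
  n_cont <- n - n_bin
  if (n_cont < 0L) stop("more prevalences than phenotypes requested")
  h2s <- rep_len(h2, max(n_cont, 0L))
  vals <- matrix(NA_real_, ns, n)
  meta <- vector("list", n)
  draw_g <- function() {
    z <- stats::rnorm(ns)
    if (is.null(L)) z else as.numeric(Matrix::crossprod(L, z))
  }
  for (j in seq_len(n)) {
    if (j <= n_cont) {
      h <- h2s[j]
      y <- sqrt(h) * draw_g() + sqrt(1 - h) * stats::rnorm(ns)
      vals[, j] <- y
      meta[[j]] <- data.table(phenotype = sprintf("pheno%04d", j),
                              trait_type = "continuous", h2 = h,
                              prevalence = NA_real_, n_cases = NA_integer_,
                              n_defined = ns)
    } else {
      prev <- prevalence[j - n_cont]
      liab <- draw_g()
      thr <- stats::quantile(liab, 1 - prev, type = 1)
      y <- as.numeric(liab > thr)
      n_cases <- floor(prev * ns)
      # empirical-quantile thresholding: exactly floor(prev * n) cases
      y <- as.numeric(rank(-liab, ties.method = "first") <= n_cases)
      vals[, j] <- y
      meta[[j]] <- data.table(phenotype = sprintf("pheno%04d", j),
                              trait_type = "binary", h2 = 1,
                              prevalence = prev, n_cases = as.integer(n_cases),
                              n_defined = ns)
    }
  }
  meta <- rbindlist(meta)
  colnames(vals) <- meta$phenotype
  rownames(vals) <- samples
  structure(list(values = vals, meta = meta, samples = samples),
            class = "phenotype_matrix")
}

# residualize columns of G on covariates X (with intercept)
residualize <- function(G, X) {
  qrX <- qr(X)
  G - X %*% qr.coef(qrX, G)
}

#' Single-variant score tests
#'
#' Association of each genotype column with one phenotype, adjusting for
#' covariates. Continuous traits: the genotype is residualized on the
#' covariates and the usual large-sample test of its regression coefficient
#' is computed from the null fit (equivalent to the full least-squares fit).
#' Binary traits: the efficient score test from the logistic null model.
#' Two-sided p-values throughout. Variants with zero genotype variance among
#' phenotyped samples are flagged and skipped.
#'
#' @param G Numeric matrix (samples x variants) of dosages.
#' @param y Phenotype vector (numeric, or 0/1 for binary).
#' @param X Covariate matrix (without intercept; one is added). `NULL` for
#'   intercept-only.
#' @param trait_type `"continuous"` or `"binary"`.
#' @return `data.table` with `variant`, `p`, `beta`, `se`, `skip_flag`.
#' @export
single_variant_score_test <- function(G, y, X = NULL,
                                      trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  G <- as.matrix(G)
  keep <- !is.na(y)
  G <- G[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y)
  X <- if (is.null(X)) matrix(1, n, 1) else cbind(1, as.matrix(X)[keep, , drop = FALSE])
  p_cov <- ncol(X)
  vn <- colnames(G)
  if (is.null(vn)) vn <- sprintf("v%d", seq_len(ncol(G)))
  gvar <- apply(G, 2, stats::var)
  res <- data.table(variant = vn, p = NA_real_, beta = NA_real_,
                    se = NA_real_, skip_flag = gvar == 0 | is.na(gvar))
  ok <- which(!res$skip_flag)
  if (!length(ok)) return(res[])

  if (trait_type == "continuous") {
    qrX <- qr(X)
    r <- qr.resid(qrX, y)
    Gt <- G[, ok, drop = FALSE] - X %*% qr.coef(qrX, G[, ok, drop = FALSE])
    gg <- colSums(Gt^2)
    u <- as.numeric(crossprod(Gt, r))
    bhat <- u / gg
    rss_full <- pmax(sum(r^2) - bhat^2 * gg, 1e-12)
    sigma2 <- rss_full / (n - p_cov - 1L)
    sehat <- sqrt(sigma2 / gg)
    z <- bhat / sehat
    res[ok, `:=`(p = 2 * stats::pnorm(-abs(z)), beta = bhat, se = sehat)]
  } else {
    fit <- stats::glm.fit(X, y, family = stats::binomial())
    mu <- fit$fitted.values
    w <- mu * (1 - mu)
    Xw <- X * w
    XtWX_inv <- solve(crossprod(X, Xw))
    Gs <- G[, ok, drop = FALSE]
    r <- y - mu
    u <- as.numeric(crossprod(Gs, r))
    GtWX <- crossprod(Gs * w, X)
    v <- colSums(Gs^2 * w) - rowSums((GtWX %*% XtWX_inv) * GtWX)
    v <- pmax(v, 1e-12)
    z2 <- u^2 / v
    res[ok, `:=`(p = stats::pchisq(z2, 1, lower.tail = FALSE),
                 beta = u / v, se = 1 / sqrt(v))]
  }
  res[]
}

#' Gene burden test
#'
#' Sums each sample's minor-allele counts over the group's qualifying
#' variants (minor allele frequency at most `max_maf`; dosages of variants
#' with frequency above 0.5 are flipped to count the minor allele) and runs
#' the single-dosage score test on the burden score. Groups with fewer than
#' two qualifying variants are excluded.
#'
#' @param G Dosage matrix (samples x variants) of the group's member
#'   variants.
#' @param y,X,trait_type As in [single_variant_score_test()].
#' @param max_maf Qualifying minor-allele-frequency ceiling (default 0.01).
#' @return One-row `data.table` with `p`, `beta`, `se`, `n_qualifying`,
#'   `excluded`.
#' @export
burden_test <- function(G, y, X = NULL,
                        trait_type = c("continuous", "binary"),
                        max_maf = 0.01) {
  trait_type <- match.arg(trait_type)
  G <- as.matrix(G)
  af <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  qual <- which(maf <= max_maf & maf > 0)
  if (length(qual) < 2L)
    return(data.table(p = NA_real_, beta = NA_real_, se = NA_real_,
                      n_qualifying = length(qual), excluded = TRUE))
  Gq <- G[, qual, drop = FALSE]
  flip <- af[qual] > 0.5
  if (any(flip)) Gq[, flip] <- 2 - Gq[, flip]
  burden <- rowSums(Gq)
  r <- single_variant_score_test(matrix(burden, ncol = 1), y, X, trait_type)
  data.table(p = r$p, beta = r$beta, se = r$se,
             n_qualifying = length(qual), excluded = FALSE)
}

CHISQ1_MEDIAN <- stats::qchisq(0.5, df = 1)  # ~0.4549

#' Genomic-control lambda
#'
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`: the median
#' association chi-square over its null expectation (~0.4549 for 1 df).
#'
#' @param p Numeric vector of p-values in `(0, 1]` (`NA`s dropped).
#' @return Numeric lambda (`NA` for empty input).
#' @export
lambda_gc <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) / CHISQ1_MEDIAN
}

#' Expected allele count filter
#'
#' The expected allele count of a summary statistic is `CAF * n_cases` for
#' gene group tests and `MAF * n_cases` for single variants (`n_defined`
#' replaces `n_cases` for continuous traits). Records below the threshold
#' (default 50), or with missing frequency, are removed.
#'
#' @param records `data.table` of summary statistics with columns `freq`
#'   (CAF or MAF), `n_eff` (cases or defined count).
#' @param threshold Minimum expected allele count (default 50).
#' @return The records with an `expected_ac` column, filtered; removed rows
#'   are attached as attribute `"removed"`.
#' @export
expected_ac_filter <- function(records, threshold = 50) {
  records <- copy(as.data.table(records))
  records[, expected_ac := freq * n_eff]
  drop <- is.na(records$expected_ac) | records$expected_ac < threshold
  out <- records[!drop]
  attr(out, "removed") <- records[drop == TRUE]
  out
}

#' Empirical significance thresholds from simulated phenotypes
#'
#' The most significant p-value of a null (simulated) phenotype estimates the
#' inverse of the effective number of tests. Taking the median of these
#' minima across phenotypes, the effective test count is `1 / median` and the
#' experiment-wise threshold is `0.05 * median`, corresponding to 0.05
#' expected false positives per phenotype.
#'
#' @param min_p Numeric vector: each simulated phenotype's minimum p-value
#'   for one test type.
#' @return `list(median_min_p, effective_tests, threshold)`.
#' @export
empirical_thresholds <- function(min_p) {
  stopifnot(length(min_p) >= 1L)
  m <- stats::median(min_p)
  list(median_min_p = m, effective_tests = 1 / m, threshold = 0.05 * m)
}

#' Summary-statistic QC gate
#'
#' Applies, in order: removal of records with `se == 0`; removal of genes
#' with mean coverage below 20 or synonymous-class lambda below 0.75;
#' removal of phenotypes with lambda below 0.75; and the expected allele
#' count filter. Idempotent. An audit log counts removals per rule.
#'
#' @param records Summary-statistic `data.table` with columns `phenotype`,
#'   `unit` (variant key or gene), `gene` (NA for single variants), `test`,
#'   `p`, `beta`, `se`, `freq`, `n_eff`.
#' @param gene_table `data.table` with `gene`, `coverage`,
#'   `lambda_synonymous`.
#' @param phenotype_lambda Named numeric: per-phenotype lambda (computed on
#'   the same records via [lambda_gc()] upstream).
#' @param lambda_cutoff Lambda floor for genes and phenotypes (default 0.75).
#' @param coverage_cutoff Gene coverage floor (default 20).
#' @param expected_ac_threshold Expected-AC floor (default 50).
#' @return Filtered records with attribute `"audit"` (named removal counts).
#' @export
qc_gate <- function(records, gene_table, phenotype_lambda,
                    lambda_cutoff = 0.75, coverage_cutoff = 20,
                    expected_ac_threshold = 50) {
  rec <- copy(as.data.table(records))
  audit <- c()
  n0 <- nrow(rec)
  rec <- rec[is.na(se) | se != 0]
  audit["se_zero"] <- n0 - nrow(rec)

  bad_cov <- gene_table$gene[!is.na(gene_table$coverage) &
                               gene_table$coverage < coverage_cutoff]
  n0 <- nrow(rec)
  rec <- rec[is.na(gene) | !gene %in% bad_cov]
  audit["gene_coverage"] <- n0 - nrow(rec)

  bad_lam <- gene_table$gene[!is.na(gene_table$lambda_synonymous) &
                               gene_table$lambda_synonymous < lambda_cutoff]
  n0 <- nrow(rec)
  rec <- rec[is.na(gene) | !gene %in% bad_lam]
  audit["gene_lambda_synonymous"] <- n0 - nrow(rec)

  bad_ph <- names(phenotype_lambda)[!is.na(phenotype_lambda) &
                                      phenotype_lambda < lambda_cutoff]
  n0 <- nrow(rec)
  rec <- rec[!phenotype %in% bad_ph]
  audit["phenotype_lambda"] <- n0 - nrow(rec)

  n0 <- nrow(rec)
  rec <- expected_ac_filter(rec, threshold = expected_ac_threshold)
  audit["expected_ac"] <- n0 - nrow(rec)

  attr(rec, "audit") <- audit
  rec
}

#' Prune correlated phenotypes
#'
#' Computes pairwise Pearson correlations on standardized phenotype columns
#' (missing values mean-imputed for this step only), draws an edge between
#' phenotype pairs with `r^2` above the cutoff, and keeps a greedy maximal
#' independent set prioritizing phenotypes with more cases (`n_defined` for
#' continuous traits). Zero-variance columns are excluded with a flag.
#'
#' @param pm A `phenotype_matrix`, or a numeric matrix with phenotype
#'   columns.
#' @param n_cases Named priority vector when `pm` is a bare matrix.
#' @param r2_cutoff Squared-correlation edge threshold (default 0.5).
#' @return List: `keep` (phenotype names), `drop`, `excluded`
#'   (zero-variance), `edges`.
#' @export
prune_correlated_phenotypes <- function(pm, n_cases = NULL, r2_cutoff = 0.5) {
  if (inherits(pm, "phenotype_matrix")) {
    vals <- pm$values
    pri <- ifelse(pm$meta$trait_type == "binary", pm$meta$n_cases,
                  pm$meta$n_defined)
    names(pri) <- pm$meta$phenotype
  } else {
    vals <- as.matrix(pm)
    pri <- if (is.null(n_cases))
      stats::setNames(rep(0, ncol(vals)), colnames(vals)) else n_cases
  }
  if (ncol(vals) < 2L) stop("at least two phenotypes required")
  # mean-impute missing values for the correlation step only
  for (j in seq_len(ncol(vals))) {
    m <- is.na(vals[, j])
    if (any(m)) vals[m, j] <- mean(vals[, j], na.rm = TRUE)
  }
  sds <- apply(vals, 2, stats::sd)
  excluded <- colnames(vals)[sds == 0 | is.na(sds)]
  use <- setdiff(colnames(vals), excluded)
  z <- scale(vals[, use, drop = FALSE])
  r <- crossprod(z) / (nrow(z) - 1)
  r2 <- r^2
  idx <- which(upper.tri(r2) & r2 > r2_cutoff, arr.ind = TRUE)
  edges <- data.table(a = use[idx[, 1]], b = use[idx[, 2]])
  keep <- maximal_independent_set(use, edges, priority = pri[use])
  list(keep = keep, drop = setdiff(use, keep), excluded = excluded,
       edges = edges)
}
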