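# CAF-matched resampling enrichment (gene sets, variant classes) and the
# 2pqa^2 variance-explained / power calculation.

#' Cumulative allele frequency of a variant group
#'
#' The plain sum of member allele frequencies (no cap); an empty group has
#' CAF 0.
#'
#' @param afs Numeric vector of member allele frequencies in `(0, 1]`.
#' @return Numeric CAF.
#' @export
cumulative_allele_frequency <- function(afs) {
  if (length(afs) == 0L) return(0)
  if (any(afs <= 0 | afs > 1)) stop("allele frequencies must lie in (0, 1]")
  sum(afs)
}

caf_bin <- function(caf, bin_width = 0.01) as.integer(floor(caf / bin_width))

#' Frequency-matched null distributions by resampling
#'
#' Bins units (genes or variants) by cumulative allele frequency into
#' half-open bins of width `bin_width`. Each resample draws, for every target
#' unit, a background unit with replacement from the same CAF bin, and
#' records the proportion of drawn units with at least one association and
#' the mean association count. An occupied target bin with no background
#' units is an error naming the bin.
#'
#' @param target `data.table` with `unit`, `caf`, `n_assoc`.
#' @param background Same columns; the matched pool.
#' @param bin_width CAF bin width (default 0.01).
#' @param n_sets Number of resampled sets (default 1000).
#' @param seed Integer seed.
#' @return `data.table` with one row per resample: `prop_hit`, `mean_assoc`.
#' @export
caf_matched_null <- function(target, background, bin_width = 0.01,
                             n_sets = 1000L, seed = 1L) {
  target <- as.data.table(target)
  background <- as.data.table(background)
  tb <- caf_bin(target$caf, bin_width)
  bb <- caf_bin(background$caf, bin_width)
  bg_by_bin <- split(seq_len(nrow(background)), bb)
  missing_bins <- setdiff(unique(tb), as.integer(names(bg_by_bin)))
  if (length(missing_bins))
    stop(sprintf("no background units in CAF bin [%g, %g)",
                 missing_bins[1] * bin_width,
                 (missing_bins[1] + 1) * bin_width))
  set.seed(seed)
  n_t <- nrow(target)
  hit_bg <- background$n_assoc > 0L
  draw_mat <- matrix(0L, n_sets, n_t)
  for (b in unique(tb)) {
    cols <- which(tb == b)
    pool <- bg_by_bin[[as.character(b)]]
    draws <- pool[sample.int(length(pool), n_sets * length(cols),
                             replace = TRUE)]
    draw_mat[, cols] <- draws
  }
  data.table(
    prop_hit = rowMeans(matrix(hit_bg[draw_mat], n_sets, n_t)),
    mean_assoc = rowMeans(matrix(background$n_assoc[draw_mat], n_sets, n_t))
  )
}

wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Enrichment test against a matched null
#'
#' Combines the observed target statistics with the resampled null: the
#' empirical one-sided p-value with `(r + 1) / (n_sets + 1)` smoothing, a
#' Fisher exact test on the 2x2 association table (target vs matched
#' background, >= 1 association vs none), the sample odds ratio
#' (cross-product `ad / bc`), and Wilson 95\% confidence intervals on the
#' proportions.
#'
#' @param target `data.table` with `unit`, `caf`, `n_assoc`.
#' @param null_dist Output of [caf_matched_null()].
#' @param table2x2 2x2 matrix: rows target/background, columns
#'   `hit`/`no_hit`. Defaults to the target counts vs the rounded mean null
#'   counts.
#' @return An `enrichment_result` list: `n_target`, `prop_hit`, `mean_assoc`,
#'   `empirical_p`, `fisher_p`, `odds_ratio`, `ci_target`, `ci_background`,
#'   `null_dist`.
#' @export
enrichment_test <- function(target, null_dist, table2x2 = NULL) {
  target <- as.data.table(target)
  n_t <- nrow(target)
  obs_prop <- mean(target$n_assoc > 0L)
  obs_mean <- mean(target$n_assoc)
  n_sets <- nrow(null_dist)
  emp_p <- (sum(null_dist$prop_hit >= obs_prop) + 1) / (n_sets + 1)
  if (is.null(table2x2)) {
    bg_hit <- round(mean(null_dist$prop_hit) * n_t)
    table2x2 <- matrix(c(sum(target$n_assoc > 0L),
                         n_t - sum(target$n_assoc > 0L),
                         bg_hit, n_t - bg_hit),
                       nrow = 2, byrow = TRUE,
                       dimnames = list(c("target", "background"),
                                       c("hit", "no_hit")))
  }
  a <- table2x2[1, 1]; b <- table2x2[1, 2]
  c_ <- table2x2[2, 1]; d <- table2x2[2, 2]
  or <- if (b == 0 || c_ == 0 || (a + b) == 0 || (c_ + d) == 0 ||
            (a + c_) == 0 || (b + d) == 0) {
    NA_real_  # zero margin: OR undefined, reported missing
  } else a * d / (b * c_)
  fis <- stats::fisher.test(table2x2)
  structure(list(
    n_target = n_t, prop_hit = obs_prop, mean_assoc = obs_mean,
    empirical_p = emp_p, fisher_p = fis$p.value, odds_ratio = or,
    ci_target = wilson_ci(a, a + b),
    ci_background = wilson_ci(c_, c_ + d),
    table2x2 = table2x2, null_dist = null_dist
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Enrichment over CAF-matched background (%d target units)\n",
    "  proportion with >= 1 association: %.4f [%.4f, %.4f]\n",
    "  background (matched):             %.4f [%.4f, %.4f]\n",
    "  empirical p = %.4g, Fisher p = %.4g, OR = %.3f\n"),
    x$n_target, x$prop_hit, x$ci_target[1], x$ci_target[2],
    x$table2x2[2, 1] / sum(x$table2x2[2, ]),
    x$ci_background[1], x$ci_background[2],
    x$empirical_p, x$fisher_p, x$odds_ratio))
  invisible(x)
}

#' Variance explained by an additive biallelic variant
#'
#' `2 p q a^2` with `q = 1 - p`: the phenotypic variance captured by a purely
#' additive variant of frequency `p` and allelic effect `a` (per-unit trait
#' scale).
#'
#' @param p Allele frequency in `(0, 1)`.
#' @param a Allelic effect.
#' @return Numeric variance explained.
#' @export
variance_explained <- function(p, a) {
  if (any(p <= 0 | p >= 1)) stop("allele frequency must lie in (0, 1)")
  2 * p * (1 - p) * a^2
}

#' Minimum detectable variance-explained fraction
#'
#' The smallest fraction of phenotypic variance `v` for which a 1-df
#' chi-square test with noncentrality `n * v` attains the target power at
#' level `alpha` (solved by bisection). Power to detect association is
#' proportional to variance explained, so this is the gene- or variant-level
#' detectability floor at a given sample size.
#'
#' @param n Sample size (>= 2).
#' @param alpha Significance level in `(0, 1)`.
#' @param power Target power in `(0, 1)`.
#' @return Numeric `v`.
#' @export
min_detectable_varexp <- function(n, alpha, power) {
  stopifnot(n >= 2, alpha > 0, alpha < 1, power > 0, power < 1)
  crit <- stats::qchisq(1 - alpha, df = 1)
  pw <- function(v) stats::pchisq(crit, df = 1, ncp = n * v,
                                  lower.tail = FALSE) - power
  stats::uniroot(pw, lower = 1e-12, upper = 1, tol = 1e-12)$root
}
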