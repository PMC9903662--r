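# Sample-level QC: interval screening, sex-karyotype imputation from
# normalized sex-chromosome ploidies, hard filters, stratified MAD outlier
# flagging, and greedy maximal-independent-set pruning of related samples.

#' Interval QC
#'
#' Pads capture intervals by `pad` bp on each side (merging intervals that
#' overlap after padding) and passes an interval when at least `frac` of
#' samples reach mean coverage `min_cov` there. Both thresholds are
#' boundary-inclusive.
#'
#' @param intervals `data.table` with `contig`, `start`, `end` (0-based
#'   half-open, BED convention).
#' @param coverage Numeric matrix, one row per input interval, one column per
#'   sample: the per-sample mean coverage of each interval. Coverage of merged
#'   padded intervals is the width-weighted mean of their members.
#' @param frac Minimum passing-sample fraction (default 0.85).
#' @param min_cov Minimum per-sample mean coverage (default 20).
#' @param pad Padding in bp (default 50).
#' @return `data.table` of padded/merged intervals with `frac_covered` and
#'   `pass`.
#' @export
interval_qc <- function(intervals, coverage, frac = 0.85, min_cov = 20,
                        pad = 50L) {
  intervals <- as.data.table(intervals)
  if (is.null(dim(coverage)) || ncol(coverage) == 0L)
    stop("coverage matrix must have at least one sample")
  stopifnot(nrow(coverage) == nrow(intervals))
  out <- list()
  for (ctg in unique(intervals$contig)) {
    idx <- which(intervals$contig == ctg)
    ir <- IRanges::IRanges(start = intervals$start[idx] + 1L - pad,
                           end = intervals$end[idx] + pad)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(ov)
    w <- intervals$end[idx] - intervals$start[idx]
    for (g in seq_along(red)) {
      mem <- which(grp == g)
      cov_g <- colSums(coverage[idx[mem], , drop = FALSE] * w[mem]) /
        sum(w[mem])
      fc <- mean(cov_g >= min_cov)
      out[[length(out) + 1L]] <- data.table(
        contig = ctg,
        start = max(0L, IRanges::start(red)[g] - 1L),
        end = IRanges::end(red)[g],
        frac_covered = fc, pass = fc >= frac)
    }
  }
  rbindlist(out)
}

SEX_PLOIDY_CUTOFFS <- list(
  x_single_upper = 1.55, x_double_lower = 1.6, x_double_upper = 2.15,
  x_triple_lower = 2.2, y_single_lower = 0.06, y_single_upper = 1.3,
  y_double_lower = 1.4
)

#' Impute sex karyotype from normalized X/Y ploidies
#'
#' Ploidies are `2 * mean sex-chromosome coverage / mean chr20 coverage`.
#' X dose: 1 if `x <= 1.55`; 2 if `1.6 <= x <= 2.15`; 3 if `x >= 2.2`.
#' Y dose: 0 if `y < 0.06`; 1 if `0.06 <= y <= 1.3`; 2 if `y >= 1.4`.
#' Values inside a band gap (or dose combinations outside the recognized set)
#' yield `"ambiguous"`, which downstream hard filters remove.
#'
#' @param x,y Normalized X and Y ploidy estimates (vectorized).
#' @return Character vector of karyotypes among
#'   `X0, XX, XXX, XY, XXY, XYY, XXYY, ambiguous`.
#' @export
impute_sex_karyotype <- function(x, y) {
  co <- SEX_PLOIDY_CUTOFFS
  x_dose <- ifelse(x <= co$x_single_upper, 1L,
            ifelse(x >= co$x_double_lower & x <= co$x_double_upper, 2L,
            ifelse(x >= co$x_triple_lower, 3L, NA_integer_)))
  y_dose <- ifelse(y < co$y_single_lower, 0L,
            ifelse(y >= co$y_single_lower & y <= co$y_single_upper, 1L,
            ifelse(y >= co$y_double_lower, 2L, NA_integer_)))
  kt <- rep("ambiguous", length(x))
  ok <- !is.na(x_dose) & !is.na(y_dose)
  key <- paste0(x_dose, "_", y_dose)
  tbl <- c("1_0" = "X0", "2_0" = "XX", "3_0" = "XXX", "1_1" = "XY",
           "2_1" = "XXY", "1_2" = "XYY", "2_2" = "XXYY")
  kt[ok] <- unname(tbl[key[ok]])
  kt[is.na(kt)] <- "ambiguous"
  kt
}

#' Sample hard filters
#'
#' A sample passes if its imputed karyotype is XX or XY, its call rate is at
#' least 0.99, and its mean coverage is at least 20x.
#'
#' @param karyotype Character vector from [impute_sex_karyotype()].
#' @param call_rate Numeric in `[0, 1]`.
#' @param mean_coverage Numeric.
#' @return `data.table` with `pass` and a comma-separated `reasons` column.
#' @export
sample_hard_filters <- function(karyotype, call_rate, mean_coverage) {
  n <- length(karyotype)
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    r <- character()
    if (!karyotype[i] %in% c("XX", "XY")) r <- c(r, "sex_karyotype")
    if (call_rate[i] < 0.99) r <- c(r, "call_rate")
    if (mean_coverage[i] < 20) r <- c(r, "coverage")
    reasons[[i]] <- r
  }
  data.table(pass = lengths(reasons) == 0L,
             reasons = vapply(reasons, paste, "", collapse = ","))
}

#' Stratified MAD outlier flags
#'
#' Within each stratum (population x batch) and metric, flags samples whose
#' value lies more than `n_mads` raw median absolute deviations from the
#' stratum median. The MAD is unscaled (no 1.4826 consistency factor). A
#' sample is an outlier if flagged on any metric.
#'
#' @param metrics `data.table` with `sample`, `stratum` and numeric metric
#'   columns (e.g. `n_snvs`, `n_insertions`, `n_deletions`, `r_ins_del`,
#'   `r_ti_tv`, `r_het_hom`).
#' @param n_mads Number of MADs (default 4).
#' @return `data.table` with `sample`, `metric`, `flag` (long form) plus an
#'   `outlier` summary attribute column via [mad_outliers()].
#' @export
mad_outlier_flags <- function(metrics, n_mads = 4) {
  metric_cols <- setdiff(names(metrics), c("sample", "stratum"))
  long <- data.table::melt(metrics, id.vars = c("sample", "stratum"),
                           measure.vars = metric_cols,
                           variable.name = "metric", value.name = "value")
  long[, `:=`(med = stats::median(value),
              mad_raw = stats::median(abs(value - stats::median(value)))),
       by = .(stratum, metric)]
  long[, flag := abs(value - med) > n_mads * mad_raw]
  long[, .(sample, stratum, metric, value, flag)]
}

#' Per-sample outlier summary over MAD flags
#'
#' @param flags Output of [mad_outlier_flags()].
#' @return `data.table` with `sample` and logical `outlier`.
#' @export
mad_outliers <- function(flags) {
  flags[, .(outlier = any(flag)), by = sample]
}

#' Greedy maximal independent set
#'
#' Returns a maximal independent set of the relatedness (or correlation)
#' graph by repeatedly removing the highest-degree vertex; ties are broken by
#' removing the vertex with the lower priority score first, then by vertex
#' id. Used to keep the largest set of unrelated samples (kinship edges) and
#' of uncorrelated phenotypes, prioritizing greater mean depth or case count.
#'
#' @param vertices Character vector of vertex ids.
#' @param edges Two-column `data.frame`/`data.table` (or matrix) of
#'   undirected edges between vertex ids; self-edges are invalid.
#' @param priority Numeric vector aligned with `vertices` (higher = keep
#'   preferentially). Defaults to 0.
#' @return Character vector: the kept (independent, maximal) vertex set.
#' @export
maximal_independent_set <- function(vertices, edges, priority = NULL) {
  if (is.null(priority)) priority <- rep(0, length(vertices))
  stopifnot(length(priority) == length(vertices))
  edges <- as.data.table(edges)
  if (nrow(edges)) {
    setnames(edges, 1:2, c("a", "b"))
    if (any(edges$a == edges$b)) stop("self-edges are not allowed")
    if (!all(c(edges$a, edges$b) %in% vertices))
      stop("edge endpoint not among vertices")
  }
  adj <- lapply(stats::setNames(vertices, vertices), function(v) character())
  for (r in seq_len(nrow(edges))) {
    a <- edges$a[r]; b <- edges$b[r]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  alive <- stats::setNames(rep(TRUE, length(vertices)), vertices)
  pri <- stats::setNames(priority, vertices)
  removed <- character()
  repeat {
    deg <- vapply(vertices[alive], function(v)
      sum(alive[adj[[v]]]), 0L)
    if (length(deg) == 0L || max(deg) == 0L) break
    cand <- names(deg)[deg == max(deg)]
    cand <- cand[pri[cand] == min(pri[cand])]
    drop <- sort(cand)[1]
    alive[drop] <- FALSE
    removed <- c(removed, drop)
  }
  # maximality sweep: re-admit removed vertices whose neighbors all ended up
  # removed too (highest priority first, then id)
  for (v in removed[order(-pri[removed], removed)]) {
    if (!any(alive[adj[[v]]])) alive[v] <- TRUE
  }
  vertices[alive[vertices]]
}
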