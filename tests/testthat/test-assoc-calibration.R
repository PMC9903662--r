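identity_grm <- function(n) {
  structure(list(samples = sprintf("S%03d", seq_len(n)),
                 matrix = Matrix::Diagonal(n)), class = "grm")
}

related_grm <- function(n_pairs, n_singletons = 0) {
  n <- 2 * n_pairs + n_singletons
  m <- Matrix::Diagonal(n)
  for (k in seq_len(n_pairs)) {
    i <- 2 * k - 1
    m[i, i + 1] <- 0.5; m[i + 1, i] <- 0.5
  }
  structure(list(samples = sprintf("S%03d", seq_len(n)),
                 matrix = Matrix::forceSymmetric(m)), class = "grm")
}

test_that("phenotype simulation honors heritability bounds and determinism", {
  expect_error(simulate_random_phenotypes(identity_grm(10), 2, h2 = 1.5),
               "heritabilities")
  expect_error(simulate_random_phenotypes(identity_grm(10), 2,
                                          prevalence = 0.7), "prevalences")
  pm1 <- simulate_random_phenotypes(identity_grm(50), 4, h2 = c(0.1, 1),
                                    seed = 9)
  pm2 <- simulate_random_phenotypes(identity_grm(50), 4, h2 = c(0.1, 1),
                                    seed = 9)
  expect_identical(pm1$values, pm2$values)
  expect_identical(pm1$meta$h2, c(0.1, 1, 0.1, 1))
})

test_that("binary phenotypes hit the requested prevalence exactly", {
  pm <- simulate_random_phenotypes(identity_grm(10000), 3,
                                   prevalence = c(0.1, 0.013), seed = 2)
  expect_equal(sum(pm$values[, 2]), 1000)
  expect_equal(sum(pm$values[, 3]), floor(0.013 * 10000))
  expect_identical(pm$meta$trait_type, c("continuous", "binary", "binary"))
  expect_identical(pm$meta$n_cases, c(NA_integer_, 1000L, 130L))
})

test_that("with h2 = 0 related pairs are uncorrelated; identity GRM gives iid columns", {
  grm <- related_grm(n_pairs = 10)
  reps <- 500
  set.seed(1)
  r0 <- sapply(seq_len(reps), function(k) {
    pm <- simulate_random_phenotypes(grm, 1, h2 = 0, seed = 1000 + k)
    y <- pm$values[, 1]
    mean(y[seq(1, 19, 2)] * y[seq(2, 20, 2)])  # mean pairwise product
  })
  expect_lt(abs(mean(r0)), 3 * sd(r0) / sqrt(reps))
  # identity GRM, h2 = 1: standard normal margins
  pm <- simulate_random_phenotypes(identity_grm(5000), 1, h2 = 1, seed = 3)
  expect_equal(mean(pm$values), 0, tolerance = 0.06)
  expect_equal(sd(pm$values), 1, tolerance = 0.05)
})

test_that("simulated phenotype covariance recovers h2 * GRM + (1 - h2) * I", {
  grm <- related_grm(n_pairs = 5)
  h2 <- 0.6
  reps <- 600
  ys <- sapply(seq_len(reps), function(k)
    simulate_random_phenotypes(grm, 1, h2 = h2, seed = 5000 + k)$values[, 1])
  emp <- tcrossprod(ys - rowMeans(ys)) / (reps - 1)
  want <- as.matrix(h2 * grm$matrix + (1 - h2) * Matrix::Diagonal(10))
  # Monte-Carlo tolerance ~ 1/sqrt(reps)
  expect_lt(max(abs(emp - want)), 6 / sqrt(reps))
  # related pairs really are correlated at h2 * 0.5
  off <- mean(sapply(seq(1, 9, 2), function(i) emp[i, i + 1]))
  expect_equal(off, h2 * 0.5, tolerance = 0.1)
})

test_that("score test is permutation-stable and matches a full regression fit", {
  set.seed(11)
  n <- 2000
  g <- rbinom(n, 2, 0.2)
  X <- cbind(age = rnorm(n, 50, 5))
  y <- 1 * g + 0.02 * X[, 1] + rnorm(n)
  r <- single_variant_score_test(matrix(g, ncol = 1), y, X)
  expect_lt(r$p, 1e-10)
  expect_gt(r$beta, 0)
  fit <- summary(lm(y ~ g + X))$coefficients["g", ]
  expect_equal(r$beta, unname(fit["Estimate"]), tolerance = 1e-3)
  expect_equal(r$se, unname(fit["Std. Error"]), tolerance = 1e-3)
  # permuting sample order of genotype and phenotype together: identical p
  perm <- sample(n)
  r2 <- single_variant_score_test(matrix(g[perm], ncol = 1), y[perm],
                                  X[perm, , drop = FALSE])
  expect_equal(r2$p, r$p, tolerance = 1e-12)
  # zero-variance genotype is skipped with a flag
  r3 <- single_variant_score_test(matrix(1, n, 1), y, X)
  expect_true(r3$skip_flag)
  expect_true(is.na(r3$p))
})

test_that("binary score test matches a logistic regression fit on strong effects", {
  set.seed(13)
  n <- 3000
  g <- rbinom(n, 2, 0.3)
  eta <- -1 + 0.8 * g
  y <- rbinom(n, 1, plogis(eta))
  r <- single_variant_score_test(matrix(g, ncol = 1), y, NULL, "binary")
  fit <- summary(glm(y ~ g, family = binomial))$coefficients["g", ]
  expect_lt(r$p, 1e-10)
  expect_equal(sign(r$beta), sign(unname(fit["Estimate"])))
})

test_that("null score tests keep nominal type-I error and lambda near 1", {
  set.seed(17)
  n <- 1000; m <- 1000
  G <- hwe_dose_matrix(n, runif(m, 0.05, 0.5), seed = 18)
  y <- rnorm(n)
  r <- single_variant_score_test(G, y, NULL)
  for (alpha in c(0.05, 0.01)) {
    se3 <- 3 * sqrt(alpha * (1 - alpha) / m)
    expect_lt(abs(mean(r$p < alpha) - alpha), se3)
  }
  expect_gt(lambda_gc(r$p), 0.9)
  expect_lt(lambda_gc(r$p), 1.1)
})

test_that("burden test enforces group size and MAF ceiling, sums disjoint carriers", {
  set.seed(19)
  n <- 500
  g1 <- c(rep(1, 4), rep(0, n - 4))
  g2 <- c(rep(0, 4), rep(1, 3), rep(0, n - 7))
  y <- rnorm(n)
  # one qualifying variant: excluded
  r1 <- burden_test(cbind(g1, g2 * 0), y)
  expect_true(r1$excluded)
  # a common variant is excluded from the score
  common <- rbinom(n, 2, 0.05)   # MAF 0.05 > 0.01
  r2 <- burden_test(cbind(g1, g2, common), y)
  expect_equal(r2$n_qualifying, 2L)
  # disjoint carriers: burden equals elementwise sum, p matches the
  # single-dosage test on that sum
  r3 <- burden_test(cbind(g1, g2), y)
  sv <- single_variant_score_test(matrix(g1 + g2, ncol = 1), y)
  expect_equal(r3$p, sv$p, tolerance = 1e-12)
  expect_equal(r3$beta, sv$beta, tolerance = 1e-12)
})

test_that("lambda GC matches the chi-square median transform", {
  expect_equal(lambda_gc(rep(0.5, 10)), 1)
  grid <- seq(1e-4, 1 - 1e-4, length.out = 10001)
  expect_equal(lambda_gc(grid), 1, tolerance = 1e-3)
  expect_equal(lambda_gc(rep(1, 5)), 0)
  expect_true(is.na(lambda_gc(numeric())))
})

test_that("expected allele count filters at CAF (or MAF) times case count", {
  rec <- data.table::data.table(
    unit = c("g1", "v1", "g2"),
    freq = c(1.5e-4, 1e-4, 0),
    n_eff = c(394841L, 400000L, 394841L))
  out <- expected_ac_filter(rec)
  # 1.5e-4 * 394841 = 59.2 retained; 1e-4 * 4e5 = 40 removed; CAF 0 removed
  expect_identical(out$unit, "g1")
  expect_equal(out$expected_ac, 59.22615, tolerance = 1e-6)
  removed <- attr(out, "removed")
  expect_setequal(removed$unit, c("v1", "g2"))
  expect_equal(removed$expected_ac[removed$unit == "v1"], 40)
  # missing frequency is removed with the rest
  rec2 <- data.table::data.table(unit = "x", freq = NA_real_, n_eff = 100L)
  expect_equal(nrow(expected_ac_filter(rec2)), 0L)
})

test_that("empirical thresholds are 0.05 times the median minimum p", {
  t1 <- empirical_thresholds(5e-6)
  expect_equal(t1$threshold, 2.5e-7)
  expect_equal(t1$effective_tests, 2e5)
  t2 <- empirical_thresholds(1.6e-7)
  expect_equal(t2$threshold, 8e-9)
  t3 <- empirical_thresholds(1)
  expect_equal(t3$threshold, 0.05)
  expect_equal(t3$effective_tests, 1)
  # monotone increasing in the median minimum p
  ms <- sort(runif(20, 1e-8, 1e-2))
  th <- vapply(ms, function(m) empirical_thresholds(m)$threshold, 0)
  expect_true(all(diff(th) > 0))
  # median across phenotypes
  tm <- empirical_thresholds(c(1e-6, 5e-6, 9e-6))
  expect_equal(tm$median_min_p, 5e-6)
})

test_that("the QC gate applies each rule, logs counts, and is idempotent", {
  rec <- data.table::data.table(
    phenotype = c("p1", "p1", "p1", "p2", "p1"),
    unit = c("g1|syn", "g2|syn", "v1", "g1|syn", "g3|syn"),
    gene = c("g1", "g2", NA, "g1", "g3"),
    test = c("burden", "burden", "single_variant", "burden", "burden"),
    p = c(0.5, 0.5, 0.5, 0.5, 0.5), beta = 0.1,
    se = c(0.1, 0.1, 0.1, 0.1, 0),
    freq = c(0.01, 0.01, 0.01, 0.01, 0.01), n_eff = 10000L)
  gene_tab <- data.table::data.table(
    gene = c("g1", "g2", "g3"), coverage = c(30, 30, 30),
    lambda_synonymous = c(1.0, 0.6, 1.0))
  ph_lambda <- c(p1 = 1.0, p2 = 0.5)
  out <- qc_gate(rec, gene_tab, ph_lambda)
  # removed: g3 record (SE 0), all g2 records (syn lambda 0.6),
  # all p2 records (phenotype lambda 0.5)
  expect_setequal(out$unit, c("g1|syn", "v1"))
  aud <- attr(out, "audit")
  expect_equal(unname(aud["se_zero"]), 1)
  expect_equal(unname(aud["gene_lambda_synonymous"]), 1)
  expect_equal(unname(aud["phenotype_lambda"]), 1)
  # idempotent
  out2 <- qc_gate(out, gene_tab, ph_lambda)
  expect_equal(as.data.frame(out2), as.data.frame(out), ignore_attr = TRUE)
  # vacuous filters: output = input (plus the expected-AC column)
  ok <- qc_gate(rec[1:3], gene_tab[lambda_synonymous > 0.75],
                c(p1 = 1.0))
  expect_equal(nrow(ok), 3L)
})

test_that("coverage and lambda gene rules drop low-coverage genes", {
  rec <- data.table::data.table(
    phenotype = "p1", unit = c("g1|syn", "g2|syn"), gene = c("g1", "g2"),
    test = "burden", p = 0.5, beta = 0, se = 0.1, freq = 0.01,
    n_eff = 10000L)
  gene_tab <- data.table::data.table(gene = c("g1", "g2"),
                                     coverage = c(19.9, 25),
                                     lambda_synonymous = c(1, 1))
  out <- qc_gate(rec, gene_tab, c(p1 = 1))
  expect_identical(out$gene, "g2")
})

test_that("phenotype pruning drops the lower-case-count duplicate", {
  set.seed(23)
  n <- 400
  base <- rbinom(n, 1, 0.3)
  vals <- cbind(ph_a = base, ph_b = base, ph_c = rnorm(n))
  pri <- c(ph_a = 100, ph_b = 200, ph_c = n)
  res <- prune_correlated_phenotypes(vals, n_cases = pri)
  expect_true("ph_b" %in% res$keep)   # more cases wins
  expect_false("ph_a" %in% res$keep)
  expect_true("ph_c" %in% res$keep)
  # orthogonal columns are all kept
  ortho <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("q", 1:4)))
  res2 <- prune_correlated_phenotypes(ortho,
                                      n_cases = setNames(1:4, paste0("q", 1:4)))
  expect_setequal(res2$keep, paste0("q", 1:4))
  # kept set has all pairwise r^2 <= 0.5 by direct recomputation
  set.seed(29)
  m <- 12
  z <- matrix(rnorm(n * m), n, m)
  z[, 2] <- z[, 1] + rnorm(n, 0, 0.3)
  z[, 5] <- -z[, 4] + rnorm(n, 0, 0.2)
  colnames(z) <- sprintf("w%02d", 1:m)
  res3 <- prune_correlated_phenotypes(z, n_cases = setNames(rep(1, m),
                                                            colnames(z)))
  ck <- cor(z[, res3$keep])^2
  diag(ck) <- 0
  expect_lt(max(ck), 0.5 + 1e-12)
  # zero-variance columns are excluded with a flag
  zz <- cbind(z[, 1:3], const = rep(1, n))
  res4 <- prune_correlated_phenotypes(zz, n_cases = setNames(rep(1, 4),
                                                             colnames(zz)))
  expect_identical(res4$excluded, "const")
})
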