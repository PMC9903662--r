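# Independent oracles used by the tests. These deliberately avoid the package
# code paths they check: the joint-matrix oracle parses gVCF text directly,
# the MIS oracle enumerates subsets, and the binomial/hypergeometric oracles
# are explicit tail sums.

# Brute-force joint genotype matrix built directly from gVCF files: for every
# variant locus (union over samples) and every sample, take the sample's
# variant line if present, else a spanning reference block, else missing.
oracle_joint_matrix <- function(gvcf_paths) {
  per_sample <- lapply(gvcf_paths, function(p) {
    lines <- readLines(p)
    body <- lines[!startsWith(lines, "#")]
    f <- strsplit(body, "\t", fixed = TRUE)
    data.frame(
      contig = vapply(f, `[`, "", 1),
      pos = as.integer(vapply(f, `[`, "", 2)),
      ref = vapply(f, `[`, "", 4),
      alt = vapply(f, `[`, "", 5),
      info = vapply(f, `[`, "", 8),
      geno = vapply(f, `[`, "", 10),
      stringsAsFactors = FALSE)
  })
  samples <- names(gvcf_paths)
  # variant loci and the union of real alternates at each
  var_loci <- list()
  for (s in samples) {
    d <- per_sample[[s]]
    v <- d[!startsWith(d$info, "END="), ]
    for (i in seq_len(nrow(v))) {
      key <- paste(v$contig[i], v$pos[i])
      alts <- setdiff(strsplit(v$alt[i], ",", fixed = TRUE)[[1]], "<NON_REF>")
      prev <- var_loci[[key]]
      var_loci[[key]] <- list(
        contig = v$contig[i], pos = v$pos[i], ref = v$ref[i],
        alts = union(if (is.null(prev)) character() else prev$alts, alts))
    }
  }
  res <- list()
  for (key in names(var_loci)) {
    lc <- var_loci[[key]]
    alts_sorted <- lc$alts[order(lc$alts, method = "radix")]
    for (s in samples) {
      d <- per_sample[[s]]
      hit <- which(d$contig == lc$contig & d$pos == lc$pos &
                     !startsWith(d$info, "END="))
      if (length(hit) == 1L) {
        own_alts <- setdiff(strsplit(d$alt[hit], ",", fixed = TRUE)[[1]],
                            "<NON_REF>")
        own_all <- c(d$ref[hit], own_alts)
        gt_local <- as.integer(
          strsplit(strsplit(d$geno[hit], ":", fixed = TRUE)[[1]][1],
                   "/", fixed = TRUE)[[1]])
        glob <- match(own_all[gt_local + 1L], c(lc$ref, alts_sorted)) - 1L
        gt <- paste(sort(glob), collapse = "/")
      } else {
        blocks <- d[startsWith(d$info, "END="), ]
        blocks <- blocks[blocks$contig == lc$contig, ]
        ends <- as.integer(sub("END=", "", blocks$info))
        span <- which(blocks$pos <= lc$pos & ends >= lc$pos)
        gt <- if (length(span)) "0/0" else NA_character_
      }
      res[[length(res) + 1L]] <- data.frame(
        contig = lc$contig, pos = lc$pos, sample = s, gt = gt,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

# exhaustive independent-set checks on small graphs
oracle_is_independent <- function(kept, edges) {
  if (nrow(edges) == 0L) return(TRUE)
  !any(edges[[1]] %in% kept & edges[[2]] %in% kept)
}

oracle_is_maximal <- function(kept, vertices, edges) {
  excluded <- setdiff(vertices, kept)
  all(vapply(excluded, function(v) {
    nb <- c(edges[[2]][edges[[1]] == v], edges[[1]][edges[[2]] == v])
    any(nb %in% kept)
  }, TRUE))
}

# two-sided exact binomial p at p0 = 0.5: sum of all outcome probabilities at
# most that of the observed count
oracle_binom_two_sided <- function(k, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= dbinom(k, n, 0.5) * (1 + 1e-7)])
}

# Fisher exact two-sided p for a 2x2 table via hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Mendelian consistency of a trio at one site: the child's unordered genotype
# must be formable from one allele of each parent (checked exhaustively)
oracle_mendelian_ok <- function(child, father, mother) {
  for (i in 1:2) for (j in 1:2) {
    if (setequal_multiset(child, c(father[i], mother[j]))) return(TRUE)
  }
  FALSE
}

setequal_multiset <- function(a, b) identical(sort(a), sort(b))

# reference implementation of the merge round count
oracle_rounds <- function(s, n) {
  if (s == 1) return(0L)
  r <- 0L
  while (n^r < s) r <- r + 1L
  r
}
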