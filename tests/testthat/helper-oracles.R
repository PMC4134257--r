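# Independent oracles used to validate the package's exact tests and
# adjustments. Each deliberately takes a different computational route
# from the implementation it checks.

# Two-sided Fisher p by direct enumeration of the hypergeometric support
# using binomial coefficients (no dhyper).
oracle_fisher <- function(a, b, c_, d) {
  m <- a + b; r <- a + c_; N <- a + b + c_ + d
  if (m == 0 || r == 0 || m == N || r == N) return(1.0)
  xs <- max(0, r + m - N):min(r, m)
  pr <- choose(m, xs) * choose(N - m, r - xs) / choose(N, r)
  obs <- pr[xs == a]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Exact HWE p by the ratio recurrence on heterozygote counts
# (unnormalized probabilities built multiplicatively, no factorials).
oracle_hwe <- function(n_hom_minor, n_het, n_hom_major) {
  nm <- 2 * n_hom_minor + n_het
  nM <- 2 * n_hom_major + n_het
  if (nm == 0 || nM == 0) return(1.0)
  hs <- seq.int(nm %% 2, min(nm, nM), by = 2)
  w <- numeric(length(hs))
  w[1] <- 1
  if (length(hs) > 1) {
    for (i in 2:length(hs)) {
      h <- hs[i - 1]
      # P(h+2)/P(h) = 4 * ((nm-h)/2) * ((nM-h)/2) / ((h+1)(h+2))
      w[i] <- w[i - 1] * 4 * ((nm - h) / 2) * ((nM - h) / 2) /
        ((h + 1) * (h + 2))
    }
  }
  pr <- w / sum(w)
  obs <- pr[hs == n_het]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Quadratic-time BH step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) p[o[j]] * m / j, 0)
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# AUC by explicit concordant-pair counting.
oracle_auc <- function(scores, outcome) {
  s1 <- scores[outcome == 1]; s0 <- scores[outcome == 0]
  tot <- 0
  for (u in s1) for (v in s0)
    tot <- tot + (u > v) + 0.5 * (u == v)
  tot / (length(s1) * length(s0))
}

# Plain per-SNP two-stage min-p (scalar Fisher calls, no margin caching).
oracle_two_stage_minp <- function(geno, cohort, snps, config) {
  y <- cohort$outcome
  mono <- cohort$monotherapy
  dos <- geno$dosage[match(cohort$patient_id, geno$patient_ids), snps,
                     drop = FALSE]
  p2s <- c()
  for (s in snps) {
    d1 <- dos[mono, s]; y1 <- y[mono]
    k1 <- !is.na(d1)
    p1 <- fisher_exact_two_sided(
      build_contingency(d1[k1], y1[k1], config$model))
    if (p1 < config$alpha1) {
      d2 <- dos[, s]; k2 <- !is.na(d2)
      p2s <- c(p2s, fisher_exact_two_sided(
        build_contingency(d2[k2], y[k2], config$model)))
    }
  }
  if (length(p2s)) min(p2s) else 1.0
}

# Small VCF fixture writer (GT-only records).
write_test_vcf <- function(path, samples, records) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    vapply(records, function(r) paste(r, collapse = "\t"), ""))
  writeLines(lines, path)
  path
}
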