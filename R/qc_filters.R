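#' Minor allele frequency from genotype counts
#'
#' @param n_hom_minor,n_het,n_hom_major genotype counts over non-missing
#'   patients (minor homozygote, heterozygote, major homozygote).
#' @return allele frequency (2*n_hom_minor + n_het) / (2*n_total). Values
#'   above 0.5 indicate that the upstream minor-allele orientation is stale;
#'   the frequency is reported as computed, never flipped here.
#' @export
minor_allele_frequency <- function(n_hom_minor, n_het, n_hom_major) {
  n <- n_hom_minor + n_het + n_hom_major
  if (n < 1) stop("need at least one non-missing genotype")
  (2 * n_hom_minor + n_het) / (2 * n)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the sample size n and the minor-allele
#' count, heterozygote counts with the same parity as the minor-allele count
#' are enumerated; the p-value sums the conditional probabilities of all
#' heterozygote counts whose probability does not exceed that of the
#' observed count (probability-ordering rule, relative tie tolerance 1e-7).
#' Monomorphic SNPs return 1. No mid-p correction.
#'
#' @inheritParams minor_allele_frequency
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom_minor, n_het, n_hom_major) {
  if (any(c(n_hom_minor, n_het, n_hom_major) < 0))
    stop("genotype counts must be non-negative")
  n <- n_hom_minor + n_het + n_hom_major
  nm <- 2 * n_hom_minor + n_het   # minor alleles
  nM <- 2 * n_hom_major + n_het   # major alleles
  if (nm == 0 || nM == 0) return(1.0)
  hs <- seq.int(nm %% 2, min(nm, nM), by = 2)
  # log P(h | n, nm) up to the common normalizer
  lp <- hs * log(2) - lfactorial((nm - hs) / 2) - lfactorial(hs) -
    lfactorial((nM - hs) / 2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

#' Per-SNP quality-control filter
#'
#' Computes genotype counts, minor allele frequency and the exact
#' Hardy-Weinberg p-value per SNP over non-missing patients, and flags SNPs
#' passing both filters. Exclusion is strict: a SNP fails iff
#' `hwe_p < hwe_threshold` or `maf < maf_threshold` (so a SNP exactly at a
#' threshold is retained). SNPs with no non-missing genotype fail with a
#' message.
#'
#' @param genotypes a [genotype_matrix()].
#' @param hwe_threshold HWE p-value threshold (default 0.2).
#' @param maf_threshold minor-allele-frequency threshold (default 0.05).
#' @return list with `pass` (character vector of passing SNP ids, input
#'   order) and `records` (data frame: snp_id, n_hom_minor, n_het,
#'   n_hom_major, n_missing, maf, hwe_p, pass).
#' @export
qc_filter <- function(genotypes, hwe_threshold = 0.2, maf_threshold = 0.05) {
  stopifnot(hwe_threshold >= 0, hwe_threshold <= 1,
            maf_threshold >= 0, maf_threshold <= 1)
  dos <- genotypes$dosage
  S <- ncol(dos)
  rec <- data.frame(
    snp_id = genotypes$snp_ids,
    n_hom_minor = integer(S), n_het = integer(S), n_hom_major = integer(S),
    n_missing = integer(S), maf = rep(NA_real_, S),
    hwe_p = rep(NA_real_, S), pass = logical(S),
    stringsAsFactors = FALSE)
  for (j in seq_len(S)) {
    d <- dos[, j]
    miss <- is.na(d)
    rec$n_missing[j] <- sum(miss)
    d <- d[!miss]
    rec$n_hom_minor[j] <- sum(d == 2L)
    rec$n_het[j] <- sum(d == 1L)
    rec$n_hom_major[j] <- sum(d == 0L)
    if (!length(d)) next
    rec$maf[j] <- minor_allele_frequency(rec$n_hom_minor[j], rec$n_het[j],
                                         rec$n_hom_major[j])
    rec$hwe_p[j] <- hwe_exact_p(rec$n_hom_minor[j], rec$n_het[j],
                                rec$n_hom_major[j])
    rec$pass[j] <- rec$hwe_p[j] >= hwe_threshold &&
      rec$maf[j] >= maf_threshold
  }
  if (any(rec$n_missing == nrow(dos)))
    message(sum(rec$n_missing == nrow(dos)),
            " all-missing SNP(s) failed QC")
  list(pass = rec$snp_id[rec$pass], records = rec)
}

#' Write the QC report
#'
#' @param qc result of [qc_filter()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  utils::write.table(format(qc$records, digits = 15, trim = TRUE,
                            scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
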