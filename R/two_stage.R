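#' Screening configuration
#'
#' @param alpha1 stage-1 selection threshold on the Fisher p-value
#'   (default 0.005).
#' @param model genetic model used at both screening stages
#'   (default "allele").
#' @param n_perm number of permutations for the min-p null (default 1e5).
#' @param seed integer RNG seed for the permutation stream.
#' @param stratified if TRUE, labels are shuffled within the monotherapy and
#'   combination strata separately; the default shuffles across all
#'   patients of the full dataset.
#' @return object of class `screen_config`.
#' @export
screen_config <- function(alpha1 = 0.005,
                          model = c("allele", "dominant", "recessive"),
                          n_perm = 100000L, seed = 1L,
                          stratified = FALSE) {
  model <- match.arg(model)
  stopifnot(alpha1 > 0, alpha1 < 1, n_perm >= 1)
  structure(list(alpha1 = alpha1, model = model,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "screen_config")
}

# Per-patient minor-unit matrix for a genetic model; allele counts
# chromosomes (2 units/patient), dominant/recessive count patients.
.unit_matrix <- function(dosage, model) {
  switch(model,
         allele = dosage,
         dominant = (dosage >= 1L) + 0L,
         recessive = (dosage == 2L) + 0L)
}

.unit_weight <- function(model) if (model == "allele") 2L else 1L

# Two-sided Fisher p over all possible 'a' for fixed margins:
# N units total, K minor units, r event units. Returns vector indexed a+1,
# a = 0..K (NA outside the hypergeometric support).
.fisher_row <- function(N, K, r) {
  out <- rep(NA_real_, K + 1L)
  if (K == 0L || r == 0L || K == N || r == N) {
    sup <- max(0L, r + K - N):min(r, K)
    out[sup + 1L] <- 1.0
    return(out)
  }
  lo <- max(0L, r + K - N); hi <- min(r, K)
  xs <- lo:hi
  pr <- stats::dhyper(xs, K, N - K, r)
  cmp <- outer(pr, pr * (1 + 1e-7), "<=")
  out[xs + 1L] <- pmin(1, colSums(pr * cmp))
  out
}

# Vectorized lookup: per-SNP margins (N, K, r) and observed a; rows cached
# across permutations in `cache` (an environment).
.lookup_fisher <- function(N, K, r, a, cache) {
  key <- paste0(N, ":", K, ":", r)
  out <- numeric(length(key))
  for (s in seq_along(key)) {
    row <- cache[[key[s]]]
    if (is.null(row)) {
      row <- .fisher_row(N[s], K[s], r[s])
      cache[[key[s]]] <- row
    }
    out[s] <- row[a[s] + 1L]
  }
  out
}

# Margin constants reused by observed and permuted screenings.
.screen_setup <- function(genotypes, cohort, snps, config) {
  stopifnot(all(snps %in% genotypes$snp_ids))
  dos <- genotypes$dosage[match(cohort$patient_id, genotypes$patient_ids),
                          snps, drop = FALSE]
  U <- .unit_matrix(dos, config$model)
  nm <- !is.na(U)
  U0 <- U; U0[!nm] <- 0L
  w <- .unit_weight(config$model)
  mono <- cohort$monotherapy
  list(U0 = U0, nm = nm + 0L, w = w, mono = mono, snps = snps,
       U1 = U0[mono, , drop = FALSE], nm1 = (nm + 0L)[mono, , drop = FALSE],
       K1 = colSums(U0[mono, , drop = FALSE]),
       N1 = w * colSums(nm[mono, , drop = FALSE]),
       K2 = colSums(U0), N2 = w * colSums(nm))
}

# p-values for all SNPs in one stage given an outcome vector.
.stage_p <- function(setup, y, stage, cache, subset = NULL) {
  if (stage == 1L) {
    U <- setup$U1; NM <- setup$nm1; K <- setup$K1; N <- setup$N1
  } else {
    U <- setup$U0; NM <- setup$nm; K <- setup$K2; N <- setup$N2
  }
  if (!is.null(subset)) {
    U <- U[, subset, drop = FALSE]; NM <- NM[, subset, drop = FALSE]
    K <- K[subset]; N <- N[subset]
  }
  a <- drop(crossprod(U, y))
  r <- setup$w * drop(crossprod(NM, y))
  .lookup_fisher(N, K, r, a, cache)
}

#' Stage-1 screening on the monotherapy subset
#'
#' Fisher's exact test per candidate SNP on the first (monotherapy) dataset
#' under the configured genetic model; SNPs with p < alpha1 are selected.
#'
#' @param genotypes a [genotype_matrix()] covering at least the first
#'   dataset's patients.
#' @param cohort cohort data frame with `outcome` and `monotherapy`; only
#'   monotherapy rows are used.
#' @param snps candidate SNP ids (must exist in `genotypes`).
#' @param config a [screen_config()].
#' @return data frame: snp_id, p_stage1, selected.
#' @export
stage1_screen <- function(genotypes, cohort, snps, config = screen_config()) {
  if (!length(snps)) stop("empty candidate set")
  if (!any(cohort$monotherapy)) stop("first dataset is empty")
  setup <- .screen_setup(genotypes, cohort, snps, config)
  cache <- new.env(parent = emptyenv())
  p1 <- .stage_p(setup, cohort$outcome[setup$mono], 1L, cache)
  data.frame(snp_id = snps, p_stage1 = p1, selected = p1 < config$alpha1,
             stringsAsFactors = FALSE)
}

#' Run the two-stage screening
#'
#' Stage 1 selects SNPs with Fisher p < alpha1 on the monotherapy subset;
#' stage 2 recomputes the Fisher p on the full dataset for the survivors
#' only. The observed statistic is the smallest stage-2 p among survivors
#' (1.0 when nothing survives stage 1).
#'
#' @inheritParams stage1_screen
#' @return object of class `screen_result`: list(stage1, stage2,
#'   observed_min_p, config) where `stage2` has snp_id, p_stage1, p_stage2.
#' @export
run_two_stage <- function(genotypes, cohort, snps, config = screen_config()) {
  s1 <- stage1_screen(genotypes, cohort, snps, config)
  setup <- .screen_setup(genotypes, cohort, snps, config)
  cache <- new.env(parent = emptyenv())
  sel <- which(s1$selected)
  if (length(sel)) {
    p2 <- .stage_p(setup, cohort$outcome, 2L, cache, subset = sel)
    stage2 <- data.frame(snp_id = snps[sel], p_stage1 = s1$p_stage1[sel],
                         p_stage2 = p2, stringsAsFactors = FALSE)
    omp <- min(p2)
  } else {
    stage2 <- data.frame(snp_id = character(), p_stage1 = numeric(),
                         p_stage2 = numeric(), stringsAsFactors = FALSE)
    omp <- 1.0
  }
  structure(list(stage1 = s1, stage2 = stage2, observed_min_p = omp,
                 config = config),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %d candidate(s), %d stage-1 survivor(s), observed min p = %.3g\n",
              nrow(x$stage1), nrow(x$stage2), x$observed_min_p))
  invisible(x)
}

#' Min-p permutation null for the two-stage screening
#'
#' Per permutation, outcome labels are shuffled uniformly at random across
#' all patients of the full (second) dataset; the monotherapy rows are then
#' re-extracted as the permuted first dataset, both screening stages are
#' replayed, and the smallest stage-2 p among stage-1 survivors is recorded
#' (1.0 when stage 1 selects nothing). Reproducible under `config$seed`.
#'
#' @inheritParams stage1_screen
#' @return object of class `permutation_null`: list(min_p, n_perm, seed).
#' @export
permutation_null <- function(genotypes, cohort, snps,
                             config = screen_config()) {
  if (!length(snps)) stop("empty candidate set")
  setup <- .screen_setup(genotypes, cohort, snps, config)
  cache <- new.env(parent = emptyenv())
  y <- cohort$outcome
  n <- length(y)
  mono <- setup$mono
  alpha1 <- config$alpha1
  minp <- numeric(config$n_perm)
  set.seed(config$seed)
  for (i in seq_len(config$n_perm)) {
    if (config$stratified) {
      yp <- y
      yp[mono] <- y[mono][sample.int(sum(mono))]
      yp[!mono] <- y[!mono][sample.int(sum(!mono))]
    } else {
      yp <- y[sample.int(n)]
    }
    p1 <- .stage_p(setup, yp[mono], 1L, cache)
    sel <- which(p1 < alpha1)
    if (!length(sel)) { minp[i] <- 1.0; next }
    p2 <- .stage_p(setup, yp, 2L, cache, subset = sel)
    minp[i] <- min(p2)
  }
  structure(list(min_p = minp, n_perm = config$n_perm, seed = config$seed),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation_null: %d min-p value(s), seed %d\n",
              x$n_perm, x$seed))
  invisible(x)
}

#' Permutation-adjusted p-value
#'
#' p_per = (number of null min-p values <= observed p) / n_perm. Plain
#' proportion, no +1 correction, so 0 is attainable and should be read as
#' "< 1/n_perm". Vectorized over `observed_p`.
#'
#' @param observed_p stage-2 p-value(s) in (0, 1].
#' @param null a [permutation_null()].
#' @return adjusted p-value(s) in \[0, 1\].
#' @export
adjusted_p <- function(observed_p, null) {
  if (!length(null$min_p)) stop("empty permutation null")
  stopifnot(all(observed_p > 0), all(observed_p <= 1))
  srt <- sort(null$min_p)
  findInterval(observed_p, srt) / null$n_perm
}

#' Write the permutation null distribution
#'
#' Single-column TSV with `#`-prefixed header metadata lines (seed, n_perm,
#' alpha1).
#'
#' @param null a [permutation_null()].
#' @param config the [screen_config()] used.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_null_distribution <- function(null, config, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seed\t%d", null$seed),
               sprintf("# n_perm\t%d", null$n_perm),
               sprintf("# alpha1\t%.17g", config$alpha1),
               "min_p",
               sprintf("%.17g", null$min_p)), con)
  invisible(path)
}
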