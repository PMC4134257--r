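# small deterministic cohort: 10 monotherapy + 10 combination patients
tiny_cohort <- function(dosage_by_snp, outcome) {
  n <- length(outcome)
  dos <- do.call(cbind, dosage_by_snp)
  dimnames(dos) <- list(sprintf("P%02d", 1:n), names(dosage_by_snp))
  list(geno = genotype_matrix(dos),
       cohort = data.frame(patient_id = sprintf("P%02d", 1:n),
                           monotherapy = rep(c(TRUE, FALSE), each = n / 2),
                           outcome = outcome))
}

test_that("stage 1 selects exactly the SNPs below alpha1", {
  # rs_sep perfectly separates the monotherapy subset; rs_null is noise
  y <- rep(c(1, 0, 1, 0), each = 5)
  tc <- tiny_cohort(list(rs_sep = rep(c(2L, 0L, 1L, 1L), each = 5),
                         rs_null = rep(c(1L, 1L, 0L, 1L), each = 5)), y)
  s1 <- stage1_screen(tc$geno, tc$cohort, c("rs_sep", "rs_null"),
                      screen_config(alpha1 = 0.005))
  expect_true(s1$selected[s1$snp_id == "rs_sep"])
  expect_false(s1$selected[s1$snp_id == "rs_null"])
  # separating allele table at n = 10 patients: p = 2/choose(20,10)
  expect_lt(s1$p_stage1[s1$snp_id == "rs_sep"], 1e-4)
  expect_error(stage1_screen(tc$geno, tc$cohort, character(0)),
               "empty candidate set")
})

test_that("observed min-p follows the stage-2 conventions", {
  y <- rep(c(1, 0, 1, 0), each = 5)
  # nothing survives stage 1 -> observed_min_p = 1
  tc <- tiny_cohort(list(rs_a = rep(c(1L, 1L, 0L, 1L), each = 5)), y)
  scr <- run_two_stage(tc$geno, tc$cohort, "rs_a", screen_config())
  expect_equal(nrow(scr$stage2), 0)
  expect_equal(scr$observed_min_p, 1.0)
  # one survivor -> its stage-2 p; two -> the smaller
  tc2 <- tiny_cohort(list(rs_sep = rep(c(2L, 0L, 2L, 0L), each = 5),
                          rs_sep2 = rep(c(2L, 0L, 1L, 1L), each = 5)), y)
  scr2 <- run_two_stage(tc2$geno, tc2$cohort, c("rs_sep", "rs_sep2"),
                        screen_config())
  expect_equal(scr2$observed_min_p, min(scr2$stage2$p_stage2))
  expect_equal(scr2$observed_min_p,
               oracle_two_stage_minp(tc2$geno, tc2$cohort,
                                     c("rs_sep", "rs_sep2"),
                                     screen_config()))
})

test_that("two-stage min-p equals a plain per-SNP re-implementation", {
  for (seed in c(31, 32, 33)) {
    x <- generate_cohort(synthetic_config(
      n_patients = 90, n_snps = 18, missing_rate = 0.02, seed = seed,
      causal_snps = data.frame(index = 3, beta = 1.4)))
    cohort <- define_endpoint(x$cohort)
    cfg <- screen_config(alpha1 = 0.1, model = "allele")
    scr <- run_two_stage(x$genotypes, cohort, x$genotypes$snp_ids, cfg)
    expect_equal(scr$observed_min_p,
                 oracle_two_stage_minp(x$genotypes, cohort,
                                       x$genotypes$snp_ids, cfg),
                 tolerance = 1e-12)
    # dominant model path too
    cfgd <- screen_config(alpha1 = 0.1, model = "dominant")
    expect_equal(run_two_stage(x$genotypes, cohort, x$genotypes$snp_ids,
                               cfgd)$observed_min_p,
                 oracle_two_stage_minp(x$genotypes, cohort,
                                       x$genotypes$snp_ids, cfgd),
                 tolerance = 1e-12)
  }
})

test_that("permutation null is reproducible and lives in (0, 1]", {
  x <- generate_cohort(synthetic_config(n_patients = 60, n_snps = 30,
                                        seed = 41))
  cohort <- define_endpoint(x$cohort)
  cfg <- screen_config(n_perm = 50, seed = 17)
  n1 <- permutation_null(x$genotypes, cohort, x$genotypes$snp_ids, cfg)
  n2 <- permutation_null(x$genotypes, cohort, x$genotypes$snp_ids, cfg)
  expect_identical(n1$min_p, n2$min_p)
  expect_length(n1$min_p, 50)
  expect_true(all(n1$min_p > 0 & n1$min_p <= 1))
  one <- permutation_null(x$genotypes, cohort, x$genotypes$snp_ids,
                          screen_config(n_perm = 1, seed = 2))
  expect_length(one$min_p, 1)
  # stratified shuffling keeps the contract
  ns <- permutation_null(x$genotypes, cohort, x$genotypes$snp_ids,
                         screen_config(n_perm = 20, seed = 5,
                                       stratified = TRUE))
  expect_true(all(ns$min_p > 0 & ns$min_p <= 1))
})

test_that("null min-p distributions from independent seeds agree (KS)", {
  x <- generate_null_cohort(synthetic_config(n_patients = 100,
                                             n_snps = 40, seed = 51))
  cohort <- define_endpoint(x$cohort)
  snps <- x$genotypes$snp_ids
  a <- permutation_null(x$genotypes, cohort, snps,
                        screen_config(n_perm = 400, seed = 1,
                                      alpha1 = 0.05))
  b <- permutation_null(x$genotypes, cohort, snps,
                        screen_config(n_perm = 400, seed = 2,
                                      alpha1 = 0.05))
  ks <- suppressWarnings(ks.test(a$min_p, b$min_p))
  expect_gt(ks$p.value, 0.01)
})

test_that("adjusted p is the plain null proportion and is monotone", {
  null <- structure(list(min_p = c(0.01, 0.02, 0.5, 1, 1), n_perm = 5L,
                         seed = 1L), class = "permutation_null")
  expect_equal(adjusted_p(0.02, null), 2 / 5)
  expect_equal(adjusted_p(0.001, null), 0)      # no +1 correction
  expect_equal(adjusted_p(1, null), 1)
  ps <- sort(runif(20))
  expect_true(all(diff(adjusted_p(ps, null)) >= 0))
  expect_error(adjusted_p(0.5, structure(list(min_p = numeric(),
                                              n_perm = 0L),
                                         class = "permutation_null")),
               "empty")
})

test_that("null distribution file round-trips through its TSV dialect", {
  x <- structure(list(min_p = c(0.25, 1, 0.125), n_perm = 3L, seed = 9L),
                 class = "permutation_null")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_null_distribution(x, screen_config(seed = 9), f)
  lines <- readLines(f)
  expect_true(any(grepl("^# seed\t9$", lines)))
  vals <- as.numeric(lines[-(1:4)])
  expect_equal(vals, x$min_p)
})
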