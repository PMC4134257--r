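test_that("contingency construction follows each genetic model", {
  d <- c(0, 1, 2, 2); y <- c(0, 0, 1, 1)
  rec <- build_contingency(d, y, "recessive")
  expect_equal(unlist(rec[c("a", "b", "c", "d")], use.names = FALSE),
               c(2, 0, 0, 2))
  dom <- build_contingency(d, y, "dominant")
  expect_equal(unlist(dom[c("a", "b", "c", "d")], use.names = FALSE),
               c(2, 1, 0, 1))
  all_ <- build_contingency(d, y, "allele")
  expect_equal(unlist(all_[c("a", "b", "c", "d")], use.names = FALSE),
               c(4, 1, 0, 3))
  # allele model counts chromosomes: 2 units per patient
  expect_equal(all_$a + all_$b + all_$c + all_$d, 2 * length(d))
  expect_error(build_contingency(numeric(0), numeric(0)), "empty")
})

test_that("two-sided Fisher matches enumeration and the base-R oracle", {
  expect_equal(fisher_exact_two_sided(c(1, 1, 1, 1)), 1.0)
  expect_equal(fisher_exact_two_sided(c(5, 0, 0, 5)), 2 / 252)
  amr <- c(2, 0, 34, 132)   # drug-by-event layout with an empty cell
  expect_equal(fisher_exact_two_sided(amr), oracle_fisher(2, 0, 34, 132),
               tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(amr),
               fisher.test(matrix(amr, 2, byrow = TRUE))$p.value,
               tolerance = 1e-9)
  # degenerate margins
  expect_equal(fisher_exact_two_sided(c(0, 0, 3, 4)), 1.0)
  set.seed(7)
  for (i in 1:40) {
    v <- as.numeric(rmultinom(1, sample(10:80, 1), runif(4, .1, 1)))
    m <- matrix(v, 2)
    expect_equal(fisher_exact_two_sided(v),
                 fisher.test(m)$p.value, tolerance = 1e-9)
    # invariance under transposition and simultaneous row+column swap
    expect_equal(fisher_exact_two_sided(v),
                 fisher_exact_two_sided(c(v[1], v[3], v[2], v[4])),
                 tolerance = 1e-12)
    expect_equal(fisher_exact_two_sided(v),
                 fisher_exact_two_sided(c(v[4], v[3], v[2], v[1])),
                 tolerance = 1e-12)
  }
})

test_that("odds ratio and Woolf interval, with Haldane correction on zeros", {
  expect_equal(odds_ratio_ci(c(10, 5, 5, 10))$odds_ratio, 4.0)
  unit <- odds_ratio_ci(c(1, 1, 1, 1))
  expect_equal(unit$odds_ratio, 1.0)
  expect_true(unit$ci95[1] < 1 && unit$ci95[2] > 1)
  hal <- odds_ratio_ci(c(2, 0, 34, 132))
  expect_equal(hal$odds_ratio, (2.5 * 132.5) / (0.5 * 34.5),
               tolerance = 1e-12)
  expect_true(hal$corrected)
  raw <- odds_ratio_ci(c(2, 0, 34, 132), haldane = FALSE)
  expect_equal(raw$odds_ratio, Inf)
  expect_false(raw$ci_defined)
  # uncorrected OR invariant under transposition
  v <- c(7, 3, 2, 9)
  expect_equal(odds_ratio_ci(v)$odds_ratio,
               odds_ratio_ci(c(v[1], v[3], v[2], v[4]))$odds_ratio)
  # Haldane-corrected OR approaches the raw OR as cells grow
  for (k in c(1, 10, 100)) {
    vz <- c(2, 1, 3, 4) * k
    expect_equal(odds_ratio_ci(vz, haldane = TRUE)$odds_ratio,
                 prod(vz[c(1, 4)]) / prod(vz[2:3]),
                 tolerance = 5 / k)
  }
})

test_that("tied-rank Spearman equals phi on binary data and handles edges", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    x <- rbinom(n, 1, runif(1, .2, .8))
    y <- rbinom(n, 1, runif(1, .2, .8))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    n11 <- sum(x & y); n00 <- sum(!x & !y)
    n10 <- sum(x & !y); n01 <- sum(!x & y)
    phi <- (n11 * n00 - n10 * n01) /
      sqrt(sum(x) * sum(!x) * sum(y) * sum(!y))
    expect_equal(spearman_tied(x, y)$rho, phi, tolerance = 1e-12)
  }
  ident <- spearman_tied(1:10, 1:10)
  expect_equal(ident$rho, 1); expect_equal(ident$p, 0)
  expect_message(cns <- spearman_tied(rep(1, 5), c(1, 2, 3, 4, 5)),
                 "constant")
  expect_true(is.na(cns$rho))
  # rho agrees with cor.test's tie-corrected estimate
  x <- c(0, 0, 1, 1, 2, 2, 0, 1); y <- c(0, 1, 0, 1, 1, 1, 0, 0)
  expect_equal(spearman_tied(x, y)$rho,
               suppressWarnings(cor.test(x, y, method = "spearman"))$estimate,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("covariate scan reports NA for constants and matches direct calls", {
  set.seed(9)
  n <- 60
  ch <- data.frame(patient_id = sprintf("P%02d", 1:n),
                   monotherapy = rep(c(TRUE, FALSE), c(20, 40)),
                   outcome = rbinom(n, 1, 0.3),
                   drug = c(rep(0L, 20), rbinom(40, 1, 0.4)),
                   lab = rnorm(n))
  first <- covariate_scan(ch, "first")
  expect_true(is.na(first$rho[first$covariate == "drug"]))
  second <- covariate_scan(ch, "second")
  direct <- spearman_tied(ch$lab, ch$outcome)
  expect_equal(second$rho[second$covariate == "lab"], direct$rho)
  expect_equal(second$p[second$covariate == "lab"], direct$p)
  expect_equal(nrow(second), 2)
})
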