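#' Build a 2x2 contingency table under a genetic model
#'
#' Cell layout follows the case-control convention: `a` = event &
#' minor-bearing unit, `b` = no event & minor-bearing unit, `c` = event &
#' major unit, `d` = no event & major unit. Under the allele model each
#' patient contributes two chromosome units and the minor-unit count per
#' patient equals the dosage; under the dominant model a patient is
#' minor-bearing iff dosage >= 1; under the recessive model iff dosage = 2.
#'
#' @param dosages non-missing per-patient minor-allele dosages (0/1/2).
#' @param outcome binary vector, 1 = event, same length.
#' @param model one of "allele", "dominant", "recessive".
#' @return object of class `contingency_2x2`: list(a, b, c, d, model).
#' @export
build_contingency <- function(dosages, outcome,
                              model = c("allele", "dominant", "recessive")) {
  model <- match.arg(model)
  if (!length(dosages)) stop("empty input")
  stopifnot(length(dosages) == length(outcome),
            !anyNA(dosages), !anyNA(outcome),
            all(dosages %in% 0:2), all(outcome %in% 0:1))
  if (model == "allele") {
    u <- dosages          # minor units per patient
    tot <- rep(2L, length(dosages))
  } else if (model == "dominant") {
    u <- as.integer(dosages >= 1L); tot <- rep(1L, length(dosages))
  } else {
    u <- as.integer(dosages == 2L); tot <- rep(1L, length(dosages))
  }
  a <- sum(u[outcome == 1L])
  b <- sum(u[outcome == 0L])
  c_ <- sum(tot[outcome == 1L]) - a
  d <- sum(tot[outcome == 0L]) - b
  structure(list(a = a, b = b, c = c_, d = d, model = model),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("2x2 table (%s model)\n          minor major\n  event   %5d %5d\n  no-evt  %5d %5d\n",
              x$model, x$a, x$c, x$b, x$d))
  invisible(x)
}

.as_abcd <- function(table) {
  if (inherits(table, "contingency_2x2"))
    return(c(table$a, table$b, table$c, table$d))
  if (is.matrix(table) && all(dim(table) == 2))
    return(c(table[1, 1], table[2, 1], table[1, 2], table[2, 2]))
  if (length(table) == 4) return(as.numeric(table))
  stop("table must be a contingency_2x2, a 2x2 matrix, or length-4 (a,b,c,d)")
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' With both margins fixed, the p-value sums the hypergeometric point
#' probabilities of all tables whose point probability does not exceed that
#' of the observed table (minimum-likelihood rule, relative tie tolerance
#' 1e-7). A degenerate margin (any row or column sum 0) gives p = 1.
#'
#' @param table a `contingency_2x2`, a 2x2 matrix, or a length-4 vector
#'   (a, b, c, d).
#' @return p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(table) {
  v <- .as_abcd(table)
  if (any(v < 0) || any(v != round(v)))
    stop("cells must be non-negative integers")
  a <- v[1]; b <- v[2]; c_ <- v[3]; d <- v[4]
  m <- a + b          # minor margin
  r <- a + c_         # event margin
  N <- a + b + c_ + d
  if (m == 0 || r == 0 || m == N || r == N) return(1.0)
  lo <- max(0, r + m - N); hi <- min(r, m)
  xs <- lo:hi
  pr <- stats::dhyper(xs, m, N - m, r)
  obs <- pr[match(a, xs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

#' Odds ratio with 95% confidence interval
#'
#' OR = a*d / (b*c). With `haldane = TRUE` (default) 0.5 is added to every
#' cell before both the OR and the CI whenever any cell is zero
#' (Haldane-Anscombe correction). The CI is the Woolf log-OR normal
#' interval exp(ln OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)). Without the
#' correction a zero cell yields OR 0 or Inf and an undefined CI.
#'
#' @param table as in [fisher_exact_two_sided()].
#' @param haldane apply the 0.5 correction on zero cells (default TRUE).
#' @return list(odds_ratio, ci95 = c(low, high), corrected, ci_defined).
#' @export
odds_ratio_ci <- function(table, haldane = TRUE) {
  v <- .as_abcd(table)
  if (any(v < 0)) stop("cells must be non-negative")
  corrected <- FALSE
  if (any(v == 0)) {
    if (haldane) { v <- v + 0.5; corrected <- TRUE }
    else {
      or <- (v[1] * v[4]) / (v[2] * v[3])  # may be 0, Inf or NaN
      return(list(odds_ratio = or, ci95 = c(NA_real_, NA_real_),
                  corrected = FALSE, ci_defined = FALSE))
    }
  }
  or <- (v[1] * v[4]) / (v[2] * v[3])
  se <- sqrt(sum(1 / v))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  list(odds_ratio = or, ci95 = ci, corrected = corrected, ci_defined = TRUE)
}

#' Association tests for one SNP under one or more genetic models
#'
#' Complete-case per SNP: patients with missing dosage are dropped.
#'
#' @param dosages per-patient dosages (may contain NA).
#' @param outcome binary vector.
#' @param models genetic models to evaluate.
#' @param snp_id optional label.
#' @return data frame: snp_id, model, a, b, c, d, p_F, odds_ratio,
#'   ci_low, ci_high, n.
#' @export
snp_association <- function(dosages, outcome,
                            models = c("allele", "dominant", "recessive"),
                            snp_id = NA_character_) {
  keep <- !is.na(dosages) & !is.na(outcome)
  dosages <- dosages[keep]; outcome <- outcome[keep]
  do.call(rbind, lapply(models, function(m) {
    tb <- build_contingency(dosages, outcome, m)
    orci <- odds_ratio_ci(tb)
    data.frame(snp_id = snp_id, model = m, a = tb$a, b = tb$b, c = tb$c,
               d = tb$d, p_F = fisher_exact_two_sided(tb),
               odds_ratio = orci$odds_ratio, ci_low = orci$ci95[1],
               ci_high = orci$ci95[2], n = length(dosages),
               stringsAsFactors = FALSE)
  }))
}

#' Spearman rank correlation with midranks for ties
#'
#' rho is the Pearson correlation of midranks (average ranks on ties); the
#' two-sided p-value uses the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom.
#' rho = +/-1 gives p = 0 by convention. Pairs with a missing value are
#' dropped first; a constant vector yields rho = NA with a message.
#'
#' @param x,y numeric or ordinal vectors of equal length.
#' @return list(rho, p, n).
#' @export
spearman_tied <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    message("constant vector: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) return(list(rho = sign(rho), p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2), n = n)
}

#' Scan covariates against the endpoint
#'
#' One tied-rank Spearman correlation per covariate against the binary
#' outcome, on the monotherapy ("first") or full ("second") dataset.
#' Covariates constant in the chosen dataset are reported NA (e.g.
#' concomitant drugs within the monotherapy subset).
#'
#' @param cohort cohort data frame with `outcome` and `monotherapy` columns
#'   (see [define_endpoint()]).
#' @param dataset `"first"` (monotherapy subset) or `"second"` (all).
#' @param covariates covariate column names; defaults to every column other
#'   than patient_id, monotherapy, outcome and `*_grade` columns.
#' @return data frame: covariate, rho, p, n.
#' @export
covariate_scan <- function(cohort, dataset = c("second", "first"),
                           covariates = NULL) {
  dataset <- match.arg(dataset)
  stopifnot("outcome" %in% names(cohort))
  if (dataset == "first") cohort <- cohort[cohort$monotherapy, , drop = FALSE]
  if (is.null(covariates)) {
    drop <- c("patient_id", "monotherapy", "outcome",
              grep("_grade$", names(cohort), value = TRUE))
    covariates <- setdiff(names(cohort), drop)
  }
  res <- lapply(covariates, function(cv) {
    x <- cohort[[cv]]
    ok <- !is.na(x) & !is.na(cohort$outcome)
    if (sum(ok) < 3 || length(unique(x[ok])) < 2 ||
        length(unique(cohort$outcome[ok])) < 2)
      return(data.frame(covariate = cv, rho = NA_real_, p = NA_real_,
                        n = sum(ok), stringsAsFactors = FALSE))
    s <- suppressMessages(spearman_tied(x, cohort$outcome))
    data.frame(covariate = cv, rho = s$rho, p = s$p, n = s$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
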