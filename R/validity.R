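#' Binomial occurrence probability of a permutation count
#'
#' Point probability of observing k successes in n Bernoulli trials with
#' success probability p_B: C(n, k) * p_B^k * (1 - p_B)^(n - k), computed
#' entirely in log space via log-gamma so that values far below the double
#' underflow threshold (e.g. 1e-241 at n = 100,000) remain exact on the
#' log10 scale. Used to judge whether a permutation repetition number is
#' large enough for the observed exceedance count.
#'
#' @param n repetition (trial) count.
#' @param k occurrence (success) count, 0 <= k <= n.
#' @param p_b per-trial probability in (0, 1).
#' @return object of class `bernoulli_check`: list(n, k, p_b,
#'   log10_probability, probability). `probability` is `exp10` of the log
#'   value and may underflow to 0; the log10 value is always finite.
#' @export
occurrence_probability <- function(n, k, p_b) {
  stopifnot(length(n) == 1, length(k) == 1, length(p_b) == 1)
  if (k < 0 || k > n) stop("require 0 <= k <= n")
  if (p_b <= 0 || p_b >= 1) stop("require 0 < p_b < 1")
  lp <- lchoose(n, k) + k * log(p_b) + (n - k) * log1p(-p_b)
  structure(list(n = n, k = k, p_b = p_b,
                 log10_probability = lp / log(10),
                 probability = exp(lp)),
            class = "bernoulli_check")
}

#' Format an occurrence probability as mantissa x 10^exponent
#'
#' @param x a `bernoulli_check`.
#' @param digits significant digits for the mantissa (default 3).
#' @return character scalar like `"4.89e-241"`.
#' @export
format_occurrence <- function(x, digits = 3) {
  e <- floor(x$log10_probability)
  m <- 10^(x$log10_probability - e)
  m <- signif(m, digits)
  if (m >= 10) { m <- m / 10; e <- e + 1 }  # rounding may carry
  sprintf("%.*ge%+d", digits, m, e)
}

#' @export
print.bernoulli_check <- function(x, ...) {
  cat(sprintf("occurrence probability: n=%d, k=%d, p=%.4g -> %s (log10 = %.4f)\n",
              x$n, x$k, x$p_b, format_occurrence(x), x$log10_probability))
  invisible(x)
}
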