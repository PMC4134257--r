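#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment for the single-stage
#' (full-dataset-only) SNP scan: after sorting ascending,
#' q_(i) = min over j >= i of min(1, p_(j) * m / j); output order matches
#' input order. Computation delegates to [stats::p.adjust()] with
#' `method = "BH"`.
#'
#' @param pvalues numeric vector of p-values in (0, 1], optionally named by
#'   SNP id.
#' @return data frame: snp_id (names or index), p, rank (min-tied rank of
#'   p), q, in input order.
#' @export
bh_qvalues <- function(pvalues) {
  if (!length(pvalues)) stop("empty p-value vector")
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  q <- stats::p.adjust(pvalues, method = "BH")
  ids <- names(pvalues)
  if (is.null(ids)) ids <- as.character(seq_along(pvalues))
  data.frame(snp_id = ids, p = as.numeric(pvalues),
             rank = rank(pvalues, ties.method = "min"),
             q = q, stringsAsFactors = FALSE)
}
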