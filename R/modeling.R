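#' Fit a binary-outcome logistic regression
#'
#' Maximum likelihood via iteratively reweighted least squares
#' ([stats::glm()] with binomial family; relative deviance tolerance 1e-10,
#' at most 100 iterations). Genotype enters additively as its 0/1/2 dosage.
#' Quasi-separation is flagged (with a warning) when any coefficient
#' exceeds 15 in absolute value on the logit scale; the achieved
#' log-likelihood is retained.
#'
#' @param design data frame (or matrix) of predictors, no intercept column;
#'   may have zero columns for the intercept-only (NULL) model.
#' @param outcome binary 0/1 vector, length nrow(design).
#' @return object of class `logistic_fit`: list(terms, coefficients,
#'   log_likelihood, n_par, converged, separation_flag, fitted, n, glm).
#' @export
fit_logistic <- function(design, outcome) {
  design <- as.data.frame(design)
  stopifnot(nrow(design) == 0L || nrow(design) == length(outcome),
            all(outcome %in% 0:1))
  n <- length(outcome)
  if (ncol(design) > 0) {
    const <- vapply(design, function(col) length(unique(col)) < 2,
                    logical(1))
    if (any(const))
      stop("constant non-intercept column(s): ",
           paste(names(design)[const], collapse = ", "))
    dat <- cbind(.y = outcome, design)
    fml <- stats::as.formula(paste(".y ~",
                                   paste(sprintf("`%s`", names(design)),
                                         collapse = " + ")))
  } else {
    dat <- data.frame(.y = outcome)
    fml <- .y ~ 1
  }
  if (n < ncol(design) + 1L) stop("fewer observations than parameters")
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; aliased column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sep <- any(abs(cf[-1]) > 15) || (!fit$converged)
  if (sep) warning("possible quasi-separation in logistic fit")
  structure(list(terms = names(design),
                 coefficients = cf,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 n_par = length(cf),
                 converged = fit$converged,
                 separation_flag = sep,
                 fitted = stats::fitted(fit),
                 n = n, glm = fit),
            class = "logistic_fit")
}

#' Akaike information criterion of a logistic fit
#'
#' AIC = -2 * log-likelihood + 2 * n_par, where n_par counts the intercept.
#' Smaller is better in model comparisons.
#'
#' @param fit a [fit_logistic()] result.
#' @return AIC value.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  -2 * fit$log_likelihood + 2 * fit$n_par
}

#' ROC curve, AUC and Youden operating point
#'
#' AUC via the rank (Mann-Whitney) formulation with ties counted 1/2. The
#' curve sweeps every distinct score as a "predict positive if score >=
#' threshold" rule; the reported operating point maximizes Youden's J
#' (sensitivity + specificity - 1), ties broken toward higher sensitivity.
#'
#' @param scores numeric risk scores (e.g. fitted probabilities).
#' @param outcome binary 0/1 vector.
#' @return object of class `roc_summary`: list(curve = data frame
#'   (threshold, sensitivity, specificity), auc, operating_point).
#' @export
roc_auc <- function(scores, outcome) {
  stopifnot(length(scores) == length(outcome), all(outcome %in% 0:1))
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(scores)  # midranks handle ties as 1/2
  auc <- (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- sort(unique(scores), decreasing = TRUE)
  sens <- spec <- numeric(length(th))
  for (i in seq_along(th)) {
    pos <- scores >= th[i]
    sens[i] <- sum(pos & outcome == 1) / n1
    spec[i] <- sum(!pos & outcome == 0) / n0
  }
  curve <- data.frame(threshold = th, sensitivity = sens,
                      specificity = spec)
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(sens[best])]
  structure(list(curve = curve, auc = auc,
                 operating_point = curve[best, , drop = FALSE]),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  op <- x$operating_point
  cat(sprintf("ROC: AUC = %.3f; Youden point: sens %.1f%%, spec %.1f%% at threshold %.3g\n",
              x$auc, 100 * op$sensitivity, 100 * op$specificity,
              op$threshold))
  invisible(x)
}

#' Compare logistic models by AIC and ROC/AUC
#'
#' Fits one logistic regression per term set (the intercept-only NULL model
#' is always included), on complete cases of the columns each model uses,
#' and tabulates AIC, in-sample AUC and the Youden operating point, sorted
#' by ascending AIC.
#'
#' @param specs list of character vectors of column names of `data`;
#'   `character(0)` denotes the NULL model.
#' @param data data frame holding predictors and the outcome column.
#' @param outcome_col name of the binary outcome column.
#' @return data frame: model, n_par, aic, auc, sensitivity, specificity,
#'   separation, n.
#' @export
compare_models <- function(specs, data, outcome_col = "outcome") {
  stopifnot(length(specs) >= 1, outcome_col %in% names(data))
  if (!any(vapply(specs, length, 1L) == 0)) specs <- c(list(character(0)), specs)
  rows <- lapply(specs, function(tm) {
    stopifnot(all(tm %in% names(data)))
    use <- stats::complete.cases(data[, c(tm, outcome_col), drop = FALSE])
    if (sum(use) < length(use))
      message(length(use) - sum(use),
              " row(s) with missing covariates dropped for model {",
              paste(tm, collapse = "+"), "}")
    d <- data[use, , drop = FALSE]
    fit <- suppressWarnings(fit_logistic(d[, tm, drop = FALSE],
                                         d[[outcome_col]]))
    if (length(tm)) {
      roc <- roc_auc(fit$fitted, d[[outcome_col]])
      auc <- roc$auc
      op <- roc$operating_point
      sens <- op$sensitivity; spec <- op$specificity
    } else {
      auc <- 0.5; sens <- NA_real_; spec <- NA_real_
    }
    data.frame(model = if (length(tm)) paste(tm, collapse = "+") else "NULL",
               n_par = fit$n_par, aic = aic(fit), auc = auc,
               sensitivity = sens, specificity = spec,
               separation = fit$separation_flag, n = fit$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$aic), , drop = FALSE]
}
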