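# The radiomics risk-score signature: Cox coefficients on the selected
# features, the linear risk score, fixed half-median cutoffs, three-group
# stratification and its evaluation.

#' Cox proportional-hazards coefficients for selected features
#'
#' Fits the (unpenalized) Cox model of survival on the given feature
#' columns by partial-likelihood maximization and returns the log-hazard
#' coefficients with their Wald p-values. With no censoring information
#' every observation is treated as an event.
#'
#' @param features Numeric table of the selected feature columns.
#' @param os_days Survival times in days.
#' @param event Event indicator per patient (default all 1).
#' @return List with `beta`, `p_values` and the underlying `fit`.
#' @export
fit_cox <- function(features, os_days, event = NULL) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (is.null(event)) event <- rep(1L, n)
  if (sum(event) < 1L) stopf("need at least one event")
  if (n <= ncol(x)) stopf("need more patients than features")
  sds <- apply(x, 2L, pop_sd)
  if (any(sds == 0))
    stopf("zero-variance covariate(s): %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  df <- data.frame(x, check.names = FALSE)
  df$.os <- os_days
  df$.event <- event
  fml <- stats::as.formula(paste(
    "survival::Surv(.os, .event) ~",
    paste(sprintf("`%s`", colnames(x)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df)
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info)))
    stopf("Cox fit did not converge")
  if (any(!is.finite(stats::coef(fit))))
    stopf("Cox fit did not converge: non-finite coefficients")
  sm <- summary(fit)
  structure(list(beta = stats::setNames(stats::coef(fit), colnames(x)),
                 p_values = stats::setNames(sm$coefficients[, "Pr(>|z|)"],
                                            colnames(x)),
                 fit = fit),
            class = "cox_coefficients")
}

#' Linear radiomics risk score
#'
#' The signature score of a patient is the dot product of the selected
#' feature values with their Cox log-hazard coefficients:
#' `score = sum_i beta_i * feature_i`.
#'
#' @param features Named numeric vector, or a matrix / data frame with
#'   named columns (one row per patient).
#' @param beta Named coefficient vector.
#' @return Numeric score(s).
#' @export
risk_score <- function(features, beta) {
  if (is.null(names(beta))) stopf("beta must be named")
  if (is.matrix(features) || is.data.frame(features)) {
    miss <- setdiff(names(beta), colnames(features))
    if (length(miss))
      stopf("missing feature(s): %s", paste(miss, collapse = ", "))
    m <- as.matrix(features[, names(beta), drop = FALSE])
    if (any(!is.finite(m))) stopf("non-finite feature value(s)")
    return(drop(m %*% beta))
  }
  miss <- setdiff(names(beta), names(features))
  if (length(miss))
    stopf("missing feature(s): %s", paste(miss, collapse = ", "))
  v <- features[names(beta)]
  if (any(!is.finite(v))) stopf("non-finite feature value(s)")
  sum(v * beta)
}

#' Half-median risk-score cutoffs
#'
#' The fixed stratification thresholds are derived from the discovery-set
#' per-group score medians: the high cutoff is half the short-survivor
#' (high-risk) group median and the low cutoff half the long-survivor
#' (low-risk) group median -- the "25th percentile approximated as the half
#' median" rule.
#'
#' @param short_median Median score of the short-survivor group.
#' @param long_median Median score of the long-survivor group.
#' @return Named vector `c(low, high)`.
#' @export
cutoffs_from_medians <- function(short_median, long_median) {
  low <- long_median / 2
  high <- short_median / 2
  if (!(low < high))
    stopf("inverted cutoffs: half-medians give low (%.4g) >= high (%.4g)",
          low, high)
  c(low = low, high = high)
}

#' Derive cutoffs from scores and true survival classes
#'
#' Computes the per-group score medians and applies
#' [cutoffs_from_medians()]. All three survival classes must be present.
#'
#' @param scores Numeric risk scores.
#' @param true_class Factor/character of `SHORT`, `MEDIUM`, `LONG`.
#' @return Named vector `c(low, high)`.
#' @export
derive_cutoffs <- function(scores, true_class) {
  true_class <- factor(as.character(true_class), levels = SURVIVAL_LEVELS)
  if (any(is.na(true_class))) stopf("unknown survival class value")
  if (!all(SURVIVAL_LEVELS %in% true_class))
    stopf("all three survival classes must be present")
  med <- tapply(scores, true_class, stats::median)
  cutoffs_from_medians(short_median = med[["SHORT"]],
                       long_median = med[["LONG"]])
}

#' Stratify risk scores into risk groups and predicted survival classes
#'
#' Scores strictly above the high cutoff are high-risk (predicted
#' short-survivor), scores strictly below the low cutoff low-risk
#' (predicted long-survivor); everything else -- including scores exactly
#' equal to a cutoff -- is medium-risk (predicted medium-survivor).
#'
#' @param scores Numeric risk scores (finite).
#' @param low,high Cutoffs with `low < high`.
#' @return Data frame with `score`, `risk_group` (`LOW`/`MEDIUM`/`HIGH`)
#'   and `predicted_class` (`LONG`/`MEDIUM`/`SHORT`).
#' @export
stratify_scores <- function(scores, low, high) {
  if (any(!is.finite(scores))) stopf("non-finite risk score")
  if (!(low < high)) stopf("cutoffs must satisfy low < high")
  risk <- ifelse(scores > high, "HIGH", ifelse(scores < low, "LOW", "MEDIUM"))
  risk <- factor(risk, levels = c("LOW", "MEDIUM", "HIGH"))
  pred <- c(LOW = "LONG", MEDIUM = "MEDIUM", HIGH = "SHORT")[as.character(risk)]
  data.frame(score = scores, risk_group = risk,
             predicted_class = factor(pred, levels = SURVIVAL_LEVELS))
}

#' Per-class confusion statistics
#'
#' The 3 x 3 confusion matrix (rows: true class, columns: predicted class)
#' with per-class sensitivity (`TP / true count`) and false-positive rate
#' (`FP / true non-class count`). A class absent from the truth has
#' undefined (`NA`) sensitivity.
#'
#' @param predicted_class,true_class Vectors over
#'   `SHORT`/`MEDIUM`/`LONG`.
#' @return Object of class `confusion_stats` with elements `counts`,
#'   `sensitivity` and `fpr`.
#' @export
confusion_stats <- function(predicted_class, true_class) {
  pred <- factor(as.character(predicted_class), levels = SURVIVAL_LEVELS)
  truth <- factor(as.character(true_class), levels = SURVIVAL_LEVELS)
  if (length(pred) != length(truth)) stopf("length mismatch")
  if (any(is.na(pred)) || any(is.na(truth))) stopf("unknown class value")
  counts <- table(true = truth, predicted = pred)
  tp <- diag(counts)
  true_n <- rowSums(counts)
  fp <- colSums(counts) - tp
  structure(list(counts = counts,
                 sensitivity = ifelse(true_n > 0, tp / true_n, NA_real_),
                 fpr = ifelse(sum(true_n) - true_n > 0,
                              fp / (sum(true_n) - true_n), NA_real_)),
            class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  print(x$counts)
  cat("sensitivity:", sprintf("%s=%.3f", names(x$sensitivity), x$sensitivity),
      "\nfpr:        ", sprintf("%s=%.3f", names(x$fpr), x$fpr), "\n")
  invisible(x)
}

#' Survival association of the risk stratification
#'
#' Welch two-sample t-test of survival time between the predicted
#' high-risk and low-risk strata (two-sided).
#'
#' @param os_days Survival times.
#' @param risk_group Factor from [stratify_scores()].
#' @return The `htest` object; its `p.value` is the two-sided p.
#' @export
association_test <- function(os_days, risk_group) {
  hi <- os_days[risk_group == "HIGH"]
  lo <- os_days[risk_group == "LOW"]
  if (length(hi) < 2L || length(lo) < 2L)
    stopf("need at least 2 patients in each of the HIGH and LOW strata")
  stats::t.test(hi, lo)
}

#' Z-score standardization of selected feature columns
#'
#' Rescales each column to mean 0 and standard deviation 1 (population
#' denominator), e.g. for the selected-feature heat map.
#'
#' @param features Numeric table.
#' @return Matrix of z-scores.
#' @export
zscore_matrix <- function(features) {
  x <- as.matrix(features)
  sds <- apply(x, 2L, pop_sd)
  if (any(sds == 0))
    stopf("zero-SD column(s): %s", paste(colnames(x)[sds == 0], collapse = ", "))
  scale(x, center = colMeans(x), scale = sds)[, , drop = FALSE]
}

#' Fit a radiomics survival signature
#'
#' The central model-fitting routine: starting from a cohort feature table
#' and survival times it (1) drops zero-MAD features, (2) selects an
#' informative subset by cross-validated LASSO ([lasso_select()]),
#' (3) obtains unpenalized Cox log-hazard coefficients for the selected
#' features ([fit_cox()]), (4) computes each patient's linear risk score,
#' and (5) freezes the half-median stratification cutoffs from the
#' per-survival-group score medians. The returned object predicts risk
#' groups and survival classes for new patients with the frozen cutoffs.
#'
#' @param features Feature table (data frame; an optional `patient_id`
#'   column is ignored for fitting).
#' @param os_days Survival times in days, one per row.
#' @param event Optional event indicator (default: fully observed).
#' @param folds LASSO cross-validation folds.
#' @param seed Seed for the cross-validation fold assignment.
#' @param family LASSO selection family, see [lasso_select()].
#' @param month_days Days per month for the survival grouping.
#' @return An object of class `radiomics_signature`.
#' @export
radiomics_signature <- function(features, os_days, event = NULL,
                                folds = 10L, seed = 1L,
                                family = c("gaussian", "cox"),
                                month_days = MONTH_DAYS) {
  family <- match.arg(family)
  cl <- match.call()
  if (is.data.frame(features) && "patient_id" %in% names(features))
    features <- features[, setdiff(names(features), "patient_id"),
                         drop = FALSE]
  filtered <- mad_filter(features)
  selection <- lasso_select(filtered, os_days, folds = folds, seed = seed,
                            family = family)
  if (!length(selection$kept_features))
    stopf(paste("LASSO selected no features at the optimal penalty;",
                "no signature can be formed"))
  sel <- as.data.frame(filtered)[, selection$kept_features, drop = FALSE]
  cox <- fit_cox(sel, os_days, event)
  scores <- risk_score(sel, cox$beta)
  classes <- survival_class(os_days, month_days)
  cutoffs <- derive_cutoffs(scores, classes)
  structure(list(call = cl,
                 feature_names = selection$kept_features,
                 beta = cox$beta,
                 p_values = cox$p_values,
                 low_cutoff = cutoffs[["low"]],
                 high_cutoff = cutoffs[["high"]],
                 selection = selection,
                 mad_removed = attr(filtered, "removed"),
                 scores = scores,
                 classes = classes,
                 os_days = os_days,
                 month_days = month_days),
            class = "radiomics_signature")
}

#' @export
print.radiomics_signature <- function(x, digits = 4L, ...) {
  cat("Radiomics survival signature\n")
  cat(sprintf("  %d feature(s) selected (lambda_opt = %.4g)\n",
              length(x$feature_names), x$selection$lambda_opt))
  cat(sprintf("  cutoffs: low %.4g, high %.4g\n", x$low_cutoff, x$high_cutoff))
  cat("  coefficients (log hazard):\n")
  print(round(x$beta, digits))
  invisible(x)
}

#' @export
coef.radiomics_signature <- function(object, ...) object$beta

#' @export
summary.radiomics_signature <- function(object, ...) {
  strat <- stratify_scores(object$scores, object$low_cutoff,
                           object$high_cutoff)
  cs <- confusion_stats(strat$predicted_class, object$classes)
  tt <- tryCatch(association_test(object$os_days, strat$risk_group),
                 error = function(e) NULL)
  structure(list(signature = object,
                 coefficients = data.frame(
                   feature = object$feature_names,
                   beta = unname(object$beta),
                   p_value = unname(object$p_values)),
                 confusion = cs,
                 t_test_p = if (is.null(tt)) NA_real_ else tt$p.value),
            class = "summary.radiomics_signature")
}

#' @export
print.summary.radiomics_signature <- function(x, ...) {
  print(x$signature)
  cat("\nTraining-set stratification:\n")
  print(x$confusion)
  if (is.finite(x$t_test_p))
    cat(sprintf("HIGH vs LOW survival t-test: p = %.3g\n", x$t_test_p))
  invisible(x)
}

#' Predict risk scores and survival classes for new patients
#'
#' @param object A fitted [radiomics_signature()].
#' @param newdata Feature table containing the signature's features.
#' @param ... Unused.
#' @return Data frame with `score`, `risk_group` and `predicted_class`.
#' @export
predict.radiomics_signature <- function(object, newdata, ...) {
  scores <- risk_score(newdata, object$beta)
  stratify_scores(scores, object$low_cutoff, object$high_cutoff)
}

#' Residuals of the underlying Cox fit
#'
#' @param object A fitted [radiomics_signature()].
#' @param type Residual type passed to the Cox model (default martingale).
#' @param ... Unused.
#' @export
residuals.radiomics_signature <- function(object, type = "martingale", ...) {
  ev <- rep(1L, length(object$os_days))
  fit <- survival::coxph(survival::Surv(object$os_days, ev) ~ object$scores)
  stats::residuals(fit, type = type)
}

#' Plot the training-set risk scores with the frozen cutoffs
#'
#' @param x A fitted [radiomics_signature()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.radiomics_signature <- function(x, ...) {
  ord <- order(x$scores)
  cols <- c(SHORT = "#d95f02", MEDIUM = "#7570b3", LONG = "#1b9e77")
  graphics::plot(seq_along(x$scores), x$scores[ord],
                 col = cols[as.character(x$classes[ord])], pch = 19,
                 xlab = "patient (ranked by score)",
                 ylab = "radiomics risk score", ...)
  graphics::abline(h = c(x$low_cutoff, x$high_cutoff), lty = 2)
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(x)
}

#' Serialize a signature as JSON
#'
#' @param signature A fitted [radiomics_signature()].
#' @param path Output path.
#' @export
write_signature <- function(signature, path) {
  jsonlite::write_json(
    list(feature_names = signature$feature_names,
         beta = as.list(signature$beta),
         p_values = as.list(signature$p_values),
         low_cutoff = signature$low_cutoff,
         high_cutoff = signature$high_cutoff),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
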