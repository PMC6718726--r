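# Feature selection: MAD filter then cross-validated LASSO.

#' Remove zero-MAD (uninformative) feature columns
#'
#' Drops every feature column whose median absolute deviation -- the median
#' of `|x - median(x)|` -- equals zero. Such columns are constant for at
#' least half the cohort and carry no ranking information. All other
#' columns pass through untouched; removed names are recorded in the
#' `removed` attribute.
#'
#' @param features Data frame or matrix of numeric feature columns (a
#'   `patient_id` column, if present, is carried through unfiltered).
#' @return The filtered table with attribute `removed`.
#' @export
mad_filter <- function(features) {
  id <- NULL
  if (is.data.frame(features) && "patient_id" %in% names(features)) {
    id <- features[["patient_id"]]
    features <- features[, setdiff(names(features), "patient_id"),
                         drop = FALSE]
  }
  if (!ncol(features)) stopf("empty feature table")
  mads <- vapply(seq_len(ncol(features)), function(j) {
    x <- features[[j]]
    stats::median(abs(x - stats::median(x)))
  }, 0)
  drop_cols <- mads == 0
  if (all(drop_cols)) stopf("all feature columns have zero MAD")
  out <- features[, !drop_cols, drop = FALSE]
  if (!is.null(id)) out <- data.frame(patient_id = id, out,
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE)
  structure(out, removed = colnames(features)[drop_cols])
}

#' LASSO feature selection with cross-validated penalty
#'
#' Fits the L1-penalized Gaussian linear model of survival time on the
#' (internally standardized) features over a 100-point log-spaced penalty
#' grid running from the smallest penalty that empties the model down to
#' 0.001 of it, chooses the penalty by k-fold cross-validated deviance
#' (fold assignment stratified by survival class and drawn from `seed`),
#' and returns the features with non-zero coefficients at the
#' deviance-minimizing penalty. Coefficients are reported on the original
#' feature scale.
#'
#' @param features Numeric feature table (data frame or matrix).
#' @param os_days Survival outcome, one value per row.
#' @param folds Number of cross-validation folds (default 10).
#' @param seed RNG seed controlling the fold assignment.
#' @param family Model family: `"gaussian"` (linear model on survival
#'   time, the default) or `"cox"` (penalized partial likelihood; requires
#'   fully observed survival).
#' @param lambda_min_ratio Ratio of the smallest to the largest grid
#'   penalty.
#' @param nlambda Number of grid penalties.
#' @return An object of class `lasso_selection`: `kept_features`,
#'   `lambda_path`, `cv_deviance` (mean and SE per penalty), `lambda_opt`,
#'   `lambda_1se` and `coefficients_at_opt`.
#' @export
lasso_select <- function(features, os_days, folds = 10L, seed = 1L,
                         family = c("gaussian", "cox"),
                         lambda_min_ratio = 0.001, nlambda = 100L) {
  family <- match.arg(family)
  x <- as.matrix(features)
  if (!is.numeric(x)) stopf("feature table must be numeric")
  n <- nrow(x)
  if (length(os_days) != n) stopf("outcome length does not match the table")
  if (pop_sd(os_days) == 0) stopf("constant outcome")
  if (folds < 2L || folds > n) stopf("folds must be in [2, n]")
  y <- if (family == "cox")
    survival::Surv(os_days, rep(1L, n)) else os_days
  foldid <- make_folds(survival_class(os_days), folds, seed = seed)
  base <- glmnet::glmnet(x, y, family = family, standardize = TRUE,
                         nlambda = nlambda,
                         lambda.min.ratio = lambda_min_ratio)
  cv <- with_seed(seed,
    glmnet::cv.glmnet(x, y, family = family, standardize = TRUE,
                      lambda = base$lambda, foldid = foldid,
                      type.measure = "deviance"))
  cf <- stats::coef(cv, s = "lambda.min")
  cf <- if (family == "cox") as.matrix(cf) else as.matrix(cf)[-1L, , drop = FALSE]
  keep <- rownames(cf)[cf[, 1L] != 0]
  structure(list(kept_features = keep,
                 lambda_path = cv$lambda,
                 cv_deviance = data.frame(lambda = cv$lambda, mean = cv$cvm,
                                          se = cv$cvsd),
                 lambda_opt = cv$lambda.min,
                 lambda_1se = cv$lambda.1se,
                 coefficients_at_opt = stats::setNames(cf[cf[, 1L] != 0, 1L],
                                                       keep),
                 family = family, folds = folds, seed = seed),
            class = "lasso_selection")
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat(sprintf(
    "<lasso_selection> %s family, %d-fold CV\n  lambda_opt = %.4g, lambda_1se = %.4g\n  kept %d feature(s)%s\n",
    x$family, x$folds, x$lambda_opt, x$lambda_1se, length(x$kept_features),
    if (length(x$kept_features))
      paste0(": ", paste(utils::head(x$kept_features, 5L), collapse = ", "),
             if (length(x$kept_features) > 5L) ", ...") else ""))
  invisible(x)
}

#' Write a selection report as JSON
#'
#' @param selection A [lasso_select()] result.
#' @param path Output path.
#' @export
write_selection <- function(selection, path) {
  jsonlite::write_json(
    list(kept_features = selection$kept_features,
         lambda_opt = selection$lambda_opt,
         lambda_1se = selection$lambda_1se,
         lambda_path = selection$lambda_path,
         cv_deviance = selection$cv_deviance,
         coefficients_at_opt = as.list(selection$coefficients_at_opt)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
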