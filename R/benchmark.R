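# Multiclass survival-group classifier benchmark: eight classifier
# configurations x four feature sets, 5-fold cross-validated, reporting
# one-vs-rest AUC per class and overall accuracy.

CLASSIFIER_FAMILIES <- c("SVM_LINEAR", "SVM_GAUSS_MEDIUM", "SVM_GAUSS_COARSE",
                         "KNN_COARSE", "KNN_COSINE", "KNN_MEDIUM", "LDA",
                         "ENSEMBLE_SUBSPACE_DISCRIMINANT")

#' One-hot encode clinical factors
#'
#' Age passes through numerically; resection status becomes a three-column
#' indicator over `GTR`, `STR`, `MISSING` (missingness is an explicit
#' category, not an absent value).
#'
#' @param clinical Data frame with `age_years` and `resection_status`.
#' @return Numeric matrix with columns `age_years`, `resection_GTR`,
#'   `resection_STR`, `resection_MISSING`.
#' @export
encode_clinical <- function(clinical) {
  status <- as.character(clinical$resection_status)
  bad <- setdiff(unique(status), RESECTION_LEVELS)
  if (length(bad))
    stopf("unknown resection status: %s", paste(bad, collapse = ", "))
  onehot <- vapply(RESECTION_LEVELS, function(l) as.numeric(status == l),
                   numeric(nrow(clinical)))
  cbind(age_years = clinical$age_years,
        matrix(onehot, nrow(clinical),
               dimnames = list(NULL, paste0("resection_", RESECTION_LEVELS))))
}

# ---- classifier backends ----------------------------------------------
# Each trainer returns an object whose `scores(newx)` gives an n x 3 matrix
# of per-class scores (larger = more likely), columns in SURVIVAL_LEVELS
# order.

# Aggregate e1071's one-vs-one decision values into per-class scores:
# pairwise vote counts, with the summed signed margins squashed into (0, 1)
# as a tie-break so the scores stay continuous for ranking AUCs. (Summing
# raw margins alone is not robust: a pair not involving a sample's class
# can contribute an arbitrarily large irrelevant margin.)
svm_class_scores <- function(fit, newx, levels) {
  pr <- stats::predict(fit, newx, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  votes <- matrix(0, nrow(newx), length(levels),
                  dimnames = list(NULL, levels))
  margin <- votes
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1L]]
    win1 <- dv[, cn] > 0
    votes[, pair[1L]] <- votes[, pair[1L]] + win1
    votes[, pair[2L]] <- votes[, pair[2L]] + !win1
    margin[, pair[1L]] <- margin[, pair[1L]] + dv[, cn]
    margin[, pair[2L]] <- margin[, pair[2L]] - dv[, cn]
  }
  votes + stats::plogis(margin)
}

train_svm <- function(x, y, gamma = NULL, kernel) {
  levels <- levels(y)
  fit <- if (kernel == "linear")
    e1071::svm(x, y, kernel = "linear", cost = 1, scale = FALSE)
  else
    e1071::svm(x, y, kernel = "radial", gamma = gamma, cost = 1,
               scale = FALSE)
  list(scores = function(newx) svm_class_scores(fit, newx, levels))
}

# k-nearest-neighbor class scores as neighbor vote fractions; distance is
# euclidean or cosine. Ties in distance resolve by stable order.
train_knn <- function(x, y, k, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  levels <- levels(y)
  k <- min(k, nrow(x))
  unit <- function(m) {
    nrm <- sqrt(rowSums(m^2))
    m / pmax(nrm, .Machine$double.eps)
  }
  xs <- if (metric == "cosine") unit(x) else x
  list(scores = function(newx) {
    ns <- if (metric == "cosine") unit(newx) else newx
    d <- if (metric == "cosine") 1 - tcrossprod(ns, xs)
    else {
      # squared euclidean via the expansion ||a-b||^2 = ||a||^2+||b||^2-2ab
      outer(rowSums(ns^2), rep(1, nrow(xs))) +
        outer(rep(1, nrow(ns)), rowSums(xs^2)) - 2 * tcrossprod(ns, xs)
    }
    sc <- t(apply(d, 1L, function(row) {
      nb <- y[order(row)[seq_len(k)]]
      tabulate(nb, nbins = length(levels)) / k
    }))
    if (nrow(d) == 1L) sc <- matrix(sc, 1L)
    colnames(sc) <- levels
    sc
  })
}

train_lda <- function(x, y) {
  keep <- apply(x, 2L, function(col) stats::sd(col) > 0)
  # collinearity is expected when p >= n (e.g. the 147-feature configs);
  # lda handles it via its generalized inverse, so the warning is noise here
  fit <- suppressWarnings(MASS::lda(x[, keep, drop = FALSE], grouping = y))
  levels <- levels(y)
  list(scores = function(newx) {
    post <- stats::predict(fit, newx[, keep, drop = FALSE])$posterior
    out <- matrix(0, nrow(newx), length(levels),
                  dimnames = list(NULL, levels))
    out[, colnames(post)] <- post
    out
  })
}

# Random-subspace ensemble of linear discriminant learners: `n_learners`
# LDA fits, each on a random feature subspace of dimension ceil(P/2);
# class scores are averaged posteriors. Learners whose subspace is
# degenerate (e.g. all-constant within a class) are skipped.
train_subspace_discriminant <- function(x, y, n_learners = 200L,
                                        seed = 1L) {
  p <- ncol(x)
  dim_sub <- max(1L, ceiling(p / 2))
  levels <- levels(y)
  subspaces <- with_seed(seed, lapply(seq_len(n_learners), function(b)
    sort(sample.int(p, dim_sub))))
  fits <- lapply(subspaces, function(js) {
    xs <- x[, js, drop = FALSE]
    keep <- apply(xs, 2L, function(col) stats::sd(col) > 0)
    if (!any(keep)) return(NULL)
    tryCatch(suppressWarnings(
      list(fit = MASS::lda(xs[, keep, drop = FALSE], grouping = y),
           cols = js[keep])),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stopf("no valid subspace discriminant learner")
  list(scores = function(newx) {
    acc <- matrix(0, nrow(newx), length(levels),
                  dimnames = list(NULL, levels))
    for (f in fits) {
      post <- stats::predict(f$fit, newx[, f$cols, drop = FALSE])$posterior
      acc[, colnames(post)] <- acc[, colnames(post)] + post
    }
    acc / length(fits)
  })
}

# Train one family on standardized features.
train_classifier <- function(family, x, y, seed = 1L) {
  p <- ncol(x)
  switch(family,
    SVM_LINEAR = train_svm(x, y, kernel = "linear"),
    # MATLAB-style kernel scale s: K = exp(-||u-v||^2 / s^2) => gamma = 1/s^2
    SVM_GAUSS_MEDIUM = train_svm(x, y, gamma = 1 / p, kernel = "radial"),
    SVM_GAUSS_COARSE = train_svm(x, y, gamma = 1 / (16 * p),
                                 kernel = "radial"),
    KNN_COARSE = train_knn(x, y, k = 100L, metric = "euclidean"),
    KNN_COSINE = train_knn(x, y, k = 10L, metric = "cosine"),
    KNN_MEDIUM = train_knn(x, y, k = 10L, metric = "euclidean"),
    LDA = train_lda(x, y),
    ENSEMBLE_SUBSPACE_DISCRIMINANT =
      train_subspace_discriminant(x, y, seed = seed),
    stopf("unknown classifier family '%s'", family))
}

#' One-vs-rest ranking AUC per class
#'
#' For every class with at least one positive and one negative, the
#' probability that a random positive outranks a random negative under the
#' class's score column, ties counting one half (mid-rank formula).
#' Degenerate classes yield `NA`.
#'
#' @param scores Numeric matrix of per-class scores, columns named by
#'   class.
#' @param labels True class per row.
#' @return Named numeric vector of AUCs.
#' @export
ovr_auc <- function(scores, labels) {
  labels <- factor(as.character(labels), levels = colnames(scores))
  vapply(colnames(scores), function(cls) {
    pos <- labels == cls
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(scores[, cls])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, 0)
}

# Center/scale by training statistics; zero-spread columns get scale 1.
fold_scaler <- function(xtr) {
  mu <- colMeans(xtr)
  sd <- apply(xtr, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  function(m) scale(m, center = mu, scale = sd)[, , drop = FALSE]
}

#' Cross-validate one classifier configuration
#'
#' Stratified k-fold cross-validation with all preprocessing inside the
#' training folds: features are standardized by each training fold's
#' statistics only, the classifier is trained on the fold's training part,
#' and out-of-fold class scores are pooled over folds for the one-vs-rest
#' AUCs and the overall accuracy. No patient is ever scored by a model
#' trained on a fold containing it. If a class has fewer members than
#' folds, a warning is issued and plain (non-stratified) folds are used.
#'
#' @param features Numeric feature table.
#' @param labels Survival class per row (`SHORT`/`MEDIUM`/`LONG`).
#' @param family One of `SVM_LINEAR`, `SVM_GAUSS_MEDIUM`,
#'   `SVM_GAUSS_COARSE`, `KNN_COARSE`, `KNN_COSINE`, `KNN_MEDIUM`, `LDA`,
#'   `ENSEMBLE_SUBSPACE_DISCRIMINANT`.
#' @param folds Number of folds (default 5).
#' @param seed Seed for fold assignment and any learner randomness.
#' @param foldid Optional externally shared fold assignment.
#' @return Object of class `cv_report`: `classifier`, `auc` (per class),
#'   `overall_accuracy`, `fold_assignments`, `pooled_scores`.
#' @export
cross_validate <- function(features, labels, family, folds = 5L, seed = 1L,
                           foldid = NULL) {
  family <- match.arg(family, CLASSIFIER_FAMILIES)
  x <- as.matrix(features)
  y <- factor(as.character(labels), levels = SURVIVAL_LEVELS)
  y <- droplevels(y)
  if (nlevels(y) < 2L) stopf("need at least 2 classes")
  n <- nrow(x)
  if (n < folds) stopf("fewer observations than folds")
  if (is.null(foldid)) {
    if (min(table(y)) < folds) {
      warning("a class has fewer members than folds; using non-stratified folds")
      foldid <- make_folds(rep(1L, n), folds, seed = seed)
    } else foldid <- make_folds(y, folds, seed = seed)
  }
  scores <- matrix(NA_real_, n, nlevels(y),
                   dimnames = list(NULL, levels(y)))
  for (f in sort(unique(foldid))) {
    tr <- foldid != f
    scaler <- fold_scaler(x[tr, , drop = FALSE])
    model <- train_classifier(family, scaler(x[tr, , drop = FALSE]),
                              droplevels(y[tr]), seed = seed + f)
    sc <- model$scores(scaler(x[!tr, , drop = FALSE]))
    scores[!tr, colnames(sc)] <- sc
    scores[!tr, setdiff(colnames(scores), colnames(sc))] <- -Inf
  }
  pred <- factor(colnames(scores)[max.col(scores, ties.method = "first")],
                 levels = levels(y))
  auc <- ovr_auc(scores, y)
  structure(list(classifier = family,
                 auc = auc,
                 overall_accuracy = mean(pred == y),
                 fold_assignments = foldid,
                 pooled_scores = scores,
                 predicted = pred),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s  accuracy %.3f  AUC %s\n", x$classifier,
              x$overall_accuracy,
              paste(sprintf("%s=%.3f", names(x$auc), x$auc), collapse = " ")))
  invisible(x)
}

#' Run the full classifier benchmark
#'
#' Evaluates all eight classifier families over the four feature
#' configurations -- all radiomics features, all + clinical, the LASSO
#' selected subset, and LASSO + clinical -- with one shared stratified
#' 5-fold assignment per configuration, and reports per-class AUC and
#' overall accuracy ranked by accuracy.
#'
#' @param features Cohort feature table (the full catalogue).
#' @param clinical Clinical table (for [encode_clinical()]).
#' @param labels Survival class per patient.
#' @param selection A [lasso_select()] result naming the kept features;
#'   required for the LASSO configurations.
#' @param folds Number of folds.
#' @param seed Seed; fold assignments and learner randomness derive from it.
#' @param families Classifier families to run (default all eight).
#' @return Data frame with one row per classifier x configuration, ranked
#'   by overall accuracy.
#' @export
run_benchmark <- function(features, clinical, labels, selection = NULL,
                          folds = 5L, seed = 1L,
                          families = CLASSIFIER_FAMILIES) {
  if (is.data.frame(features) && "patient_id" %in% names(features))
    features <- features[, setdiff(names(features), "patient_id"),
                         drop = FALSE]
  x_all <- as.matrix(features)
  clin <- encode_clinical(clinical)
  configs <- list(ALL = x_all, `ALL+CLINICAL` = cbind(x_all, clin))
  if (!is.null(selection)) {
    kept <- selection$kept_features
    miss <- setdiff(kept, colnames(x_all))
    if (length(miss))
      stopf("selected feature(s) absent from the table: %s",
            paste(miss, collapse = ", "))
    x_sel <- x_all[, kept, drop = FALSE]
    configs$LASSO <- x_sel
    configs$`LASSO+CLINICAL` <- cbind(x_sel, clin)
  } else if (!is.null(families)) {
    # LASSO configurations require a selection result
    configs <- configs[c("ALL", "ALL+CLINICAL")]
  }
  y <- factor(as.character(labels), levels = SURVIVAL_LEVELS)
  rows <- list()
  for (ci in seq_along(configs)) {
    cfg <- names(configs)[ci]
    foldid <- if (min(table(y)) >= folds)
      make_folds(y, folds, seed = seed + ci)
    else make_folds(rep(1L, length(y)), folds, seed = seed + ci)
    for (family in families) {
      rep_ <- cross_validate(configs[[cfg]], y, family, folds = folds,
                             seed = seed + ci, foldid = foldid)
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = family, feature_config = cfg,
        auc_short = rep_$auc[["SHORT"]],
        auc_medium = rep_$auc[["MEDIUM"]],
        auc_long = rep_$auc[["LONG"]],
        overall_accuracy = rep_$overall_accuracy,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(-out$overall_accuracy), , drop = FALSE]
}
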