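sep_clusters <- function(n_per = 50, sep = 10, p = 4, seed = 1) {
  set.seed(seed)
  centers <- rbind(rep(0, p), c(rep(sep, p %/% 2), rep(0, p - p %/% 2)),
                   rep(-sep, p))
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n_per * p), n_per, p), 2, centers[k, ], `+`)))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x,
       y = factor(rep(c("SHORT", "MEDIUM", "LONG"), each = n_per),
                  levels = c("SHORT", "MEDIUM", "LONG")))
}

test_that("clinical encoding one-hots resection and passes age through", {
  clin <- data.frame(age_years = c(61.17, 70),
                     resection_status = c("GTR", "MISSING"))
  enc <- encode_clinical(clin)
  expect_identical(colnames(enc),
                   c("age_years", "resection_GTR", "resection_STR",
                     "resection_MISSING"))
  expect_equal(unname(enc[1, ]), c(61.17, 1, 0, 0))
  expect_equal(unname(enc[2, ]), c(70, 0, 0, 1))
  clin$resection_status[1] <- "PARTIAL"
  expect_error(encode_clinical(clin), "unknown resection")
})

test_that("one-vs-rest AUC matches pair enumeration and pROC", {
  sc <- cbind(A = c(0.9, 0.8, 0.3, 0.2), B = c(0.1, 0.2, 0.7, 0.8))
  labels <- c("A", "B", "A", "B")
  auc <- ovr_auc(sc, labels)
  expect_equal(unname(auc["A"]), 0.75)    # 3 of 4 pairs concordant
  perfect <- ovr_auc(cbind(A = c(3, 2, 1, 0), B = c(0, 1, 2, 3)),
                     c("A", "A", "B", "B"))
  expect_equal(unname(perfect), c(1, 1))
  reversed <- ovr_auc(cbind(A = c(0, 1, 2, 3), B = c(3, 2, 1, 0)),
                      c("A", "A", "B", "B"))
  expect_equal(unname(reversed), c(0, 0))
  skip_if_not_installed("pROC")
  set.seed(5)
  s <- rnorm(40)
  lab <- sample(c("A", "B"), 40, replace = TRUE)
  ours <- ovr_auc(cbind(A = s, B = -s), lab)[["A"]]
  ref <- as.numeric(pROC::auc(pROC::roc(lab == "A", s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("cross-validation folds are balanced and out-of-fold only", {
  d <- sep_clusters(n_per = 10, p = 3, seed = 2)
  # n = 30, folds = 5: every fold has exactly 6 patients
  rep5 <- cross_validate(d$x, d$y, "LDA", folds = 5, seed = 3)
  expect_identical(as.integer(table(rep5$fold_assignments)), rep(6L, 5))
  expect_false(anyNA(rep5$pooled_scores))
  # n = 10, folds = 5 -> folds of exactly 2
  idx <- c(1:4, 11:14, 21:22)
  rep2 <- suppressWarnings(
    cross_validate(d$x[idx, ], d$y[idx], "LDA", folds = 5, seed = 3))
  expect_identical(as.integer(table(rep2$fold_assignments)), rep(2L, 5))
})

test_that("every classifier family separates well-separated clusters", {
  d <- sep_clusters(n_per = 50, sep = 10, p = 4, seed = 7)
  for (fam in c("SVM_LINEAR", "SVM_GAUSS_MEDIUM", "KNN_MEDIUM", "LDA",
                "ENSEMBLE_SUBSPACE_DISCRIMINANT")) {
    rep_ <- cross_validate(d$x, d$y, fam, folds = 5, seed = 11)
    expect_gte(rep_$overall_accuracy, 0.95)
    expect_true(all(rep_$auc >= 0.99))
  }
})

test_that("permuted labels drive accuracy to chance", {
  d <- sep_clusters(n_per = 20, sep = 0, p = 5, seed = 9)
  accs <- vapply(1:30, function(s) {
    set.seed(s)
    cross_validate(d$x, sample(d$y), "LDA", folds = 5,
                   seed = s)$overall_accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 1 / 3), 0.05)
})

test_that("the benchmark reports all 32 ranked configurations deterministically", {
  fc <- generate_feature_cohort(
    cohort_config(n_patients = 120,
                  effect_features = feature_manifest()$name[1],
                  effect_sizes = 0.8, seed = 3),
    p_features = 12)
  labels <- survival_class(fc$clinical$os_days)
  sel <- lasso_select(fc$features, fc$clinical$os_days, folds = 5, seed = 2)
  skip_if(length(sel$kept_features) == 0)
  bm1 <- run_benchmark(fc$features, fc$clinical, labels, selection = sel,
                       seed = 5)
  expect_identical(nrow(bm1), 32L)
  expect_identical(sort(unique(bm1$classifier)),
                   sort(radiosurv:::CLASSIFIER_FAMILIES))
  expect_identical(sort(unique(bm1$feature_config)),
                   c("ALL", "ALL+CLINICAL", "LASSO", "LASSO+CLINICAL"))
  expect_true(all(diff(bm1$overall_accuracy) <= 0))
  expect_true(all(bm1$overall_accuracy >= 0 & bm1$overall_accuracy <= 1))
  aucs <- unlist(bm1[, c("auc_short", "auc_medium", "auc_long")])
  expect_true(all(aucs >= 0 & aucs <= 1, na.rm = TRUE))
  bm2 <- run_benchmark(fc$features, fc$clinical, labels, selection = sel,
                       seed = 5)
  expect_identical(bm1, bm2)
})

test_that("clinical covariates with real signal help the ensemble", {
  # age carries class signal beyond the radiomics columns: adding the
  # clinical block should not hurt the subspace-discriminant model
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 120
    x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
    cls <- factor(rep(c("SHORT", "MEDIUM", "LONG"), length.out = n),
                  levels = c("SHORT", "MEDIUM", "LONG"))
    age <- 60 + 8 * (as.integer(cls) - 2) + rnorm(n, 0, 3)
    clin <- data.frame(age_years = age,
                       resection_status = sample(c("GTR", "STR", "MISSING"),
                                                 n, replace = TRUE))
    foldid <- radiosurv:::make_folds(cls, 5, seed = s)
    acc_lasso <- cross_validate(x, cls, "ENSEMBLE_SUBSPACE_DISCRIMINANT",
                                seed = s, foldid = foldid)$overall_accuracy
    acc_both <- cross_validate(cbind(x, encode_clinical(clin)), cls,
                               "ENSEMBLE_SUBSPACE_DISCRIMINANT",
                               seed = s, foldid = foldid)$overall_accuracy
    acc_both >= acc_lasso
  }, NA)
  expect_gt(mean(wins), 0.5)
})
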