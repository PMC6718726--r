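test_that("Cox fitting validates its inputs and returns Wald p-values", {
  set.seed(41)
  x <- data.frame(f1 = rnorm(50), f2 = rep(3, 50))
  expect_error(fit_cox(x, rexp(50, 1 / 300)), "zero-variance")
  x$f2 <- rnorm(50)
  fit <- fit_cox(x, rexp(50, 1 / 300))
  expect_named(fit$beta, c("f1", "f2"))
  expect_true(all(fit$p_values >= 0 & fit$p_values <= 1))
})

test_that("null covariates give uniform Cox p-values", {
  pvals <- vapply(1:200, function(s) {
    set.seed(s)
    x <- data.frame(f1 = rnorm(60))
    fit_cox(x, rexp(60, 1 / 362))$p_values
  }, 0)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("the risk score is the linear form of the coefficients", {
  beta <- c(a = 1.5, b = -2, c = 0.25)
  expect_equal(risk_score(c(a = 0, b = 0, c = 0), beta), 0)
  v <- c(a = 2, b = 1, c = 4)
  expect_equal(risk_score(v, beta), 2)
  expect_equal(risk_score(2 * v, beta), 2 * risk_score(v, beta))
  expect_error(risk_score(c(a = 1, b = 2), beta), "c")
  # matrix input gives one score per row
  m <- rbind(v, 2 * v)
  expect_equal(unname(risk_score(m, beta)), c(2, 4))
})

test_that("half-median cutoffs reproduce the worked example", {
  cut <- cutoffs_from_medians(short_median = 0.245, long_median = -1.009)
  expect_equal(unname(cut["low"]), -0.5045)
  expect_equal(unname(cut["high"]), 0.1225)
  sym <- cutoffs_from_medians(2, -2)
  expect_equal(unname(sym), c(-1, 1))
  expect_error(cutoffs_from_medians(-0.5, 0.5), "inverted")
})

test_that("cutoffs derive from per-group score medians", {
  scores <- c(-1.5, 0.245, 4.1,   # SHORT group, median 0.245
              -2.6, -0.81, 0.9,   # MEDIUM
              -3.2, -1.009, 1.6)  # LONG
  cls <- rep(c("SHORT", "MEDIUM", "LONG"), each = 3)
  cut <- derive_cutoffs(scores, cls)
  expect_equal(unname(cut["low"]), -0.5045)
  expect_equal(unname(cut["high"]), 0.1225)
  expect_error(derive_cutoffs(scores[1:6], cls[1:6]), "present")
})

test_that("stratification uses strict cutoff inequalities", {
  s <- stratify_scores(c(0.5, -1.0, 0.122, -0.505, 0), -0.505, 0.122)
  expect_identical(as.character(s$risk_group),
                   c("HIGH", "LOW", "MEDIUM", "MEDIUM", "MEDIUM"))
  expect_identical(as.character(s$predicted_class),
                   c("SHORT", "LONG", "MEDIUM", "MEDIUM", "MEDIUM"))
  expect_error(stratify_scores(c(1, NA), -1, 1), "non-finite")
  expect_error(stratify_scores(0, 1, -1), "low < high")
})

test_that("confusion statistics follow the counting definitions", {
  cls <- c("SHORT", "MEDIUM", "LONG")
  truth <- rep(cls, times = c(6, 6, 5))
  perfect <- confusion_stats(truth, truth)
  expect_equal(unname(perfect$sensitivity), c(1, 1, 1))
  expect_equal(unname(perfect$fpr), c(0, 0, 0))
  # everyone predicted SHORT on balanced truth
  all_short <- confusion_stats(rep("SHORT", 9), rep(cls, each = 3))
  expect_equal(unname(all_short$sensitivity), c(1, 0, 0))
  expect_equal(unname(all_short$fpr["SHORT"]), 1)
  # a printed toy matrix: rows true, columns predicted
  truth3 <- rep(cls, times = c(6, 6, 5))
  pred3 <- c(rep("SHORT", 5), "MEDIUM",
             rep("SHORT", 2), rep("MEDIUM", 3), "LONG",
             "MEDIUM", rep("LONG", 4))
  cs <- confusion_stats(pred3, truth3)
  expect_equal(unname(cs$sensitivity), c(5 / 6, 3 / 6, 4 / 5))
  expect_equal(unname(rowSums(cs$counts)), c(6, 6, 5))
})

test_that("the stratum t-test has its nominal size and detects separation", {
  set.seed(17)
  rej <- mean(vapply(1:500, function(i) {
    os <- rexp(120, 1 / 362)
    grp <- factor(rep(c("HIGH", "LOW"), each = 60),
                  levels = c("LOW", "MEDIUM", "HIGH"))
    association_test(os, grp)$p.value < 0.05
  }, NA))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  os2 <- c(rnorm(30, 100, 20), rnorm(30, 1000, 20))
  grp2 <- factor(rep(c("HIGH", "LOW"), each = 30),
                 levels = c("LOW", "MEDIUM", "HIGH"))
  expect_lt(association_test(os2, grp2)$p.value, 0.001)
  expect_error(association_test(os2, factor(rep("HIGH", 60),
                                            levels = levels(grp2))),
               "stratum|at least 2")
})

test_that("z-scoring standardizes with the population denominator", {
  z <- zscore_matrix(cbind(a = c(1, 2, 3)))
  expect_equal(unname(z[, 1]), c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-6)
  expect_equal(unname(z[, 1]), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(zscore_matrix(z), z, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(zscore_matrix(cbind(a = rep(4, 3))), "zero-SD")
})

test_that("the fitted signature stratifies survival end to end", {
  # hazard rises with two designated features; the fitted signature's
  # HIGH group must die sooner than its LOW group in >= 90% of seeds
  hits <- vapply(1:50, function(s) {
    fc <- generate_feature_cohort(
      cohort_config(n_patients = 300,
                    effect_features = feature_manifest()$name[c(1, 2)],
                    effect_sizes = c(0.7, 0.5), seed = s),
      p_features = 40)
    sig <- tryCatch(
      radiomics_signature(fc$features, fc$clinical$os_days, folds = 5,
                          seed = s),
      error = function(e) NULL)
    if (is.null(sig)) return(NA)
    pred <- predict(sig, fc$features)
    hi <- fc$clinical$os_days[pred$risk_group == "HIGH"]
    lo <- fc$clinical$os_days[pred$risk_group == "LOW"]
    length(hi) > 0 && length(lo) > 0 && median(hi) < median(lo)
  }, NA)
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
  expect_lte(sum(is.na(hits)), 5)
})

test_that("signature objects expose the standard modelling methods", {
  fc <- generate_feature_cohort(
    cohort_config(n_patients = 200,
                  effect_features = feature_manifest()$name[c(1, 2)],
                  effect_sizes = c(0.8, 0.6), seed = 4),
    p_features = 30)
  sig <- radiomics_signature(fc$features, fc$clinical$os_days, folds = 5,
                             seed = 2)
  expect_s3_class(sig, "radiomics_signature")
  expect_lt(sig$low_cutoff, sig$high_cutoff)
  expect_identical(names(coef(sig)), sig$feature_names)
  expect_output(print(sig), "Radiomics survival signature")
  sm <- summary(sig)
  expect_s3_class(sm, "summary.radiomics_signature")
  expect_identical(nrow(sm$coefficients), length(sig$feature_names))
  pred <- predict(sig, fc$features)
  expect_identical(nrow(pred), 200L)
  expect_equal(pred$score,
               unname(risk_score(fc$features[, sig$feature_names],
                                 coef(sig))))
  expect_length(residuals(sig), 200L)
  # serialization keeps the frozen cutoffs
  p <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, p)
  js <- jsonlite::read_json(p)
  expect_equal(js$low_cutoff, sig$low_cutoff)
  expect_equal(js$high_cutoff, sig$high_cutoff)
})
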