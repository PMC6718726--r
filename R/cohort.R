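# Synthetic cohorts: phantom imaging studies or feature-level tables with
# survival times generated from an exponential proportional-hazards model
# whose log-hazard is a linear combination of designated generating
# features.

#' Cohort simulation configuration
#'
#' Parameters shared by the cohort generators: cohort size, the generating
#' features that drive the hazard with their log-hazard coefficients (per
#' standard deviation of the generating value), the baseline median
#' survival, the age distribution, and the fraction of patients with
#' missing resection status.
#'
#' @param n_patients Number of patients (at least 3, so all survival groups
#'   can occur).
#' @param effect_features Character names of hazard-driving features.
#' @param effect_sizes Log-hazard coefficients, one per effect feature.
#' @param baseline_median_os_days Median survival at zero linear predictor.
#' @param age_mean,age_sd Age distribution (years), truncated to `[18, 90]`.
#' @param missing_resection_frac Proportion of `MISSING` resection status.
#' @param censoring_frac Optional fraction of administratively censored
#'   observations (default 0: survival fully observed).
#' @param seed RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 163L, effect_features = character(),
                          effect_sizes = numeric(),
                          baseline_median_os_days = 362,
                          age_mean = 60, age_sd = 12,
                          missing_resection_frac = 0.49,
                          censoring_frac = 0, seed = 1L) {
  if (n_patients < 3L)
    stopf("n_patients must be >= 3 to form three survival groups")
  if (length(effect_features) != length(effect_sizes))
    stopf("effect_features and effect_sizes must have equal length")
  if (anyDuplicated(effect_features))
    stopf("duplicate effect feature names")
  if (missing_resection_frac < 0 || missing_resection_frac > 1)
    stopf("missing_resection_frac must be in [0, 1]")
  if (baseline_median_os_days <= 0) stopf("baseline median OS must be positive")
  structure(list(n_patients = as.integer(n_patients),
                 effect_features = as.character(effect_features),
                 effect_sizes = as.numeric(effect_sizes),
                 baseline_median_os_days = baseline_median_os_days,
                 age_mean = age_mean, age_sd = age_sd,
                 missing_resection_frac = missing_resection_frac,
                 censoring_frac = censoring_frac, seed = as.integer(seed)),
            class = "cohort_config")
}

# Ages ~ N(mean, sd^2) truncated to [18, 90] by rejection.
draw_ages <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * n, mean, sd)
    out <- c(out, x[x >= 18 & x <= 90])
  }
  out[seq_len(n)]
}

draw_resection <- function(n, missing_frac) {
  status <- ifelse(stats::runif(n) < missing_frac, "MISSING",
                   ifelse(stats::runif(n) < 0.7, "GTR", "STR"))
  factor(status, levels = RESECTION_LEVELS)
}

# Exponential proportional-hazards survival times: the baseline rate is
# scaled so the median OS at linear predictor 0 equals the configured
# baseline; OS_i ~ Exp(rate = log(2)/median * exp(lp_i)).
draw_os <- function(lp, baseline_median) {
  rate <- log(2) / baseline_median * exp(lp)
  stats::rexp(length(lp), rate)
}

# Standardize generating values so effect sizes read as log-hazard per SD.
zscore_cols <- function(m) {
  apply(m, 2L, function(x) {
    s <- pop_sd(x)
    if (s == 0) x - mean(x) else (x - mean(x)) / s
  })
}

#' Generate a phantom imaging cohort
#'
#' Draws per-patient phantom parameters (tumor radii and intra-tumoral
#' texture contrast vary across patients), renders each study with
#' [generate_phantom_study()], and samples survival from the exponential
#' proportional-hazards model whose log-hazard is the configured linear
#' combination of the standardized generating parameter values. Valid
#' effect-feature names are the generating parameters `wt_radius_mm`,
#' `tc_radius_mm`, `at_radius_mm` and `texture_contrast`.
#'
#' @param config A [cohort_config()].
#' @param phantom A [phantom_config()] giving the template phantom.
#' @return List with `studies` (list of [mri_study()]), `clinical` (data
#'   frame `patient_id`, `age_years`, `os_days`, `event`,
#'   `resection_status`) and `generating` (the per-patient generating
#'   parameter values).
#' @export
generate_cohort <- function(config = cohort_config(),
                            phantom = phantom_config()) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(phantom, "phantom_config"))
  gen_names <- c("wt_radius_mm", "tc_radius_mm", "at_radius_mm",
                 "texture_contrast")
  bad <- setdiff(config$effect_features, gen_names)
  if (length(bad))
    stopf("unknown generating feature(s): %s (valid: %s)",
          paste(bad, collapse = ", "), paste(gen_names, collapse = ", "))
  n <- config$n_patients
  with_seed(config$seed, {
    # per-patient generating parameters around the template phantom
    half_extent <- min(phantom$grid_shape * phantom$voxel_mm) / 2
    wt <- pmax(phantom$wt_radius_mm[1L] * stats::rlnorm(n, 0, 0.15), 10)
    wt <- pmin(wt, half_extent - 2)      # keep inside the grid
    tc <- pmax(pmin(wt * stats::runif(n, 0.4, 0.8), wt), 4)
    at <- pmax(pmin(tc * stats::runif(n, 0.3, 0.7), tc), 2)
    tex <- pmax(stats::rnorm(n, phantom$texture_contrast, 15), 0)
    gen <- cbind(wt_radius_mm = wt, tc_radius_mm = tc, at_radius_mm = at,
                 texture_contrast = tex)
    z <- zscore_cols(gen)
    lp <- if (length(config$effect_features))
      drop(z[, config$effect_features, drop = FALSE] %*% config$effect_sizes)
    else rep(0, n)
    os <- pmax(draw_os(lp, config$baseline_median_os_days), 1)
    event <- rep(1L, n)
    if (config$censoring_frac > 0) {
      cens <- stats::runif(n) < config$censoring_frac
      os[cens] <- os[cens] * stats::runif(sum(cens))
      event[cens] <- 0L
    }
    ages <- draw_ages(n, config$age_mean, config$age_sd)
    resection <- draw_resection(n, config$missing_resection_frac)
    seeds <- sample.int(.Machine$integer.max, n)
    ids <- sprintf("synth-%03d", seq_len(n))
    studies <- lapply(seq_len(n), function(i) {
      pc <- phantom
      pc$wt_radius_mm <- rep_len(gen[i, "wt_radius_mm"], 3L)
      pc$tc_radius_mm <- rep_len(gen[i, "tc_radius_mm"], 3L)
      pc$at_radius_mm <- rep_len(gen[i, "at_radius_mm"], 3L)
      pc$texture_contrast <- gen[i, "texture_contrast"]
      pc$seed <- seeds[i]
      generate_phantom_study(pc, patient_id = ids[i])
    })
    list(studies = studies,
         clinical = data.frame(patient_id = ids, age_years = ages,
                               os_days = os, event = event,
                               resection_status = resection,
                               stringsAsFactors = FALSE),
         generating = data.frame(patient_id = ids, gen,
                                 stringsAsFactors = FALSE))
  })
}

#' Generate a feature-level synthetic cohort
#'
#' Fast path for testing the selection, signature and classifier stages
#' without imaging: draws an `n x p` standard-normal feature table whose
#' columns carry the catalogue's `Modality_Region_FeatureName_F<index>`
#' names, and samples survival from the exponential proportional-hazards
#' model driven by the designated effect columns. Effect features that are
#' not already column names replace the names of the first columns, so the
#' planted signal is always present in the table.
#'
#' @param config A [cohort_config()].
#' @param p_features Number of feature columns (at least the number of
#'   effect features).
#' @param constant_columns Optional character names of columns to hold
#'   constant (zero spread), e.g. to exercise the MAD filter.
#' @return List with `features` (data frame `n x p`) and `clinical` (as in
#'   [generate_cohort()]).
#' @export
generate_feature_cohort <- function(config = cohort_config(),
                                    p_features = 147L,
                                    constant_columns = character()) {
  stopifnot(inherits(config, "cohort_config"))
  k <- length(config$effect_features)
  if (p_features < k)
    stopf("p_features (%d) smaller than the number of effect features (%d)",
          p_features, k)
  manifest <- feature_manifest()$name
  nm <- if (p_features <= length(manifest)) manifest[seq_len(p_features)]
        else c(manifest, sprintf("Synth_Noise_Gaussian_F%d",
                                 seq.int(length(manifest) + 1L, p_features)))
  extra <- setdiff(config$effect_features, nm)
  if (length(extra)) {
    free <- setdiff(seq_along(nm), match(config$effect_features, nm))
    nm[free[seq_along(extra)]] <- extra
  }
  n <- config$n_patients
  with_seed(config$seed, {
    x <- matrix(stats::rnorm(n * p_features), n, p_features,
                dimnames = list(NULL, nm))
    for (cc in constant_columns) {
      if (!cc %in% nm) stopf("constant column '%s' not in the table", cc)
      x[, cc] <- 1
    }
    lp <- if (k) drop(x[, config$effect_features, drop = FALSE] %*%
                        config$effect_sizes)
          else rep(0, n)
    os <- pmax(draw_os(lp, config$baseline_median_os_days), 1)
    event <- rep(1L, n)
    if (config$censoring_frac > 0) {
      cens <- stats::runif(n) < config$censoring_frac
      os[cens] <- os[cens] * stats::runif(sum(cens))
      event[cens] <- 0L
    }
    ids <- sprintf("synth-%03d", seq_len(n))
    list(features = data.frame(x, check.names = FALSE),
         clinical = data.frame(patient_id = ids,
                               age_years = draw_ages(n, config$age_mean,
                                                     config$age_sd),
                               os_days = os, event = event,
                               resection_status =
                                 draw_resection(n,
                                                config$missing_resection_frac),
                               stringsAsFactors = FALSE))
  })
}
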