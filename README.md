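# radiosurv

Radiomics survival-group stratification for glioblastoma from
pre-operative multi-parametric MRI.

Glioblastoma multiforme (GBM) has a median survival of roughly two years
or less, and the choice of treatment intensity benefits from knowing, at
diagnosis, whether a patient is likely to be a short- (< 10 months),
medium- (10–15 months) or long-term (> 15 months) survivor. `radiosurv`
implements a complete, testable radiomics pipeline for that three-class
problem, aimed at medical-imaging researchers who work with BRATS-style
data: four co-registered, skull-stripped MRI channels (T1, T1-Gd, T2,
T2-FLAIR) plus a tumor sub-region label volume per patient, and a
clinical table with age, overall survival and resection status.

The pipeline comprises:

1. **Intensity standardization** — each channel is clipped to
   μ ± 3σ over the brain mask and quantized onto `[0, 255]`
   (`normalize_mu3sigma()`), making downstream features invariant to
   scanner gain and offset.
2. **A fixed 147-feature catalogue** (`extract_features()`) — 48 features
   per (region, modality) pairing — whole tumor on T2-FLAIR, active tumor
   on T1-Gd, tumor core on T2 — each block holding 14 shape, 14
   first-order intensity, 14 GLCM texture, 3 HOG and 3 LBP descriptors,
   plus 3 joint volume ratios (AT/WT, TC/WT, AT/TC). Features are named
   `Modality_Region_FeatureName_F<index>`, e.g. `T2_TC_SumHOG_F139`.
3. **Feature selection** — a median-absolute-deviation filter
   (`mad_filter()`) followed by 10-fold cross-validated LASSO
   (`lasso_select()`).
4. **The risk-score signature** (`radiomics_signature()`) — unpenalized
   Cox log-hazard coefficients β on the selected features give each
   patient the linear score

   ```
   score = Σᵢ βᵢ · featureᵢ
   ```

   Patients are stratified by two fixed cutoffs derived once from the
   discovery cohort: half the short-survivor group's median score (high
   cutoff) and half the long-survivor group's median score (low cutoff).
   `score > high` ⇒ high-risk/short-survivor, `score < low` ⇒
   low-risk/long-survivor, otherwise medium.
5. **A classifier benchmark** (`run_benchmark()`) — eight classifier
   configurations (linear/medium/coarse-Gaussian SVM, coarse/cosine/medium
   KNN, LDA, and a random-subspace discriminant ensemble) × four feature
   sets (all 147, all + clinical, LASSO subset, LASSO + clinical), scored
   by stratified 5-fold cross-validation with one-vs-rest AUC per class
   and overall accuracy.

A synthetic phantom generator (`generate_phantom_study()`,
`generate_cohort()`, `generate_feature_cohort()`) produces nested
ellipsoidal tumors with controllable texture and survival times whose
hazard is linked to designated features, so the entire pipeline is
testable without patient data.

## Worked example

A synthetic 163-patient feature cohort in which two designated features
drive the hazard; the fitted signature recovers both and separates the
predicted strata:

```r
library(radiosurv)

cfg <- cohort_config(
  n_patients = 163,
  effect_features = c("T2_TC_SumHOG_F139", "T1-GD_AT_Energy_F79"),
  effect_sizes = c(0.6, -0.5), seed = 20)
fc  <- generate_feature_cohort(cfg)

sig <- radiomics_signature(fc$features, fc$clinical$os_days,
                           folds = 10, seed = 1)
print(sig)
#> Radiomics survival signature
#>   8 feature(s) selected (lambda_opt = 188.7)
#>   cutoffs: low -0.2718, high 0.3223
#>   coefficients (log hazard):
#>    T2-FLAIR_WT_MinimumIntensity_F15           T2-FLAIR_WT_Moment3rd_F22
#>                              0.0135                              0.2264
#> T2-FLAIR_WT_DifferenceVariance2_F41              T1-GD_AT_Perimeter_F62
#>                              0.1525                             -0.0108
#>                 T1-GD_AT_Energy_F79           T1-GD_AT_GLCMVariance_F83
#>                             -0.4798                             -0.1362
#>               T2_TC_BrainVolume_F98                   T2_TC_SumHOG_F139
#>                             -0.1786                              0.5361

summary(sig)$confusion
#>         predicted
#> true     SHORT MEDIUM LONG
#>   SHORT     47     12   15
#>   MEDIUM     4      6    8
#>   LONG      10     11   50
#> sensitivity: SHORT=0.635 MEDIUM=0.333 LONG=0.704
#> fpr:         SHORT=0.157 MEDIUM=0.159 LONG=0.250
```

Both planted effect features (`T2_TC_SumHOG_F139`, positive log-hazard;
`T1-GD_AT_Energy_F79`, negative) are selected with the right signs, and
survival differs strongly between the predicted HIGH and LOW strata
(Welch t-test p = 4.2e-07 on this cohort).

New patients are scored with `predict(sig, newdata)`, which returns the
score, risk group and predicted survival class under the frozen cutoffs.

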