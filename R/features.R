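# The fixed 147-feature radiomics catalogue: 48 features per
# (region, modality) pairing -- WT on T2-FLAIR, AT on T1-Gd, TC on T2 --
# plus 3 joint volume ratios.

SHAPE_NAMES <- c("TumorVolume", "BrainVolume", "TumorToBrainVolumeRatio",
                 "TumorConvexArea", "TumorFilledArea", "TumorArea",
                 "BrainArea", "TumorToBrainAreaRatio", "Eccentricity",
                 "Orientation", "EquivalentDiameter", "Solidity", "Extent",
                 "Perimeter")
INTENSITY_NAMES <- c("MinimumIntensity", "MaximumIntensity",
                     "MedianIntensity", "MeanIntensity", "Range", "Variance",
                     "Moment2nd", "Moment3rd", "Entropy", "Kurtosis", "RMS",
                     "Skewness", "StandardDeviation", "MeanAbsoluteDeviation")
GLCM_NAMES <- c("Contrast", "Correlation", "Energy", "Homogeneity",
                "SumVariance", "SumAverage", "GLCMVariance",
                "Autocorrelation", "GLCMEntropy", "SumEntropy2",
                "DifferenceEntropy2", "SumVariance2", "DifferenceVariance2",
                "GLCMRange")
HOG_NAMES <- c("SumHOG", "MedianHOG", "StdHOG")
LBP_NAMES <- c("SumLBP", "MeanLBP", "StdLBP")

# (region, modality, channel) pairings in catalogue order.
PAIRINGS <- data.frame(
  region = c("WT", "AT", "TC"),
  modality = c("T2-FLAIR", "T1-GD", "T2"),
  channel = c("flair", "t1gd", "t2"),
  stringsAsFactors = FALSE)

JOINT_NAMES <- c("ATtoWTVolumeRatio", "TCtoWTVolumeRatio",
                 "ATtoTCVolumeRatio")

#' The 147-feature order manifest
#'
#' Returns the fixed feature order and naming of the catalogue. Each of the
#' three (region, modality) pairings -- WT on T2-FLAIR (features 1-48), AT
#' on T1-Gd (49-96), TC on T2 (97-144) -- contributes 14 shape, 14
#' intensity, 14 GLCM, 3 HOG and 3 LBP features, followed by the 3 joint
#' volume ratios (145-147). Names follow the
#' `Modality_Region_FeatureName_F<index>` convention, e.g.
#' `T2_TC_SumHOG_F139`.
#'
#' @return Data frame with columns `index`, `name`, `modality`, `region`,
#'   `class` and `feature`.
#' @export
feature_manifest <- function() {
  block <- function(region, modality) {
    feats <- c(SHAPE_NAMES, INTENSITY_NAMES, GLCM_NAMES, HOG_NAMES, LBP_NAMES)
    data.frame(modality = modality, region = region,
               class = rep(c("shape", "intensity", "glcm", "hog", "lbp"),
                           c(14L, 14L, 14L, 3L, 3L)),
               feature = feats, stringsAsFactors = FALSE)
  }
  df <- rbind(block("WT", "T2-FLAIR"), block("AT", "T1-GD"),
              block("TC", "T2"),
              data.frame(modality = "Joint", region = "WTTCAT",
                         class = "joint", feature = JOINT_NAMES,
                         stringsAsFactors = FALSE))
  df$index <- seq_len(nrow(df))
  df$name <- sprintf("%s_%s_%s_F%d", df$modality, df$region, df$feature,
                     df$index)
  df[, c("index", "name", "modality", "region", "class", "feature")]
}

#' Write the feature-order manifest as JSON
#'
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_feature_manifest <- function(path) {
  jsonlite::write_json(feature_manifest(), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Select the axial slice with the largest tumor cross-section
#'
#' Returns the index of the axial (transverse) slice maximizing the
#' in-slice mask area; ties go to the lowest index.
#'
#' @param mask3d Logical 3-D mask.
#' @return Integer slice index along the third axis.
#' @export
select_slice <- function(mask3d) {
  if (!any(mask3d)) stopf("empty mask: no slice to select")
  areas <- apply(mask3d, 3L, sum)
  which.max(areas)
}

#' Crop a slice to the tight bounding box of its mask
#'
#' @param image2d Numeric matrix.
#' @param mask2d Logical matrix of the same shape.
#' @return List with `image2d`, `mask2d` and the half-open
#'   `bounding_box = c(row0, col0, row1, col1)` (0-based, half-open).
#' @export
crop_roi <- function(image2d, mask2d) {
  if (!identical(dim(image2d), dim(mask2d)))
    stopf("image and mask shapes differ")
  if (!any(mask2d)) stopf("empty mask: nothing to crop")
  xy <- which(mask2d, arr.ind = TRUE)
  r <- range(xy[, 1L]); c <- range(xy[, 2L])
  list(image2d = image2d[r[1L]:r[2L], c[1L]:c[2L], drop = FALSE],
       mask2d = mask2d[r[1L]:r[2L], c[1L]:c[2L], drop = FALSE],
       bounding_box = c(r[1L] - 1L, c[1L] - 1L, r[2L], c[2L]))
}

#' First-order intensity statistics
#'
#' Fourteen histogram statistics of the masked grey levels: minimum,
#' maximum, median, mean, range, (sample) variance, 2nd- and 3rd-order
#' central moments, entropy of the 256-bin normalized histogram in bits,
#' kurtosis (non-excess), root mean square, skewness, (sample) standard
#' deviation and mean absolute deviation. Skewness and kurtosis are 0 for
#' zero-spread input.
#'
#' @param values Numeric vector of grey levels in `[0, 255]`.
#' @return Named numeric vector of length 14.
#' @export
intensity_features <- function(values) {
  if (!length(values)) stopf("empty intensity sample")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  counts <- tabulate(pmin(pmax(floor(values), 0), 255) + 1L, nbins = 256L)
  p <- counts[counts > 0] / length(values)
  c(MinimumIntensity = min(values),
    MaximumIntensity = max(values),
    MedianIntensity = stats::median(values),
    MeanIntensity = m,
    Range = max(values) - min(values),
    Variance = if (length(values) > 1L) stats::var(values) else 0,
    Moment2nd = m2,
    Moment3rd = m3,
    Entropy = -sum(p * log2(p)),
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    RMS = sqrt(mean(values^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    StandardDeviation = if (length(values) > 1L) stats::sd(values) else 0,
    MeanAbsoluteDeviation = mean(abs(values - m)))
}

#' Joint volume ratios of the nested sub-regions
#'
#' AT/WT, TC/WT and AT/TC voxel-count ratios. A zero denominator yields the
#' empty-region policy value.
#'
#' @param masks Mask list from [decode_masks()] / [tumor_masks()].
#' @param policy_value Value used when a denominator is empty (default 0).
#' @return Named numeric vector of length 3.
#' @export
joint_shape_features <- function(masks, policy_value = 0) {
  nwt <- sum(masks$wt); ntc <- sum(masks$tc); nat <- sum(masks$at)
  if (nwt == 0) stopf("empty whole-tumor mask")
  rat <- function(a, b) if (b > 0) a / b else policy_value
  c(ATtoWTVolumeRatio = rat(nat, nwt),
    TCtoWTVolumeRatio = rat(ntc, nwt),
    ATtoTCVolumeRatio = rat(nat, ntc))
}

# One 48-feature block for a (region, channel) pairing, or the policy value
# throughout when the region is empty.
extract_block <- function(region3d, volume, brain3d, voxel_mm, glcm_levels,
                          policy_value) {
  if (!any(region3d))
    return(list(values = rep(policy_value, 48L), empty = TRUE))
  k <- select_slice(region3d)
  img <- volume[, , k]
  msk <- region3d[, , k]
  roi <- crop_roi(img, msk)
  shape <- shape_features(region3d, brain3d, k, voxel_mm)
  intens <- intensity_features(img[msk])
  glcm <- tryCatch(glcm_features(roi$image2d, roi$mask2d, glcm_levels),
                   error = function(e) stats::setNames(rep(policy_value, 14L),
                                                      GLCM_NAMES))
  hog <- hog_features(roi$image2d, roi$mask2d)
  lbp <- lbp_features(roi$image2d, roi$mask2d)
  list(values = unname(c(shape, intens, glcm, hog, lbp)), empty = FALSE)
}

#' Extract the full 147-feature vector for one study
#'
#' Normalizes the study (unless already on the 8-bit scale), decodes the
#' nested masks, and computes the 48-feature block for each
#' (region, modality) pairing plus the 3 joint volume ratios, in the fixed
#' order of [feature_manifest()]. Empty sub-regions (e.g. no enhancing
#' tumor) receive the policy value for their whole block and are listed in
#' the `qc_empty_regions` attribute; the vector length is always 147.
#'
#' @param study An [mri_study()].
#' @param masks Optional precomputed [tumor_masks()] list.
#' @param normalize Standardize channels first with [normalize_study()].
#' @param glcm_levels Grey levels for the co-occurrence quantization.
#' @param policy_value Sentinel used for empty-region blocks (default 0).
#' @return Named numeric vector of length 147 with attribute
#'   `qc_empty_regions`.
#' @export
extract_features <- function(study, masks = NULL, normalize = TRUE,
                             glcm_levels = 8L, policy_value = 0) {
  stopifnot(inherits(study, "mri_study"))
  if (is.null(masks)) masks <- tumor_masks(study)
  if (normalize) study <- normalize_study(study)
  brain <- masks$brain
  if (is.null(brain)) brain <- array(study$channels$t1gd > 0, dim(study$labels))
  qc <- character(0)
  values <- numeric(0)
  for (i in seq_len(nrow(PAIRINGS))) {
    region <- tolower(PAIRINGS$region[i])
    blk <- extract_block(masks[[region]], study$channels[[PAIRINGS$channel[i]]],
                         brain, study$voxel_mm, glcm_levels, policy_value)
    if (blk$empty) qc <- c(qc, PAIRINGS$region[i])
    values <- c(values, blk$values)
  }
  values <- c(values, unname(joint_shape_features(masks, policy_value)))
  structure(stats::setNames(values, feature_manifest()$name),
            qc_empty_regions = qc)
}

#' Extract features for a list of studies
#'
#' @param studies List of [mri_study()] objects.
#' @param ... Passed to [extract_features()].
#' @return Data frame with `patient_id` plus the 147 named feature columns.
#' @export
extract_cohort <- function(studies, ...) {
  rows <- lapply(studies, function(s) extract_features(s, ...))
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  data.frame(patient_id = vapply(studies, `[[`, "", "patient_id"), out,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a feature table as CSV
#'
#' @param features Data frame from [extract_cohort()].
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
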