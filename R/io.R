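# Study IO, mask decoding, intensity standardization, cohort split and
# survival grouping.

CHANNELS <- c("t1", "t1gd", "t2", "flair")
LABEL_SET <- c(0L, 1L, 2L, 4L)  # background, NCR/NET, ED, ET
RESECTION_LEVELS <- c("GTR", "STR", "MISSING")
SURVIVAL_LEVELS <- c("SHORT", "MEDIUM", "LONG")

#' Construct an MRI study object
#'
#' Bundles the four co-registered, skull-stripped channel volumes (`t1`,
#' `t1gd`, `t2`, `flair`), the tumor label volume and the voxel spacing for
#' one patient. All volumes must share one shape; labels must come from the
#' set `{0, 1, 2, 4}` (background, necrosis/non-enhancing core, edema,
#' enhancing tumor).
#'
#' @param patient_id Character id.
#' @param channels Named list of four 3-D numeric arrays.
#' @param labels 3-D integer array of tumor sub-region labels.
#' @param voxel_mm Voxel spacing per axis in millimetres.
#' @return An object of class `mri_study`.
#' @export
mri_study <- function(patient_id, channels, labels, voxel_mm = c(1, 1, 1)) {
  if (!all(CHANNELS %in% names(channels)))
    stopf("missing channel(s): %s",
          paste(setdiff(CHANNELS, names(channels)), collapse = ", "))
  channels <- channels[CHANNELS]
  dims <- dim(channels[[1L]])
  if (length(dims) != 3L) stopf("channel volumes must be 3-D")
  for (ch in CHANNELS)
    if (!identical(dim(channels[[ch]]), dims))
      stopf("channel '%s' shape differs from '%s'", ch, CHANNELS[1L])
  if (!identical(dim(labels), dims))
    stopf("label volume shape differs from channel volumes")
  bad <- setdiff(unique(as.integer(labels)), LABEL_SET)
  if (length(bad))
    stopf("unknown label value(s): %s", paste(bad, collapse = ", "))
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  if (any(voxel_mm <= 0)) stopf("voxel spacing must be positive")
  structure(list(patient_id = as.character(patient_id), channels = channels,
                 labels = labels, voxel_mm = voxel_mm),
            class = "mri_study")
}

#' @export
print.mri_study <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<mri_study> %s  %dx%dx%d voxels @ %.3g mm, labels: %s\n",
              x$patient_id, d[1], d[2], d[3], x$voxel_mm[1],
              paste(sort(unique(as.integer(x$labels))), collapse = ",")))
  invisible(x)
}

#' Write a study to NIfTI files
#'
#' Writes one gzipped NIfTI file per channel plus the label volume, named
#' `<id>_<t1|t1gd|t2|flair|seg>.nii.gz`, and returns the paths.
#'
#' @param study An [mri_study()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "mri_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    vapply(CHANNELS, function(ch)
      file.path(dir, sprintf("%s_%s.nii.gz", study$patient_id, ch)), ""),
    seg = file.path(dir, sprintf("%s_seg.nii.gz", study$patient_id)))
  vols <- c(study$channels, list(seg = study$labels))
  types <- c(rep("double", 4L), "int16")
  for (i in seq_along(paths))
    RNifti::writeNifti(RNifti::asNifti(vols[[i]], pixdim = study$voxel_mm),
                       paths[[i]], datatype = types[i])
  paths
}

#' Read a study from NIfTI files
#'
#' @param paths Named character vector with elements `t1`, `t1gd`, `t2`,
#'   `flair` and `seg`, as produced by [write_study()].
#' @param patient_id Patient id; defaults to the common filename prefix.
#' @param legacy_labels If `TRUE`, maps the older five-value label dialect
#'   (`3` for non-enhancing tumor) onto the current one (`3 -> 1`).
#' @return An [mri_study()].
#' @export
read_study <- function(paths, patient_id = NULL, legacy_labels = FALSE) {
  need <- c(CHANNELS, "seg")
  miss <- setdiff(need, names(paths))
  if (length(miss))
    stopf("missing path(s) for: %s", paste(miss, collapse = ", "))
  for (nm in need)
    if (!file.exists(paths[[nm]])) stopf("file for '%s' not found: %s", nm, paths[[nm]])
  vols <- lapply(paths[need], RNifti::readNifti)
  spacing <- RNifti::pixdim(vols$t1)[seq_len(3)]
  labels <- round(vols$seg)
  if (legacy_labels) labels[labels == 3] <- 1
  if (is.null(patient_id))
    patient_id <- sub("_(t1|t1gd|t2|flair|seg)\\.nii(\\.gz)?$", "",
                      basename(paths[["t1"]]))
  mri_study(patient_id,
            channels = lapply(vols[CHANNELS],
                              function(v) array(as.numeric(v), dim(v))),
            labels = array(as.integer(labels), dim(labels)),
            voxel_mm = spacing)
}

#' Decode nested tumor masks from a label volume
#'
#' Decodes the whole tumor (labels 1, 2, 4), tumor core (1, 4) and active
#' tumor (4) boolean volumes, plus the brain support (nonzero intensity in
#' the reference channel) when a reference volume is supplied. The decoded
#' masks are nested: AT subset of TC subset of WT.
#'
#' @param labels 3-D integer label volume over `{0, 1, 2, 4}`.
#' @param reference Optional 3-D intensity volume whose nonzero support
#'   defines the brain mask.
#' @return List with logical volumes `wt`, `tc`, `at` and `brain` (or `NULL`).
#' @export
decode_masks <- function(labels, reference = NULL) {
  bad <- setdiff(unique(as.integer(labels)), LABEL_SET)
  if (length(bad))
    stopf("unknown label value(s): %s", paste(bad, collapse = ", "))
  wt <- array(labels %in% c(1L, 2L, 4L), dim(labels))
  if (!any(wt)) stopf("empty whole-tumor mask: no tumor present")
  brain <- if (is.null(reference)) NULL else array(reference > 0, dim(labels))
  list(wt = wt,
       tc = array(labels %in% c(1L, 4L), dim(labels)),
       at = array(labels == 4L, dim(labels)),
       brain = brain)
}

#' Decode masks for a study
#'
#' Convenience wrapper around [decode_masks()] using the study's `t1gd`
#' channel (the co-registration reference) for the brain support.
#'
#' @param study An [mri_study()].
#' @return As [decode_masks()].
#' @export
tumor_masks <- function(study) {
  stopifnot(inherits(study, "mri_study"))
  decode_masks(study$labels, reference = study$channels$t1gd)
}

#' Standardize intensities to mu +/- 3 sigma on an 8-bit scale
#'
#' Computes the mean and population standard deviation of the grey levels
#' over the brain mask, clips the volume to `[mu - 3*sigma, mu + 3*sigma]`,
#' maps that range affinely onto `[0, 255]` and rounds half-up to integer
#' grey levels. The result is invariant under positive affine transforms of
#' the input intensities (`a*V + b`, `a > 0`), which removes scanner gain
#' and offset differences.
#'
#' @param volume 3-D numeric intensity volume.
#' @param brain Logical volume of the same shape; statistics are computed
#'   over `volume[brain]`.
#' @return Integer-valued array in `[0, 255]` with the input's shape.
#' @export
normalize_mu3sigma <- function(volume, brain) {
  if (!identical(dim(volume), dim(brain)))
    stopf("volume and brain mask shapes differ")
  if (!any(brain)) stopf("empty brain mask")
  v <- volume[brain]
  mu <- mean(v)
  sigma <- pop_sd(v)
  if (sigma == 0) stopf("degenerate volume: zero intensity spread over brain")
  z <- (volume - mu) / sigma              # affine-invariant standard scores
  z <- pmin(pmax(z, -3), 3)
  out <- floor((z + 3) / 6 * 255 + 0.5)   # round half-up onto [0, 255]
  array(out, dim(volume))
}

#' Standardize every channel of a study
#'
#' Applies [normalize_mu3sigma()] per channel, each against its own brain
#' statistics, with the brain mask taken from the nonzero support of the
#' `t1gd` reference channel.
#'
#' @param study An [mri_study()].
#' @return The study with all channels on the common `[0, 255]` scale.
#' @export
normalize_study <- function(study) {
  stopifnot(inherits(study, "mri_study"))
  brain <- array(study$channels$t1gd > 0, dim(study$labels))
  study$channels <- lapply(study$channels, normalize_mu3sigma, brain = brain)
  study
}

#' Assign overall-survival classes
#'
#' Partitions survival times into short- (< 10 months), medium- (10 to 15
#' months, inclusive) and long-term (> 15 months) survivor groups. A month
#' is 30.4375 days (Julian year / 12) by default.
#'
#' @param os_days Positive survival times in days.
#' @param month_days Days per month used for the conversion.
#' @return Factor with levels `SHORT`, `MEDIUM`, `LONG`.
#' @export
survival_class <- function(os_days, month_days = MONTH_DAYS) {
  if (any(!is.finite(os_days)) || any(os_days <= 0))
    stopf("os_days must be positive and finite")
  months <- os_days / month_days
  cls <- ifelse(months < 10, "SHORT", ifelse(months > 15, "LONG", "MEDIUM"))
  factor(cls, levels = SURVIVAL_LEVELS)
}

#' Sort a clinical table for the cohort split
#'
#' Stable ascending sort by `(os_days, patient_id)` so duplicate survival
#' times split reproducibly.
#'
#' @param clinical Data frame with `os_days` and `patient_id` columns.
#' @return The sorted data frame.
#' @export
sort_for_split <- function(clinical) {
  clinical[order(clinical$os_days, clinical$patient_id), , drop = FALSE]
}

#' Split a survival-sorted cohort into discovery and validation sets
#'
#' With records sorted ascending by survival, every third record (1-based
#' ranks divisible by 3) goes to the validation set and the rest to the
#' discovery set, so the full survival range appears in both cohorts.
#'
#' @param clinical Data frame sorted ascending by `os_days` (see
#'   [sort_for_split()]); at least 3 rows.
#' @return List with data frames `discovery` and `validation`.
#' @export
split_discovery_validation <- function(clinical) {
  n <- nrow(clinical)
  if (n < 3L) stopf("need at least 3 records to split")
  if (is.unsorted(clinical$os_days))
    stopf("records must be sorted ascending by os_days (see sort_for_split)")
  val <- seq_len(n) %% 3L == 0L
  list(discovery = clinical[!val, , drop = FALSE],
       validation = clinical[val, , drop = FALSE])
}

#' Read / write a clinical table
#'
#' CSV with columns `patient_id`, `age_years`, `os_days`,
#' `resection_status` (one of `GTR`, `STR`, `MISSING`).
#'
#' @param path File path.
#' @return `read_clinical` returns a validated data frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "age_years", "os_days", "resection_status")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("clinical table missing column(s): %s", paste(miss, collapse = ", "))
  if (any(df$os_days <= 0)) stopf("os_days must be positive")
  if (any(df$age_years < 0 | df$age_years > 120))
    stopf("age_years out of [0, 120]")
  bad <- setdiff(unique(df$resection_status), RESECTION_LEVELS)
  if (length(bad))
    stopf("unknown resection status: %s", paste(bad, collapse = ", "))
  df
}

#' @rdname read_clinical
#' @param clinical Data frame to write.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
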