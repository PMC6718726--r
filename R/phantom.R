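# Synthetic phantom mpMRI studies: nested ellipsoidal tumor sub-regions
# inside an ellipsoidal brain, per-channel contrast, a checkerboard
# intra-tumoral texture of controllable amplitude, and Gaussian noise.

# Fixed per-(channel, region) intensity offsets, in grey units, giving each
# sub-region a distinct contrast pattern across the four channels
# (edema bright on FLAIR/T2, enhancing tumor bright on T1-Gd, core dark on
# T1). Values are arbitrary but fixed: phantom realism is not a goal.
REGION_OFFSET <- matrix(
  c(  0, -25,  10,  15,   # t1:    brain, ED, NCR/NET, ET
      0, -10, -20,  70,   # t1gd
      0,  45,  60,  20,   # t2
      0,  55,  25,  10),  # flair
  nrow = 4L, byrow = TRUE,
  dimnames = list(c("t1", "t1gd", "t2", "flair"),
                  c("brain", "ed", "ncr", "et")))

#' Phantom study configuration
#'
#' Parameters of the synthetic mpMRI phantom: grid shape, voxel spacing,
#' the three nested ellipsoid semi-axis radii (strictly
#' `at <= tc <= wt`, all smaller than half the grid extent), the
#' checkerboard texture amplitude and period, per-channel baseline
#' intensities, and the additive Gaussian noise SD.
#'
#' @param grid_shape Voxels per axis.
#' @param voxel_mm Isotropic voxel spacing (mm).
#' @param wt_radius_mm,tc_radius_mm,at_radius_mm Nested ellipsoid
#'   semi-axes (mm); scalars give spheres.
#' @param texture_contrast Checkerboard amplitude inside the whole tumor,
#'   in grey units.
#' @param checker_period_mm Checkerboard cell period (mm).
#' @param channel_baselines Named mean brain intensity per channel.
#' @param noise_sd Additive Gaussian noise SD inside the brain.
#' @param seed RNG seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64L, 64L, 48L), voxel_mm = 1,
                           wt_radius_mm = 20, tc_radius_mm = 12,
                           at_radius_mm = 6, texture_contrast = 40,
                           checker_period_mm = 4,
                           channel_baselines = c(t1 = 110, t1gd = 140,
                                                 t2 = 160, flair = 130),
                           noise_sd = 5, seed = 1L) {
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  radii <- function(r) rep_len(as.numeric(r), 3L)
  wt <- radii(wt_radius_mm); tc <- radii(tc_radius_mm); at <- radii(at_radius_mm)
  if (any(at > tc) || any(tc > wt))
    stopf("radii must be nested: at <= tc <= wt on every axis")
  if (any(wt <= 0)) stopf("radii must be positive")
  half_extent <- grid_shape * rep_len(voxel_mm, 3L) / 2
  if (any(wt >= half_extent))
    stopf("whole-tumor radius exceeds half the grid extent")
  if (!all(CHANNELS %in% names(channel_baselines)))
    stopf("channel_baselines must name all of: %s",
          paste(CHANNELS, collapse = ", "))
  if (texture_contrast < 0 || noise_sd < 0)
    stopf("texture_contrast and noise_sd must be non-negative")
  structure(list(grid_shape = grid_shape, voxel_mm = rep_len(voxel_mm, 3L),
                 wt_radius_mm = wt, tc_radius_mm = tc, at_radius_mm = at,
                 texture_contrast = texture_contrast,
                 checker_period_mm = checker_period_mm,
                 channel_baselines = channel_baselines[CHANNELS],
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

# Squared normalized ellipsoid coordinate of every voxel center relative to
# the grid center, for semi-axes `r` (mm).
ellipsoid_dist2 <- function(grid_shape, voxel_mm, r) {
  ax <- lapply(1:3, function(d) {
    x <- (seq_len(grid_shape[d]) - (grid_shape[d] + 1) / 2) * voxel_mm[d]
    (x / r[d])^2
  })
  outer(outer(ax[[1L]], ax[[2L]], `+`), ax[[3L]], `+`)
}

#' Generate one phantom study
#'
#' Builds the nested AT / TC / WT ellipsoids at the grid center, encodes
#' the BRATS-style label volume (edema 2, necrosis/non-enhancing core 1,
#' enhancing tumor 4), and renders the four channels as brain baseline plus
#' per-region contrast offsets, a checkerboard texture inside the whole
#' tumor, and Gaussian noise. Identical config and seed reproduce identical
#' voxel data; the caller's RNG state is untouched.
#'
#' @param config A [phantom_config()].
#' @param patient_id Patient id for the study.
#' @return An [mri_study()].
#' @export
generate_phantom_study <- function(config = phantom_config(),
                                   patient_id = "phantom-001") {
  stopifnot(inherits(config, "phantom_config"))
  gs <- config$grid_shape; vm <- config$voxel_mm
  brain_r <- gs * vm * 0.45
  brain <- ellipsoid_dist2(gs, vm, brain_r) <= 1
  wt <- ellipsoid_dist2(gs, vm, config$wt_radius_mm) <= 1
  tc <- ellipsoid_dist2(gs, vm, config$tc_radius_mm) <= 1
  at <- ellipsoid_dist2(gs, vm, config$at_radius_mm) <= 1
  if (!any(at) || !any(tc & !at) || !any(wt & !tc))
    stopf("radii too small for the grid: a sub-region is empty")
  labels <- array(0L, gs)
  labels[wt] <- 2L   # ED
  labels[tc] <- 1L   # NCR/NET
  labels[at] <- 4L   # ET
  # checkerboard parity of voxel positions, in mm period
  p <- max(config$checker_period_mm, vm[1L])
  ax <- lapply(1:3, function(d) floor((seq_len(gs[d]) - 1) * vm[d] / p))
  parity <- (outer(outer(ax[[1L]], ax[[2L]], `+`), ax[[3L]], `+`)) %% 2
  checker <- (2 * parity - 1) * config$texture_contrast
  region_idx <- array(1L, gs)                       # brain tissue
  region_idx[labels == 2L] <- 2L
  region_idx[labels == 1L] <- 3L
  region_idx[labels == 4L] <- 4L
  channels <- with_seed(config$seed, {
    lapply(CHANNELS, function(ch) {
      v <- array(0, gs)
      base <- config$channel_baselines[[ch]]
      v[brain] <- base + REGION_OFFSET[ch, ][region_idx[brain]]
      v[wt] <- v[wt] + checker[wt]
      if (config$noise_sd > 0)
        v[brain] <- v[brain] + stats::rnorm(sum(brain), 0, config$noise_sd)
      v[brain] <- pmax(v[brain], 1)                 # keep brain support > 0
      v
    })
  })
  names(channels) <- CHANNELS
  mri_study(patient_id, channels, labels, vm)
}
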