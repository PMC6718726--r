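# 2-D regionprops-style shape descriptors computed on a binary slice mask.

# Pixel coordinates (row, col) of a mask's TRUE pixels.
mask_coords <- function(mask2d) which(mask2d, arr.ind = TRUE)

# Second-moment ellipse descriptors of a pixel region, with the standard
# 1/12 per-pixel extent correction. Orientation is the major-axis angle in
# degrees in (-90, 90], measured from the column (horizontal) axis,
# positive counterclockwise with rows pointing down the image.
region_moments <- function(mask2d) {
  xy <- mask_coords(mask2d)
  n <- nrow(xy)
  x <- xy[, 2L]; y <- xy[, 1L]                 # x = columns, y = rows
  mu20 <- mean((x - mean(x))^2) + 1 / 12
  mu02 <- mean((y - mean(y))^2) + 1 / 12
  mu11 <- -mean((x - mean(x)) * (y - mean(y))) # y-up sign convention
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  major <- 2 * sqrt(2) * sqrt(mu20 + mu02 + common)
  minor <- 2 * sqrt(2) * sqrt(max(mu20 + mu02 - common, 0))
  theta <- if (mu20 == mu02 && mu11 == 0) 0
           else 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  list(major_axis = major, minor_axis = minor,
       eccentricity = sqrt(max(1 - (minor / major)^2, 0)),
       orientation = theta)
}

# Pixel count of the convex hull of the mask: pixels of the bounding box
# whose centers lie inside (or on) the hull polygon of the mask's pixel
# centers. Degenerate regions (< 3 non-collinear pixels) fall back to the
# mask's own area.
convex_area_px <- function(mask2d) {
  xy <- mask_coords(mask2d)
  n <- nrow(xy)
  if (n < 3L) return(n)
  hull <- grDevices::chull(xy[, 2L], xy[, 1L])
  if (length(hull) < 3L) return(n)
  hx <- xy[hull, 2L]; hy <- xy[hull, 1L]
  rr <- range(xy[, 1L]); cc <- range(xy[, 2L])
  grid <- expand.grid(r = rr[1L]:rr[2L], c = cc[1L]:cc[2L])
  inside <- rep(TRUE, nrow(grid))
  m <- length(hull)
  nxt <- c(seq_len(m)[-1L], 1L)
  # orient the edge cross-product test by the hull's signed area
  sgn <- sign(sum(hx * hy[nxt] - hx[nxt] * hy))
  if (sgn == 0) return(n)
  eps <- 1e-9
  for (k in seq_len(m)) {
    k2 <- nxt[k]
    cr <- (hx[k2] - hx[k]) * (grid$r - hy[k]) -
          (hy[k2] - hy[k]) * (grid$c - hx[k])
    inside <- inside & (sgn * cr >= -eps)
  }
  sum(inside)
}

# Fill interior holes: background pixels not connected (4-connectivity) to
# the patch border become foreground. Iterative neighbor propagation; cheap
# on cropped tumor slices.
fill_holes <- function(mask2d) {
  nr <- nrow(mask2d); nc <- ncol(mask2d)
  bg <- !mask2d
  reach <- matrix(FALSE, nr, nc)
  reach[1L, ] <- bg[1L, ]; reach[nr, ] <- bg[nr, ]
  reach[, 1L] <- bg[, 1L]; reach[, nc] <- bg[, nc]
  repeat {
    grown <- reach
    grown[-1L, ] <- grown[-1L, ] | reach[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | reach[-1L, ]
    grown[, -1L] <- grown[, -1L] | reach[, -nc]
    grown[, -nc] <- grown[, -nc] | reach[, -1L]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  mask2d | (bg & !reach)
}

# Perimeter as the count of pixel edges exposed to background
# (4-connectivity), i.e. the length of the pixel-boundary contour.
perimeter_px <- function(mask2d) {
  nr <- nrow(mask2d); nc <- ncol(mask2d)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask2d
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  sum(core & !pad[1:nr, 2:(nc + 1L)]) +
    sum(core & !pad[3:(nr + 2L), 2:(nc + 1L)]) +
    sum(core & !pad[2:(nr + 1L), 1:nc]) +
    sum(core & !pad[2:(nr + 1L), 3:(nc + 2L)])
}

#' Shape features of a tumor sub-region
#'
#' Fourteen geometry descriptors: the tumor and brain volumes (3-D voxel
#' counts times voxel volume, mm^3) and their ratio; the convex, filled,
#' mask and brain areas on the selected axial slice (mm^2) and the
#' tumor-to-brain area ratio; and six 2-D region descriptors of the slice
#' mask (eccentricity, orientation in degrees, equivalent diameter in mm,
#' solidity, extent, perimeter in mm).
#'
#' @param region3d Logical tumor sub-region volume.
#' @param brain3d Logical brain-support volume.
#' @param slice_index Axial slice on which 2-D descriptors are computed
#'   (see [select_slice()]).
#' @param voxel_mm Voxel spacing per axis (mm).
#' @return Named numeric vector of length 14.
#' @export
shape_features <- function(region3d, brain3d, slice_index,
                           voxel_mm = c(1, 1, 1)) {
  vox_vol <- prod(voxel_mm)
  pix_area <- voxel_mm[1L] * voxel_mm[2L]
  pix_side <- sqrt(pix_area)
  mask2d <- region3d[, , slice_index]
  if (!any(mask2d)) stopf("empty region on the selected slice")
  area_px <- sum(mask2d)
  conv_px <- convex_area_px(mask2d)
  fill_px <- sum(fill_holes(mask2d))
  brain2d_px <- sum(brain3d[, , slice_index])
  xy <- mask_coords(mask2d)
  bbox_px <- (diff(range(xy[, 1L])) + 1L) * (diff(range(xy[, 2L])) + 1L)
  mom <- region_moments(mask2d)
  c(TumorVolume = sum(region3d) * vox_vol,
    BrainVolume = sum(brain3d) * vox_vol,
    TumorToBrainVolumeRatio = sum(region3d) / sum(brain3d),
    TumorConvexArea = conv_px * pix_area,
    TumorFilledArea = fill_px * pix_area,
    TumorArea = area_px * pix_area,
    BrainArea = brain2d_px * pix_area,
    TumorToBrainAreaRatio = area_px / brain2d_px,
    Eccentricity = mom$eccentricity,
    Orientation = mom$orientation,
    EquivalentDiameter = sqrt(4 * area_px * pix_area / pi),
    Solidity = area_px / conv_px,
    Extent = area_px / bbox_px,
    Perimeter = perimeter_px(mask2d) * pix_side)
}
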