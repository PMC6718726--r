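test_that("slice selection maximizes in-slice area with low-index ties", {
  m <- array(FALSE, c(5, 5, 5))
  m[2, 3, 4] <- TRUE
  expect_identical(select_slice(m), 4L)
  # ellipsoid: equatorial slice has the largest cross-section
  cfg <- phantom_config(seed = 1)
  s <- generate_phantom_study(cfg)
  masks <- tumor_masks(s)
  expect_identical(select_slice(masks$wt), 24L)   # grid 48 deep, centered
  tie <- array(FALSE, c(4, 4, 4))
  tie[1:2, 1:2, 2] <- TRUE; tie[1:2, 1:2, 3] <- TRUE
  expect_identical(select_slice(tie), 2L)
  expect_error(select_slice(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("ROI cropping keeps the tight bounding box and mask", {
  img <- matrix(1:36, 6, 6)
  full <- matrix(TRUE, 6, 6)
  roi <- crop_roi(img, full)
  expect_identical(roi$image2d, img)
  expect_identical(roi$bounding_box, c(0L, 0L, 6L, 6L))
  single <- matrix(FALSE, 6, 6); single[3, 4] <- TRUE
  roi1 <- crop_roi(img, single)
  expect_identical(dim(roi1$image2d), c(1L, 1L))
  expect_identical(roi1$image2d[1, 1], img[3, 4])
  # L-shaped mask: box covers the L, mask preserves it
  L <- matrix(FALSE, 6, 6)
  L[2:5, 2] <- TRUE; L[5, 2:4] <- TRUE
  roiL <- crop_roi(img, L)
  expect_identical(dim(roiL$mask2d), c(4L, 3L))
  expect_identical(sum(roiL$mask2d), sum(L))
  expect_false(roiL$mask2d[1, 3])
})

test_that("intensity statistics match hand arithmetic", {
  f <- intensity_features(c(5, 5, 5, 5))
  expect_equal(unname(f[c("MinimumIntensity", "MaximumIntensity",
                          "MedianIntensity", "MeanIntensity")]),
               rep(5, 4))
  expect_equal(unname(f["Range"]), 0)
  expect_equal(unname(f["Variance"]), 0)
  expect_equal(unname(f["Entropy"]), 0)
  f2 <- intensity_features(c(1, 2, 3, 4))
  expect_equal(unname(f2["MeanIntensity"]), 2.5)
  expect_equal(unname(f2["Range"]), 3)
  expect_equal(unname(f2["RMS"]), sqrt(7.5))
  expect_equal(unname(f2["Moment2nd"]), 1.25)
  expect_equal(unname(f2["Moment3rd"]), 0)
  # fair-coin histogram carries one bit
  f3 <- intensity_features(rep(c(0, 255), 8))
  expect_equal(unname(f3["Entropy"]), 1)
})

test_that("shape descriptors recover closed-form geometry", {
  # single voxel at 1 mm isotropic spacing
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  brain <- array(TRUE, c(5, 5, 5))
  f <- shape_features(one, brain, 3L)
  expect_equal(unname(f["TumorVolume"]), 1)
  expect_equal(unname(f["BrainVolume"]), 125)
  # 10 x 20 filled rectangle
  rect <- array(FALSE, c(30, 30, 3))
  rect[6:15, 6:25, 2] <- TRUE
  f2 <- shape_features(rect, array(TRUE, c(30, 30, 3)), 2L)
  expect_equal(unname(f2["Extent"]), 1)
  expect_equal(unname(f2["EquivalentDiameter"]), sqrt(4 * 200 / pi))
  expect_equal(unname(f2["Solidity"]), 1)
  expect_equal(unname(f2["TumorArea"]), 200)
  expect_equal(unname(f2["Perimeter"]), 60)
  # filled disc: near-zero eccentricity, solidity about 1
  disc <- array(FALSE, c(41, 41, 3))
  ctr <- 21
  for (r in 1:41) for (c in 1:41)
    if ((r - ctr)^2 + (c - ctr)^2 <= 15^2) disc[r, c, 2] <- TRUE
  f3 <- shape_features(disc, array(TRUE, c(41, 41, 3)), 2L)
  expect_lt(unname(f3["Eccentricity"]), 0.1)
  expect_gt(unname(f3["Solidity"]), 0.95)
})

test_that("joint volume ratios follow the mask counts", {
  mk <- function(nwt, ntc, nat) {
    a <- array(FALSE, c(4, 4, 4))
    wt <- a; wt[seq_len(nwt)] <- TRUE
    tc <- a; tc[seq_len(ntc)] <- TRUE
    at <- a; at[seq_len(nat)] <- TRUE
    list(wt = wt, tc = tc, at = at)
  }
  expect_equal(unname(joint_shape_features(mk(4, 4, 4))), c(1, 1, 1))
  expect_equal(unname(joint_shape_features(mk(4, 2, 1))), c(0.25, 0.5, 0.5))
  f <- joint_shape_features(mk(4, 2, 0))
  expect_equal(unname(f), c(0, 0.5, 0))
})

test_that("extraction yields the full, correctly named 147-vector", {
  s <- generate_phantom_study(phantom_config(seed = 2))
  fv <- extract_features(s)
  expect_length(fv, 147L)
  expect_true(all(is.finite(fv)))
  man <- feature_manifest()
  expect_identical(names(fv), man$name)
  expect_identical(sum(man$region == "WT"), 48L)
  expect_identical(sum(man$region == "TC"), 48L)
  expect_identical(sum(man$region == "AT"), 48L)
  expect_identical(names(fv)[139], "T2_TC_SumHOG_F139")
  expect_match(names(fv)[139], "^T2_TC_")
  expect_match(names(fv)[139], "_F139$")
  # extraction is deterministic
  expect_identical(fv, extract_features(s))
})

test_that("empty sub-regions get the policy value, vector stays 147 long", {
  s <- make_toy_study(label_values = c(1L, 2L))   # no enhancing tumor
  fv <- extract_features(s)
  expect_length(fv, 147L)
  at_idx <- which(feature_manifest()$region == "AT")
  expect_true(all(fv[at_idx] == 0))
  expect_identical(attr(fv, "qc_empty_regions"), "AT")
  other <- fv[setdiff(seq_len(147), at_idx)]
  expect_true(all(is.finite(other)))
})

test_that("the feature cohort table matches the manifest", {
  studies <- list(generate_phantom_study(phantom_config(seed = 1), "a"),
                  generate_phantom_study(phantom_config(seed = 2), "b"))
  tab <- extract_cohort(studies)
  expect_identical(dim(tab), c(2L, 148L))
  expect_identical(tab$patient_id, c("a", "b"))
  expect_identical(colnames(tab)[-1], feature_manifest()$name)
})
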