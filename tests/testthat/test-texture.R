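random_patch <- function(n = 8L) {
  matrix(sample(0:255, n * n, replace = TRUE), n, n)
}

test_that("co-occurrence matrices match hand-enumerated cases", {
  const <- matrix(100, 4, 4)
  mask <- matrix(TRUE, 4, 4)
  P <- glcm_matrix(const, mask, levels = 8)
  expect_equal(sum(P), 1)
  expect_equal(sum(diag(P)), 1)            # all mass on one diagonal cell
  expect_equal(sum(P > 0), 1L)
  # 2x2 two-level checkerboard at 0 degrees: both ordered pairs cross
  chk <- matrix(c(0, 255, 255, 0), 2, 2)
  P2 <- glcm_matrix(chk, matrix(TRUE, 2, 2), levels = 2)
  expect_equal(P2[1, 2], 0.5)
  expect_equal(P2[2, 1], 0.5)
  expect_equal(P2[1, 1] + P2[2, 2], 0)
  expect_error(glcm_matrix(matrix(5, 1, 1), matrix(TRUE, 1, 1)),
               "degenerate")
})

test_that("GLCM matrices and statistics equal the brute-force oracle", {
  set.seed(11)
  for (rep in 1:25) {
    img <- random_patch()
    mask <- matrix(runif(64) > 0.2, 8, 8)
    if (sum(mask) < 4) next
    for (offs in list(list(c(0L, 1L)), list(c(0L, 1L), c(-1L, 1L)))) {
      P <- glcm_matrix(img, mask, levels = 8, offsets = offs)
      O <- oracle_glcm(img, mask, levels = 8, offsets = offs)
      expect_equal(P, O, tolerance = 1e-12)
      got <- radiosurv:::glcm_stats(P)
      want <- oracle_glcm_stats(P)
      for (nm in names(want))
        expect_equal(unname(got[[nm]]), want[[nm]], tolerance = 1e-10)
    }
  }
})

test_that("GLCM features behave on degenerate and checkerboard textures", {
  const <- matrix(100, 6, 6)
  f <- glcm_features(const, matrix(TRUE, 6, 6))
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["Energy"]), 1)
  expect_equal(unname(f["Homogeneity"]), 1)
  expect_equal(unname(f["GLCMEntropy"]), 0)
  # two-level checkerboard: all 0-degree mass one level distance apart,
  # so contrast equals the squared level distance (levels 1 and 8)
  chk <- matrix(0, 8, 8); chk[(row(chk) + col(chk)) %% 2 == 1] <- 255
  f2 <- glcm_features(chk, matrix(TRUE, 8, 8))
  expect_equal(unname(f2["Contrast"]), 49)
  expect_equal(unname(f2["GLCMRange"]),
               max(f2[1:13]) - min(f2[1:13]))
})

test_that("accumulated-offset statistics are more rotation-stable", {
  # horizontal stripes vs their 45-degree rotation (diagonal stripes)
  horiz <- matrix(0, 12, 12); horiz[row(horiz) %% 2 == 1] <- 255
  diag45 <- matrix(0, 12, 12)
  diag45[(row(diag45) + col(diag45)) %% 2 == 1] <- 255
  mask <- matrix(TRUE, 12, 12)
  f_h <- glcm_features(horiz, mask)
  f_d <- glcm_features(diag45, mask)
  # single-offset counterparts of the four "...2" statistics
  single <- function(img) {
    P0 <- glcm_matrix(img, mask, levels = 8)
    s <- radiosurv:::glcm_stats(P0)
    c(s[["sum_entropy"]], s[["difference_entropy"]],
      s[["sum_variance"]], s[["difference_variance"]])
  }
  change_single <- sum(abs(single(horiz) - single(diag45)))
  two_names <- c("SumEntropy2", "DifferenceEntropy2", "SumVariance2",
                 "DifferenceVariance2")
  change_two <- sum(abs(f_h[two_names] - f_d[two_names]))
  expect_lt(change_two, change_single)
})

test_that("HOG features match their contracts", {
  const <- matrix(7, 16, 16)
  f <- hog_features(const)
  expect_equal(unname(f), c(0, 0, 0))
  # vertical step edge: gradient energy concentrated in one orientation
  step <- matrix(0, 16, 16); step[, 9:16] <- 200
  d <- hog_descriptor(step)
  f2 <- hog_features(step)
  expect_gt(f2[["SumHOG"]], 0)
  # each block vector is laid out as (2 x 2 cells) x 9 bins
  arr <- array(d, c(4L, 9L, length(d) / 36L))
  by_orientation <- apply(arr, 2L, sum)
  # one bin carries all gradient mass for a pure vertical edge
  expect_equal(sum(by_orientation > 1e-9), 1L)
  # summaries are consistent with the raw descriptor
  expect_equal(f2[["SumHOG"]], sum(d))
  expect_equal(f2[["MedianHOG"]], median(d))
  expect_equal(f2[["StdHOG"]], sd(d))
})

test_that("LBP histograms match the brute-force oracle", {
  const <- matrix(9, 6, 6)
  inner <- matrix(FALSE, 6, 6); inner[2:5, 2:5] <- TRUE
  h <- lbp_histogram(const, inner)
  expect_equal(sum(h), 1)
  expect_equal(sum(h > 0), 1L)              # single pattern for flat texture
  set.seed(13)
  for (rep in 1:25) {
    img <- random_patch()
    mask <- matrix(runif(64) > 0.25, 8, 8)
    if (!any(mask)) next
    expect_equal(lbp_histogram(img, mask), oracle_lbp_hist(img, mask),
                 tolerance = 1e-12)
    expect_equal(sum(lbp_histogram(img, mask)), 1)
  }
})
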