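# Grey-level co-occurrence, oriented-gradient and local-binary-pattern
# texture descriptors for 2-D region-of-interest patches on the 8-bit scale.

#' Quantize 8-bit grey levels into co-occurrence levels
#'
#' Uniformly bins `[0, 255]` into `levels` grey levels, returning integer
#' levels in `1..levels`.
#'
#' @param image2d Numeric matrix in `[0, 255]`.
#' @param levels Number of grey levels (default 8).
#' @return Integer matrix of level indices.
#' @export
quantize_grey <- function(image2d, levels = 8L) {
  if (levels < 2L) stopf("need at least 2 grey levels")
  q <- floor(image2d * levels / 256)
  matrix(as.integer(pmin(pmax(q, 0), levels - 1L)) + 1L, nrow(image2d))
}

#' Grey-level co-occurrence matrix
#'
#' Counts ordered pairs `(p, p + offset)` of grey levels with both pixels
#' inside the mask, accumulated over all offsets, symmetrized by adding the
#' transpose, and normalized to sum 1. Offsets are `(drow, dcol)`
#' displacements: `c(0, 1)` is the 0-degree direction and `c(-1, 1)` the
#' 45-degree direction.
#'
#' @param image2d Numeric matrix in `[0, 255]`.
#' @param mask2d Logical matrix of the same shape.
#' @param levels Grey-level count for quantization.
#' @param offsets List of integer `(drow, dcol)` displacement vectors.
#' @param symmetric Add the transposed counts (default `TRUE`).
#' @param normalize Normalize counts to probabilities (default `TRUE`).
#' @return `levels` x `levels` co-occurrence matrix.
#' @export
glcm_matrix <- function(image2d, mask2d, levels = 8L,
                        offsets = list(c(0L, 1L)), symmetric = TRUE,
                        normalize = TRUE) {
  if (!identical(dim(image2d), dim(mask2d)))
    stopf("image and mask shapes differ")
  if (!length(offsets)) stopf("need at least one offset")
  q <- quantize_grey(image2d, levels)
  nr <- nrow(q); nc <- ncol(q)
  counts <- matrix(0, levels, levels)
  for (off in offsets) {
    dr <- off[[1L]]; dc <- off[[2L]]
    if (max(1L, 1L - dr) > min(nr, nr - dr) ||
        max(1L, 1L - dc) > min(nc, nc - dc)) next
    r0 <- max(1L, 1L - dr):min(nr, nr - dr)
    c0 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- q[r0, c0, drop = FALSE]
    b <- q[r0 + dr, c0 + dc, drop = FALSE]
    ok <- mask2d[r0, c0, drop = FALSE] & mask2d[r0 + dr, c0 + dc, drop = FALSE]
    if (!any(ok)) next
    lin <- (b[ok] - 1L) * levels + a[ok]
    counts <- counts + matrix(tabulate(lin, nbins = levels^2), levels)
  }
  if (sum(counts) == 0)
    stopf("degenerate texture: no valid pixel pairs under the given offsets")
  if (symmetric) counts <- counts + t(counts)
  if (normalize) counts <- counts / sum(counts)
  counts
}

# Haralick-style statistics of one normalized co-occurrence matrix.
# Level indices i, j run 1..L; marginals p_{x+y}, p_{x-y} as in the
# classical definitions; entropies in bits; correlation is 0 for a
# degenerate (zero-spread) matrix.
glcm_stats <- function(P) {
  L <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mx <- sum(seq_len(L) * px); my <- sum(seq_len(L) * py)
  sx <- sqrt(sum((seq_len(L) - mx)^2 * px))
  sy <- sqrt(sum((seq_len(L) - my)^2 * py))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  # p_{x+y}(k), k = 2..2L ; p_{x-y}(k), k = 0..L-1
  psum <- vapply(2:(2 * L), function(k) sum(P[i + j == k]), 0)
  pdif <- vapply(0:(L - 1), function(k) sum(P[abs(i - j) == k]), 0)
  ks <- 2:(2 * L); kd <- 0:(L - 1)
  sum_avg <- sum(ks * psum)
  dif_avg <- sum(kd * pdif)
  c(contrast = sum((i - j)^2 * P),
    correlation = if (sx > 0 && sy > 0)
      (sum(i * j * P) - mx * my) / (sx * sy) else 0,
    energy = sum(P^2),
    homogeneity = sum(P / (1 + abs(i - j))),
    sum_variance = sum((ks - sum_avg)^2 * psum),
    sum_average = sum_avg,
    variance = sum((i - mx)^2 * P),
    autocorrelation = sum(i * j * P),
    entropy = ent(P),
    sum_entropy = ent(psum),
    difference_entropy = ent(pdif),
    difference_variance = sum((kd - dif_avg)^2 * pdif))
}

#' GLCM texture features of a patch
#'
#' Computes 14 co-occurrence statistics: contrast, correlation, energy,
#' homogeneity, sum variance, sum average, variance, autocorrelation and
#' entropy from the 0-degree matrix (offset `(0, 1)`); sum entropy,
#' difference entropy, sum variance and difference variance (the "...2"
#' statistics) from a single matrix accumulated over the 0- and 45-degree
#' offsets `{(0, 1), (-1, 1)}`; and the range (max - min) over the other 13
#' values.
#'
#' @inheritParams glcm_matrix
#' @param accumulate_offsets If `TRUE` (default) the "...2" statistics use
#'   one matrix accumulated over both offsets; if `FALSE` they average the
#'   per-offset statistics instead.
#' @return Named numeric vector of length 14.
#' @export
glcm_features <- function(image2d, mask2d, levels = 8L,
                          accumulate_offsets = TRUE) {
  P0 <- glcm_matrix(image2d, mask2d, levels, offsets = list(c(0L, 1L)))
  base <- glcm_stats(P0)
  two <- if (accumulate_offsets) {
    glcm_stats(glcm_matrix(image2d, mask2d, levels,
                           offsets = list(c(0L, 1L), c(-1L, 1L))))
  } else {
    P45 <- glcm_matrix(image2d, mask2d, levels, offsets = list(c(-1L, 1L)))
    (glcm_stats(P0) + glcm_stats(P45)) / 2
  }
  out <- c(Contrast = unname(base["contrast"]),
           Correlation = unname(base["correlation"]),
           Energy = unname(base["energy"]),
           Homogeneity = unname(base["homogeneity"]),
           SumVariance = unname(base["sum_variance"]),
           SumAverage = unname(base["sum_average"]),
           GLCMVariance = unname(base["variance"]),
           Autocorrelation = unname(base["autocorrelation"]),
           GLCMEntropy = unname(base["entropy"]),
           SumEntropy2 = unname(two["sum_entropy"]),
           DifferenceEntropy2 = unname(two["difference_entropy"]),
           SumVariance2 = unname(two["sum_variance"]),
           DifferenceVariance2 = unname(two["difference_variance"]))
  c(out, GLCMRange = max(out) - min(out))
}

#' Histogram-of-oriented-gradients descriptor
#'
#' Computes a dense HOG descriptor of the masked patch: background pixels
#' are zeroed, the patch is zero-padded to at least 16 x 16 and to a
#' multiple of the cell size, gradients are taken with centered `[-1, 0, 1]`
#' differences (one-sided at the borders), gradient magnitudes are
#' accumulated
#' into 9 unsigned orientation bins per 8 x 8 cell, and 2 x 2-cell blocks
#' (stride one cell) are L2-normalized and concatenated.
#'
#' @param image2d Numeric matrix.
#' @param mask2d Logical matrix; background is zeroed before gradients.
#' @param cell Cell size in pixels.
#' @param block Block size in cells.
#' @param bins Number of unsigned orientation bins over `[0, 180)` degrees.
#' @return Numeric descriptor vector.
#' @export
hog_descriptor <- function(image2d, mask2d = NULL, cell = 8L, block = 2L,
                           bins = 9L) {
  img <- if (is.null(mask2d)) image2d else image2d * mask2d
  # pad to >= block*cell and to a multiple of the cell size
  target <- function(n) max(block * cell, cell * ceiling(n / cell))
  nr <- target(nrow(img)); nc <- target(ncol(img))
  pad <- matrix(0, nr, nc)
  pad[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  img <- pad
  z <- matrix(0, nr, nc)
  gx <- z; gy <- z
  gx[, 2:(nc - 1)] <- img[, 3:nc] - img[, 1:(nc - 2)]
  gx[, 1] <- img[, 2] - img[, 1]; gx[, nc] <- img[, nc] - img[, nc - 1]
  gy[2:(nr - 1), ] <- img[3:nr, ] - img[1:(nr - 2), ]
  gy[1, ] <- img[2, ] - img[1, ]; gy[nr, ] <- img[nr, ] - img[nr - 1, ]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180                       # unsigned orientations
  bin <- pmin(floor(ang / (180 / bins)), bins - 1L) + 1L
  cr <- (row(img) - 1L) %/% cell + 1L
  cc <- (col(img) - 1L) %/% cell + 1L
  ncr <- nr %/% cell; ncc <- nc %/% cell
  hist <- array(0, c(ncr, ncc, bins))
  idx <- cbind(as.vector(cr), as.vector(cc), as.vector(bin))
  w <- as.vector(mag)
  keep <- w > 0
  if (any(keep)) {
    idx <- idx[keep, , drop = FALSE]; w <- w[keep]
    lin <- (idx[, 3L] - 1L) * ncr * ncc + (idx[, 2L] - 1L) * ncr + idx[, 1L]
    tab <- rowsum(w, lin)
    hist[as.integer(rownames(tab))] <- tab
  }
  desc <- numeric(0)
  for (br in seq_len(max(ncr - block + 1L, 1L)))
    for (bc in seq_len(max(ncc - block + 1L, 1L))) {
      v <- as.vector(hist[br:(br + block - 1L), bc:(bc + block - 1L), ])
      nrm <- sqrt(sum(v^2))
      desc <- c(desc, if (nrm > 0) v / nrm else v)
    }
  desc
}

#' HOG summary features
#'
#' Sum, median and standard deviation of the [hog_descriptor()] vector.
#'
#' @inheritParams hog_descriptor
#' @return Named numeric vector `SumHOG`, `MedianHOG`, `StdHOG`.
#' @export
hog_features <- function(image2d, mask2d = NULL) {
  d <- hog_descriptor(image2d, mask2d)
  c(SumHOG = sum(d), MedianHOG = stats::median(d),
    StdHOG = if (length(d) > 1L) stats::sd(d) else 0)
}

# Circular neighbor offsets for 8-neighbor radius-1 LBP, in angular order.
LBP_OFFSETS <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
                    c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))

# Map 0..255 LBP codes to the 59-bin uniform coding (58 uniform patterns in
# ascending code order, plus one catch-all bin).
lbp_uniform_map <- function() {
  codes <- 0:255
  transitions <- vapply(codes, function(code) {
    bits <- as.integer(intToBits(code))[1:8]
    sum(bits != bits[c(2:8, 1)])
  }, 0L)
  map <- integer(256)
  uniform <- which(transitions <= 2L)
  map[uniform] <- seq_along(uniform)
  map[transitions > 2L] <- length(uniform) + 1L
  map
}

#' Uniform local-binary-pattern histogram
#'
#' Computes the 8-neighbor, radius-1 LBP code of every masked pixel
#' (neighbors outside the patch count as zero-intensity background, so
#' background pixels are used as neighbors but never contribute codes) and
#' returns the normalized 59-bin uniform-pattern histogram.
#'
#' @param image2d Numeric matrix.
#' @param mask2d Logical matrix; codes are computed for masked pixels only.
#' @return Numeric vector of 59 bin probabilities summing to 1.
#' @export
lbp_histogram <- function(image2d, mask2d = NULL) {
  if (is.null(mask2d)) mask2d <- matrix(TRUE, nrow(image2d), ncol(image2d))
  nr <- nrow(image2d); nc <- ncol(image2d)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- image2d
  center <- image2d
  code <- matrix(0L, nr, nc)
  for (k in seq_along(LBP_OFFSETS)) {
    off <- LBP_OFFSETS[[k]]
    nb <- pad[(2:(nr + 1L)) + off[1L], (2:(nc + 1L)) + off[2L], drop = FALSE]
    code <- code + (nb >= center) * 2L^(k - 1L)
  }
  map <- lbp_uniform_map()
  bins <- map[code[mask2d] + 1L]
  if (!length(bins)) stopf("empty mask: no LBP codes")
  h <- tabulate(bins, nbins = 59L)
  h / sum(h)
}

#' LBP summary features
#'
#' Sum, mean and standard deviation of the normalized [lbp_histogram()]
#' vector (the sum is 1 by construction).
#'
#' @inheritParams lbp_histogram
#' @return Named numeric vector `SumLBP`, `MeanLBP`, `StdLBP`.
#' @export
lbp_features <- function(image2d, mask2d = NULL) {
  h <- lbp_histogram(image2d, mask2d)
  c(SumLBP = sum(h), MeanLBP = mean(h), StdLBP = stats::sd(h))
}
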