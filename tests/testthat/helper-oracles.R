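# Brute-force oracles and small fixture builders, independent of the
# package's vectorized implementations.

# Enumerate co-occurring pixel pairs one by one.
oracle_glcm <- function(img, mask, levels = 8L, offsets = list(c(0L, 1L)),
                        symmetric = TRUE) {
  q <- floor(img * levels / 256)
  q <- pmin(pmax(q, 0), levels - 1) + 1
  counts <- matrix(0, levels, levels)
  for (off in offsets)
    for (r in seq_len(nrow(img)))
      for (c in seq_len(ncol(img))) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img) &&
            mask[r, c] && mask[r2, c2])
          counts[q[r, c], q[r2, c2]] <- counts[q[r, c], q[r2, c2]] + 1
      }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# Textbook Haralick definitions evaluated with explicit loops.
oracle_glcm_stats <- function(P) {
  L <- nrow(P)
  mu_x <- 0; mu_y <- 0
  for (i in 1:L) for (j in 1:L) { mu_x <- mu_x + i * P[i, j]
                                  mu_y <- mu_y + j * P[i, j] }
  s_x <- 0; s_y <- 0
  for (i in 1:L) for (j in 1:L) { s_x <- s_x + (i - mu_x)^2 * P[i, j]
                                  s_y <- s_y + (j - mu_y)^2 * P[i, j] }
  s_x <- sqrt(s_x); s_y <- sqrt(s_y)
  contrast <- 0; energy <- 0; homog <- 0; entropy <- 0; acor <- 0
  varc <- 0; corr_num <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    contrast <- contrast + (i - j)^2 * p
    energy <- energy + p^2
    homog <- homog + p / (1 + abs(i - j))
    if (p > 0) entropy <- entropy - p * log2(p)
    acor <- acor + i * j * p
    varc <- varc + (i - mu_x)^2 * p
    corr_num <- corr_num + (i - mu_x) * (j - mu_y) * p
  }
  psum <- numeric(2 * L - 1)   # index k-1 for k = 2..2L
  pdif <- numeric(L)           # index k+1 for k = 0..L-1
  for (i in 1:L) for (j in 1:L) {
    psum[i + j - 1] <- psum[i + j - 1] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  sum_avg <- 0
  for (k in 2:(2 * L)) sum_avg <- sum_avg + k * psum[k - 1]
  sum_var <- 0; sum_ent <- 0
  for (k in 2:(2 * L)) {
    sum_var <- sum_var + (k - sum_avg)^2 * psum[k - 1]
    if (psum[k - 1] > 0) sum_ent <- sum_ent - psum[k - 1] * log2(psum[k - 1])
  }
  dif_avg <- 0
  for (k in 0:(L - 1)) dif_avg <- dif_avg + k * pdif[k + 1]
  dif_var <- 0; dif_ent <- 0
  for (k in 0:(L - 1)) {
    dif_var <- dif_var + (k - dif_avg)^2 * pdif[k + 1]
    if (pdif[k + 1] > 0) dif_ent <- dif_ent - pdif[k + 1] * log2(pdif[k + 1])
  }
  list(contrast = contrast,
       correlation = if (s_x > 0 && s_y > 0) corr_num / (s_x * s_y) else 0,
       energy = energy, homogeneity = homog, sum_variance = sum_var,
       sum_average = sum_avg, variance = varc, autocorrelation = acor,
       entropy = entropy, sum_entropy = sum_ent,
       difference_entropy = dif_ent, difference_variance = dif_var)
}

# Per-pixel neighbor thresholding with an independently built uniform map.
oracle_lbp_hist <- function(img, mask) {
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  is_uniform <- function(code) {
    bits <- as.integer(intToBits(code))[1:8]
    sum(abs(diff(c(bits, bits[1])))) <= 2
  }
  uniform_codes <- Filter(is_uniform, 0:255)
  hist <- numeric(59)
  for (r in seq_len(nrow(img)))
    for (c in seq_len(ncol(img))) {
      if (!mask[r, c]) next
      code <- 0
      for (k in seq_along(offs)) {
        r2 <- r + offs[[k]][1]; c2 <- c + offs[[k]][2]
        nb <- if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img))
          img[r2, c2] else 0
        if (nb >= img[r, c]) code <- code + 2^(k - 1)
      }
      bin <- if (code %in% uniform_codes) match(code, uniform_codes) else 59
      hist[bin] <- hist[bin] + 1
    }
  hist / sum(hist)
}

# Tiny study with hand-placed labels for mask/extraction tests.
make_toy_study <- function(label_values = c(1L, 2L, 4L), dim3 = c(12L, 12L, 8L),
                           seed = 42L) {
  labels <- array(0L, dim3)
  # a small nested blob in the middle slice neighborhood
  mid <- dim3[3] %/% 2
  if (2L %in% label_values) labels[4:9, 4:9, (mid - 1):(mid + 1)] <- 2L
  if (1L %in% label_values) labels[5:8, 5:8, mid:(mid + 1)] <- 1L
  if (4L %in% label_values) labels[6:7, 6:7, mid] <- 4L
  set.seed(seed)
  mkch <- function(base) {
    v <- array(0, dim3)
    brain <- array(TRUE, dim3)
    v[] <- base + rnorm(prod(dim3), 0, 8)
    v <- pmax(v, 1)
    v
  }
  mri_study("toy-001",
            channels = list(t1 = mkch(100), t1gd = mkch(140),
                            t2 = mkch(160), flair = mkch(130)),
            labels = labels)
}
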