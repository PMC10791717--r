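# Independent brute-force oracles: deliberately naive double loops over
# pixels/levels, sharing no code with the package implementation.

oracle_dilate <- function(mask, offsets) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (i in seq_len(nrow(offsets))) {
      rr <- r - offsets[i, 1]; cc <- c - offsets[i, 2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && mask[rr, cc]) {
        out[r, c] <- TRUE
        break
      }
    }
  }
  out
}

oracle_erode <- function(mask, offsets) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(TRUE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (i in seq_len(nrow(offsets))) {
      rr <- r + offsets[i, 1]; cc <- c + offsets[i, 2]
      inside <- rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && mask[rr, cc]
      if (!inside) {
        out[r, c] <- FALSE
        break
      }
    }
  }
  out
}

oracle_periwound <- function(mask, offsets) {
  oracle_dilate(mask, offsets) & !oracle_erode(mask, offsets)
}

# Naive Haralick f1-f13 from a normalized L x L GLCM: explicit double sums,
# grey values 0..L-1, logs base 2, 0 log 0 = 0.
oracle_haralick <- function(p) {
  L <- nrow(p)
  lg <- function(x) if (x > 0) log2(x) else 0
  px <- numeric(L); py <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:L) {
    mux <- mux + (i - 1) * px[i]
    muy <- muy + (i - 1) * py[i]
  }
  sdx <- 0; sdy <- 0
  for (i in 1:L) {
    sdx <- sdx + (i - 1 - mux)^2 * px[i]
    sdy <- sdy + (i - 1 - muy)^2 * py[i]
  }
  sdx <- sqrt(sdx); sdy <- sqrt(sdy)
  psum <- numeric(2 * L - 1)   # index k+1, k = i+j in 0..2L-2
  pdiff <- numeric(L)          # index k+1, k = |i-j| in 0..L-1
  for (i in 1:L) for (j in 1:L) {
    psum[(i - 1) + (j - 1) + 1] <- psum[(i - 1) + (j - 1) + 1] + p[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
  }
  f1 <- 0; f2 <- 0; f3n <- 0; f4 <- 0; f5 <- 0; f9 <- 0
  for (i in 1:L) for (j in 1:L) {
    f1 <- f1 + p[i, j]^2
    f3n <- f3n + (i - 1) * (j - 1) * p[i, j]
    f4 <- f4 + (i - 1 - mux)^2 * p[i, j]
    f5 <- f5 + p[i, j] / (1 + (i - j)^2)
    f9 <- f9 - p[i, j] * lg(p[i, j])
  }
  for (k in 0:(L - 1)) f2 <- f2 + k^2 * pdiff[k + 1]
  f3 <- if (sdx > 0 && sdy > 0) (f3n - mux * muy) / (sdx * sdy) else 0
  f6 <- 0
  for (k in 0:(2 * L - 2)) f6 <- f6 + k * psum[k + 1]
  f7 <- 0; f8 <- 0
  for (k in 0:(2 * L - 2)) {
    f7 <- f7 + (k - f6)^2 * psum[k + 1]
    f8 <- f8 - psum[k + 1] * lg(psum[k + 1])
  }
  mud <- 0
  for (k in 0:(L - 1)) mud <- mud + k * pdiff[k + 1]
  f10 <- 0; f11 <- 0
  for (k in 0:(L - 1)) {
    f10 <- f10 + (k - mud)^2 * pdiff[k + 1]
    f11 <- f11 - pdiff[k + 1] * lg(pdiff[k + 1])
  }
  hx <- 0; hy <- 0
  for (i in 1:L) {
    hx <- hx - px[i] * lg(px[i])
    hy <- hy - py[i] * lg(py[i])
  }
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    hxy1 <- hxy1 - p[i, j] * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  f12 <- if (max(hx, hy) > 0) (f9 - hxy1) / max(hx, hy) else 0
  f13 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - f9) * log(2))))
  c(angular_second_moment = f1, contrast = f2, correlation = f3,
    sum_of_squares_variance = f4, inverse_difference_moment = f5,
    sum_average = f6, sum_variance = f7, sum_entropy = f8, entropy = f9,
    difference_variance = f10, difference_entropy = f11,
    info_measure_correlation_1 = f12, info_measure_correlation_2 = f13)
}

# Rank-difference Spearman for distinct values (no ties).
oracle_spearman <- function(a, b) {
  d <- rank(a) - rank(b)
  n <- length(a)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

random_mask <- function(nr, nc, p = 0.4) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

random_image <- function(nr, nc) {
  arr <- array(sample.int(256L, nr * nc * 3L, replace = TRUE) - 1L,
               dim = c(nr, nc, 3L))
  storage.mode(arr) <- "integer"
  arr
}
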