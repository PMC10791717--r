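#' Convert an RGB image to 8-bit grayscale
#'
#' ITU-R BT.601 luma: `0.299 R + 0.587 G + 0.114 B`, rounded to the nearest
#' integer in \[0, 255\].
#'
#' @param image Integer array `h x w x 3` in \[0, 255\].
#' @return Integer matrix `h x w`.
#' @export
to_grayscale <- function(image) {
  image <- validate_rgb_image(image)
  g <- round(0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L])
  storage.mode(g) <- "integer"
  g
}

#' Quantize 8-bit grey values into L equal-width bins
#'
#' Uniform binning of \[0, 255\] into `levels` bins: value `v` maps to
#' `floor(v * levels / 256)`, so `levels = 256` is the identity on 8-bit
#' data and `levels = 2` splits at 127/128.
#'
#' @param gray Integer matrix of grey values in \[0, 255\].
#' @param levels Number of grey levels L >= 2.
#' @return Integer matrix with values in `0 .. levels - 1`.
#' @export
quantize <- function(gray, levels = 64L) {
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L) stop("`levels` must be >= 2", call. = FALSE)
  if (min(gray) < 0 || max(gray) > 255) {
    stop("grey values must be in [0, 255]", call. = FALSE)
  }
  # floor(v * L / 256) is exact in double precision (v*L integral, /256 a
  # power-of-two division)
  q <- (gray * levels) %/% 256L
  storage.mode(q) <- "integer"
  q
}

#' Default GLCM displacement set
#'
#' The four standard directions 0, 45, 90 and 135 degrees at a given pixel
#' distance, as (row, col) displacements.
#'
#' @param distance Pixel distance (default 1).
#' @return List of four integer vectors `c(drow, dcol)`.
#' @export
glcm_offsets <- function(distance = 1L) {
  d <- as.integer(distance)
  list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d))
}

#' Masked grey-level co-occurrence matrix
#'
#' Counts co-occurring grey-level pairs `(q[p], q[p + o])` over every
#' offset `o`, restricted to pairs where *both* pixels lie inside the mask;
#' pixels outside the mask can never influence the matrix. With
#' `symmetric = TRUE` each pair is also counted in the reverse direction,
#' making the matrix equal to its transpose. The counts are normalized to a
#' probability distribution (entries sum to 1).
#'
#' @param quantized Integer matrix of grey levels in `0 .. levels - 1`.
#' @param mask Logical matrix on the same grid.
#' @param offsets List of `c(drow, dcol)` displacements
#'   (default [glcm_offsets()]).
#' @param symmetric Count each pair in both directions (default TRUE).
#' @param levels Number of grey levels L; default `max(quantized) + 1`.
#' @return An object of class `glcm`: list with `p` (L x L probability
#'   matrix), `levels`, `offsets`, `symmetric`, `n_pairs`.
#' @export
compute_glcm <- function(quantized, mask, offsets = glcm_offsets(),
                         symmetric = TRUE, levels = NULL) {
  mask <- as_binary_mask(mask)
  if (!all(dim(mask) == dim(quantized))) {
    stop("mask and image dimensions differ", call. = FALSE)
  }
  if (is.null(levels)) levels <- max(quantized[mask]) + 1L
  levels <- as.integer(levels)
  nr <- nrow(quantized); nc <- ncol(quantized)
  counts <- matrix(0, levels, levels)
  n_pairs <- 0L
  for (o in offsets) {
    dr <- o[1L]; dc <- o[2L]
    if (abs(dr) >= nr || abs(dc) >= nc) next
    r_src <- max(1L, 1L - dr):min(nr, nr - dr)
    c_src <- max(1L, 1L - dc):min(nc, nc - dc)
    m_src <- mask[r_src, c_src, drop = FALSE]
    m_dst <- mask[r_src + dr, c_src + dc, drop = FALSE]
    ok <- m_src & m_dst
    if (!any(ok)) next
    i <- quantized[r_src, c_src, drop = FALSE][ok]
    j <- quantized[r_src + dr, c_src + dc, drop = FALSE][ok]
    tab <- tabulate(i * levels + j + 1L, nbins = levels * levels)
    counts <- counts + matrix(tab, levels, levels, byrow = TRUE)
    n_pairs <- n_pairs + sum(ok)
  }
  if (n_pairs == 0L) {
    stop(structure(class = c("pwat_degenerate_texture", "error", "condition"),
                   list(message = "degenerate texture: no co-occurring in-mask pixel pair",
                        call = NULL)))
  }
  if (symmetric) counts <- counts + t(counts)
  structure(list(p = counts / sum(counts), levels = levels, offsets = offsets,
                 symmetric = symmetric, n_pairs = n_pairs),
            class = "glcm")
}

#' The 13 canonical Haralick features of a GLCM
#'
#' Computes Haralick's f1..f13 from a normalized co-occurrence matrix:
#' angular second moment (energy), contrast (inertia), correlation, sum of
#' squares (variance), inverse difference moment, sum average, sum variance,
#' sum entropy, entropy, difference variance, difference entropy, and the
#' two information measures of correlation. Logarithms are base 2 with the
#' convention `0 log 0 = 0`; grey levels enter the moment sums by their
#' quantized value `0 .. L-1`. Degenerate marginals (a constant region)
#' make the information measures undefined; they are reported as 0 with a
#' warning.
#'
#' @param glcm A [compute_glcm()] result, or a bare normalized L x L matrix.
#' @return Named numeric vector of length 13.
#' @export
haralick_features <- function(glcm) {
  p <- if (inherits(glcm, "glcm")) glcm$p else as.matrix(glcm)
  if (abs(sum(p) - 1) > 1e-8) stop("GLCM must be normalized", call. = FALSE)
  L <- nrow(p)
  v <- seq_len(L) - 1          # grey-level values
  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum(v * px); mu_y <- sum(v * py)
  sd_x <- sqrt(sum((v - mu_x)^2 * px))
  sd_y <- sqrt(sum((v - mu_y)^2 * py))

  # p_{x+y}(k), k = 0 .. 2L-2 and p_{x-y}(k), k = 0 .. L-1
  iv <- matrix(v, L, L)      # row value i
  jv <- t(iv)                # col value j
  sum_idx <- iv + jv
  diff_idx <- abs(iv - jv)
  p_sum <- as.numeric(tapply(p, sum_idx, sum))        # ordered k = 0..2L-2
  k_sum <- sort(unique(as.numeric(sum_idx)))
  p_diff <- as.numeric(tapply(p, diff_idx, sum))
  k_diff <- sort(unique(as.numeric(diff_idx)))

  asm <- sum(p^2)
  contrast <- sum(k_diff^2 * p_diff)
  correlation <- if (sd_x > 0 && sd_y > 0) {
    (sum(iv * jv * p) - mu_x * mu_y) / (sd_x * sd_y)
  } else 0
  variance <- sum((iv - mu_x)^2 * p)
  idm <- sum(p / (1 + (iv - jv)^2))
  sum_average <- sum(k_sum * p_sum)
  sum_variance <- sum((k_sum - sum_average)^2 * p_sum)
  sum_entropy <- -sum(xlog2(p_sum))
  entropy <- -sum(xlog2(p))
  mu_diff <- sum(k_diff * p_diff)
  difference_variance <- sum((k_diff - mu_diff)^2 * p_diff)
  difference_entropy <- -sum(xlog2(p_diff))

  hx <- -sum(xlog2(px)); hy <- -sum(xlog2(py))
  pxy_outer <- outer(px, py)
  hxy1 <- -sum(p * safe_log2(pxy_outer, p))
  hxy2 <- -sum(xlog2(pxy_outer))
  if (max(hx, hy) > 0) {
    imc1 <- (entropy - hxy1) / max(hx, hy)
  } else {
    warning("degenerate marginals: information measures of correlation set to 0")
    imc1 <- 0
  }
  imc2_arg <- 1 - exp(-2 * (hxy2 - entropy) * log(2))
  imc2 <- sqrt(max(imc2_arg, 0))

  c(angular_second_moment = asm, contrast = contrast, correlation = correlation,
    sum_of_squares_variance = variance, inverse_difference_moment = idm,
    sum_average = sum_average, sum_variance = sum_variance,
    sum_entropy = sum_entropy, entropy = entropy,
    difference_variance = difference_variance,
    difference_entropy = difference_entropy,
    info_measure_correlation_1 = imc1, info_measure_correlation_2 = imc2)
}

#' Cluster shade and cluster prominence of a GLCM
#'
#' Third and fourth central moments of `i + j` about `mu_x + mu_y`. These
#' two features are *not* part of the canonical 13-feature set and are
#' excluded from the default 54-feature vector; they are offered as opt-in
#' extras.
#'
#' @inheritParams haralick_features
#' @return Named numeric vector `cluster_shade, cluster_prominence`.
#' @export
haralick_extras <- function(glcm) {
  p <- if (inherits(glcm, "glcm")) glcm$p else as.matrix(glcm)
  L <- nrow(p)
  v <- seq_len(L) - 1
  px <- rowSums(p); py <- colSums(p)
  mu <- sum(v * px) + sum(v * py)
  iv <- matrix(v, L, L); jv <- t(iv)
  c(cluster_shade = sum((iv + jv - mu)^3 * p),
    cluster_prominence = sum((iv + jv - mu)^4 * p))
}

#' Haralick texture features of a masked image region
#'
#' Grayscales and quantizes the image, builds one symmetric GLCM per
#' displacement direction, computes the 13 features on each, and averages
#' them over the directions (the common radiomics convention, which makes
#' the result invariant to the ordering of the offset list).
#'
#' @param image Integer array `h x w x 3` in \[0, 255\].
#' @param mask Logical matrix on the same grid.
#' @param levels Quantization depth (default 64).
#' @param distance GLCM pixel distance (default 1).
#' @param symmetric Symmetric accumulation (default TRUE).
#' @param extras Also append cluster shade/prominence (default FALSE).
#' @return Named numeric vector of length 13 (15 with `extras`).
#' @export
haralick_region <- function(image, mask, levels = 64L, distance = 1L,
                            symmetric = TRUE, extras = FALSE) {
  x <- check_region(image, mask)
  q <- quantize(to_grayscale(x$image), levels)
  per_dir <- lapply(glcm_offsets(distance), function(o) {
    g <- tryCatch(
      compute_glcm(q, x$mask, offsets = list(o), symmetric = symmetric,
                   levels = levels),
      pwat_degenerate_texture = function(e) NULL)
    if (is.null(g)) return(NULL)
    f <- haralick_features(g)
    if (extras) c(f, haralick_extras(g)) else f
  })
  per_dir <- Filter(Negate(is.null), per_dir)
  if (length(per_dir) == 0L) {
    stop(structure(class = c("pwat_degenerate_texture", "error", "condition"),
                   list(message = "degenerate texture: no co-occurring in-mask pixel pair in any direction",
                        call = NULL)))
  }
  Reduce(`+`, per_dir) / length(per_dir)
}

# x log2(x) with 0 log 0 = 0
xlog2 <- function(x) {
  out <- numeric(length(x))
  nz <- x > 0
  out[nz] <- x[nz] * log2(x[nz])
  dim(out) <- dim(x)
  out
}

# log2(x) where weights w are zero whenever x is zero (0 * log 0 = 0)
safe_log2 <- function(x, w) {
  out <- matrix(0, nrow(x), ncol(x))
  nz <- x > 0
  out[nz] <- log2(x[nz])
  out[!nz & w > 0] <- 0   # cannot occur for product marginals when p > 0
  out
}
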