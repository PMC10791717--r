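test_that("grayscale conversion uses BT.601 luma", {
  img <- array(0L, c(1, 3, 3))
  img[1, 1, ] <- c(255L, 255L, 255L)
  img[1, 2, ] <- c(255L, 0L, 0L)
  img[1, 3, ] <- c(100L, 100L, 100L)
  g <- to_grayscale(img)
  expect_equal(as.integer(g), c(255L, 76L, 100L))
})

test_that("quantization is equal-width binning of [0, 255]", {
  v <- matrix(0:255, 16, 16)
  expect_equal(quantize(v, 256), v)                      # identity at L=256
  q2 <- quantize(v, 2)
  expect_true(all(q2[v <= 127] == 0) && all(q2[v >= 128] == 1))
  expect_equal(quantize(matrix(255L), 64)[1, 1], 63L)
  expect_equal(quantize(matrix(0L), 64)[1, 1], 0L)
  expect_error(quantize(v, 1), "levels")
})

test_that("the GLCM counts in-mask pairs only and normalizes to probabilities", {
  # constant region: one nonzero entry with probability 1
  q <- matrix(3L, 4, 4)
  g <- compute_glcm(q, matrix(TRUE, 4, 4), levels = 8)
  expect_equal(sum(g$p), 1)
  expect_equal(g$p[4, 4], 1)

  # 1x2 region with levels (0, 1), offset (0,1), symmetric
  g <- compute_glcm(matrix(c(0L, 1L), 1, 2), matrix(TRUE, 1, 2),
                    offsets = list(c(0L, 1L)), symmetric = TRUE, levels = 2)
  expect_equal(g$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  # symmetric flag makes the matrix its own transpose; entries sum to 1
  set.seed(3)
  q <- quantize(matrix(sample.int(256L, 100, TRUE) - 1L, 10, 10), 8)
  g <- compute_glcm(q, random_mask(10, 10, 0.7), levels = 8)
  expect_equal(g$p, t(g$p))
  expect_equal(sum(g$p), 1, tolerance = 1e-12)

  # no co-occurring pair -> degenerate-texture error
  lone <- matrix(FALSE, 10, 10); lone[3, 3] <- TRUE
  expect_error(compute_glcm(q, lone), class = "pwat_degenerate_texture")
})

test_that("altering pixels outside the mask never changes the GLCM", {
  set.seed(4)
  for (rep in 1:10) {
    q <- matrix(sample.int(8L, 64, TRUE) - 1L, 8, 8)
    mask <- random_mask(8, 8, 0.6)
    q2 <- q
    q2[!mask] <- sample.int(8L, sum(!mask), TRUE) - 1L
    g1 <- try(compute_glcm(q, mask, levels = 8), silent = TRUE)
    if (inherits(g1, "try-error")) next
    expect_identical(g1$p, compute_glcm(q2, mask, levels = 8)$p)
  }
})

test_that("degenerate and uniform GLCMs give the closed-form feature values", {
  # constant region: single-entry distribution
  q <- matrix(2L, 3, 3)
  g <- compute_glcm(q, matrix(TRUE, 3, 3), levels = 4)
  f <- suppressWarnings(haralick_features(g))
  expect_equal(unname(f["angular_second_moment"]), 1)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["inverse_difference_moment"]), 1)
  expect_warning(haralick_features(g), "degenerate")

  # uniform 2x2 GLCM
  f <- haralick_features(matrix(0.25, 2, 2))
  expect_equal(unname(f["angular_second_moment"]), 0.25)
  expect_equal(unname(f["entropy"]), 2)
})

test_that("all 13 features match the brute-force double-sum oracle", {
  set.seed(5)
  for (rep in 1:100) {
    L <- sample(2:8, 1)
    q <- matrix(sample.int(L, 64, TRUE) - 1L, 8, 8)
    mask <- random_mask(8, 8, stats::runif(1, 0.4, 1))
    g <- try(compute_glcm(q, mask, levels = L), silent = TRUE)
    if (inherits(g, "try-error")) next
    got <- suppressWarnings(haralick_features(g))
    want <- oracle_haralick(g$p)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("direction averaging is invariant to offset-list permutation", {
  set.seed(6)
  img <- random_image(12, 12)
  mask <- matrix(TRUE, 12, 12)
  q <- quantize(to_grayscale(img), 16)
  per_dir <- function(offs) {
    fs <- lapply(offs, function(o)
      haralick_features(compute_glcm(q, mask, offsets = list(o), levels = 16)))
    Reduce(`+`, fs) / length(fs)
  }
  offs <- glcm_offsets(1)
  expect_equal(per_dir(offs), per_dir(rev(offs)))
})

test_that("a grey shift that stays within quantization bins leaves contrast unchanged", {
  set.seed(8)
  base <- matrix((sample.int(63L, 100, TRUE) - 1L) * 4L, 10, 10)  # bin floors at L=64
  mask <- matrix(TRUE, 10, 10)
  f0 <- haralick_features(compute_glcm(quantize(base, 64), mask, levels = 64))
  f1 <- haralick_features(compute_glcm(quantize(base + 3L, 64), mask, levels = 64))
  expect_equal(f0["contrast"], f1["contrast"])
  expect_equal(f0, f1)  # identical bins, identical GLCM
})

test_that("cluster shade and prominence are opt-in extras outside the default vector", {
  set.seed(9)
  img <- random_image(10, 10)
  mask <- matrix(TRUE, 10, 10)
  f <- haralick_region(img, mask, levels = 16)
  expect_length(f, 13)
  fe <- haralick_region(img, mask, levels = 16, extras = TRUE)
  expect_length(fe, 15)
  expect_true(all(c("cluster_shade", "cluster_prominence") %in% names(fe)))
  expect_false(any(c("cluster_shade", "cluster_prominence") %in%
                     pwat_feature_names()))
})
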