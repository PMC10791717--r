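#' Per-channel RGB statistics over a masked region
#'
#' Mean and population standard deviation (divisor `n`, matching the plain
#' averages of the underlying formulas) of the R, G and B channels, computed
#' over the masked pixels only. Pixels outside the mask never influence the
#' result.
#'
#' @param image Integer array `h x w x 3` in \[0, 255\].
#' @param mask Logical matrix on the same grid; must contain >= 1 pixel.
#' @return Named numeric vector
#'   `mean_R, std_R, mean_G, std_G, mean_B, std_B`.
#' @export
rgb_stats <- function(image, mask) {
  x <- check_region(image, mask)
  out <- numeric(6L)
  names(out) <- c("mean_R", "std_R", "mean_G", "std_G", "mean_B", "std_B")
  for (ch in 1:3) {
    v <- x$image[, , ch][x$mask]
    out[2L * ch - 1L] <- mean(v)
    out[2L * ch] <- pop_sd(v)
  }
  out
}

#' Per-channel HSV statistics over a masked region
#'
#' Converts the masked pixels to HSV with the standard hexcone model
#' (hue in degrees \[0, 360), saturation and value as fractions in \[0, 1\];
#' achromatic pixels have hue 0) and returns the mean and population
#' standard deviation of each channel.
#'
#' @inheritParams rgb_stats
#' @return Named numeric vector
#'   `mean_H, std_H, mean_S, std_S, mean_V, std_V`.
#' @export
hsv_stats <- function(image, mask) {
  hsv <- masked_hsv(image, mask)
  c(mean_H = mean(hsv$h), std_H = pop_sd(hsv$h),
    mean_S = mean(hsv$s), std_S = pop_sd(hsv$s),
    mean_V = mean(hsv$v), std_V = pop_sd(hsv$v))
}

#' RGB erythema index of a masked region
#'
#' Mean over the `n` masked pixels of `(2R - G - B) / (2 (R + G + B))`.
#' The per-pixel ratio lies in \[-0.5, 1\] (pure red gives 1, pure green or
#' blue gives -0.5, any grey gives 0) and is invariant to uniform channel
#' rescaling. Black pixels (`R + G + B = 0`) contribute 0: a black pixel
#' carries no redness and would otherwise divide by zero.
#'
#' @inheritParams rgb_stats
#' @return A single number in \[-0.5, 1\].
#' @export
redness_rgb <- function(image, mask) {
  x <- check_region(image, mask)
  r <- as.numeric(x$image[, , 1L][x$mask])
  g <- as.numeric(x$image[, , 2L][x$mask])
  b <- as.numeric(x$image[, , 3L][x$mask])
  s <- r + g + b
  ratio <- ifelse(s == 0, 0, (2 * r - g - b) / (2 * s))
  mean(ratio)
}

#' HSV erythema index of a masked region
#'
#' Mean over the masked pixels of the product `H * S`, with hue in degrees
#' \[0, 360) and saturation in \[0, 1\]. Achromatic regions score 0. Note
#' the hue origin: pure red sits at H = 0, so this index responds to
#' orange/red hues away from the origin; reds just below 360 degrees score
#' maximally — a discontinuity inherent in the index as defined.
#'
#' @inheritParams rgb_stats
#' @return A single non-negative number.
#' @export
redness_hsv <- function(image, mask) {
  hsv <- masked_hsv(image, mask)
  mean(hsv$h * hsv$s)
}

#' All 14 color features of a region
#'
#' The 12 channel statistics (RGB and HSV means/standard deviations) plus
#' the two erythema indices, as one named vector in the pinned order.
#'
#' @inheritParams rgb_stats
#' @return Named numeric vector of length 14.
#' @export
region_color_summary <- function(image, mask) {
  c(rgb_stats(image, mask), hsv_stats(image, mask),
    redness_rgb = redness_rgb(image, mask),
    redness_hsv = redness_hsv(image, mask))
}

# HSV values of the masked pixels; h in degrees [0, 360), s and v in [0, 1].
masked_hsv <- function(image, mask) {
  x <- check_region(image, mask)
  rgb <- rbind(x$image[, , 1L][x$mask], x$image[, , 2L][x$mask],
               x$image[, , 3L][x$mask])
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  h <- hsv[1L, ] * 360
  s <- hsv[2L, ]
  h[s == 0] <- 0  # pin the achromatic-hue convention
  list(h = h, s = s, v = hsv[3L, ])
}

# Population standard deviation (divisor n).
pop_sd <- function(v) {
  sqrt(mean((v - mean(v))^2))
}
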