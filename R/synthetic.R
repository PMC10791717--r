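#' Synthetic wound photograph generator
#'
#' Renders an elliptical wound on a skin-toned background whose appearance
#' is driven by a latent severity score in the 2-24 range of the PWAT
#' grades observed clinically. Severity is expressed through five
#' independent appearance channels, each adding the score-plus-jitter value
#' `clamp01((pwat - 2)/22 + N(0, 0.15))`:
#'
#' * `erythema` - wound chroma: higher severity suppresses the green/blue
#'   fraction of the wound colour (a ratio change, invisible to brightness);
#' * `necrosis` - wound darkening: a global brightness drop plus a matching
#'   fraction of dark necrotic blobs (a multiplicative change, invisible to
#'   the chroma ratios);
#' * `roughness` - wound texture scale: a fixed-amplitude oscillatory
#'   luminance pattern whose spatial frequency grows with severity, so
#'   neighbour contrast rises while the marginal pixel variance stays flat;
#' * `ring_chroma` - peri-wound chroma: the surrounding ring reddens;
#' * `ring_darkening` - peri-wound brightness: the ring darkens.
#'
#' Because the five channel jitters are independent, each channel carries
#' its own information about the severity score, and a feature ranking of a
#' model trained on the rendered images should surface one readout feature
#' per channel (see [channel_feature_groups()]).
#'
#' @param seed Integer seed; the sample is a pure function of
#'   `(seed, true_pwat, size)` and the overrides.
#' @param true_pwat Severity score in \[2, 24\].
#' @param size Image side in pixels (default 256).
#' @param erythema,necrosis,roughness,ring_chroma,ring_darkening Optional
#'   overrides in \[0, 1\] for the corresponding channel (defaults: drawn
#'   from the severity as described above).
#' @return List of class `synthetic_sample`: `image` (integer
#'   `size x size x 3`), `wound_mask` (logical matrix), `true_pwat`,
#'   `params` (seed, channel values, background tone, ellipse geometry).
#' @export
generate_sample <- function(seed, true_pwat, size = 256L,
                            erythema = NULL, necrosis = NULL, roughness = NULL,
                            ring_chroma = NULL, ring_darkening = NULL) {
  if (true_pwat < 2 || true_pwat > 24) {
    stop("`true_pwat` must be in [2, 24]", call. = FALSE)
  }
  S <- as.integer(size)
  if (S < 32L) stop("`size` must be >= 32", call. = FALSE)
  t <- (true_pwat - 2) / 22
  with_seed(seed, {
    jitter <- stats::rnorm(5L, 0, 0.15)
    ch <- pmin(pmax(t + jitter, 0), 1)
    c_ery <- if (is.null(erythema)) ch[1L] else erythema
    c_nec <- if (is.null(necrosis)) ch[2L] else necrosis
    c_rough <- if (is.null(roughness)) ch[3L] else roughness
    c_ring <- if (is.null(ring_chroma)) ch[4L] else ring_chroma
    c_dark <- if (is.null(ring_darkening)) ch[5L] else ring_darkening

    # geometry: ellipse strictly inside the border with ample margin
    cx <- S / 2 + stats::runif(1, -0.04, 0.04) * S
    cy <- S / 2 + stats::runif(1, -0.04, 0.04) * S
    a <- stats::runif(1, 0.12, 0.20) * S
    b <- stats::runif(1, 0.12, 0.20) * S
    theta <- stats::runif(1, 0, pi)
    rows <- matrix(seq_len(S), S, S)
    cols <- matrix(seq_len(S), S, S, byrow = TRUE)
    dx <- cols - cx; dy <- rows - cy
    u <- (dx * cos(theta) + dy * sin(theta)) / a
    w <- (-dx * sin(theta) + dy * cos(theta)) / b
    e2 <- u^2 + w^2
    wound <- e2 <= 1
    annulus <- e2 <= 1.3^2 & !wound

    # background: skin tone with a gentle smooth gradient
    bg_tone <- c(224, 182, 158) + stats::rnorm(3L, 0, 4)
    grad <- field_sinusoid(S, 1.2, terms = 3L) * 4
    img <- array(0, dim = c(S, S, 3L))
    for (k in 1:3) img[, , k] <- bg_tone[k] + grad

    # wound colour: chroma ratios from the erythema channel, brightness from
    # the necrosis channel. The base intensity is luma-compensated so that a
    # chroma change leaves the grey-level rendering of the wound untouched:
    # erythema reads out only through ratio features, necrosis only through
    # luminance features.
    ratio <- c(1, 0.62 - 0.32 * c_ery, 0.45 - 0.24 * c_ery)
    luma_factor <- 0.299 * ratio[1] + 0.587 * ratio[2] + 0.114 * ratio[3]
    v_w <- (160 - 110 * c_nec) * 0.726 / luma_factor
    # fixed-variance texture whose spatial frequency tracks roughness
    tex <- field_sinusoid(S, freq = 4 + 56 * c_rough, terms = 6L) * 14
    # necrotic blobs: exact pixel fraction via an in-wound quantile cut;
    # multiplicative darkening preserves the chroma ratios
    nec_frac <- 0.45 * c_nec
    nec_field <- field_sinusoid(S, freq = 4, terms = 4L)
    necrotic <- wound & FALSE
    if (nec_frac > 0 && any(wound)) {
      cut <- stats::quantile(nec_field[wound], probs = 1 - nec_frac, names = FALSE)
      necrotic <- wound & nec_field > cut
    }
    darken <- ifelse(necrotic, 0.35, 1)
    # wound margin: the outer rim of the wound bed (radial fraction > 0.90)
    # blends towards the peri-wound tone, so the morphological ring derived
    # downstream reads the ring channels on both of its one-pixel bands
    ring_col <- c(225, 170 - 100 * c_ring, 135 - 85 * c_ring) * (1 - 0.5 * c_dark)
    margin_w <- pmin(pmax((sqrt(e2) - 0.90) / 0.10, 0), 1)
    for (k in 1:3) {
      mw <- margin_w[wound]
      wound_px <- v_w * ratio[k] * darken[wound] + tex[wound] * (1 - mw)
      img[, , k][wound] <- wound_px * (1 - mw) + ring_col[k] * mw
    }

    # peri-wound ring: tone gradient fading from the wound edge outwards
    ring_w <- pmin(pmax((1.3 - sqrt(e2[annulus])) / 0.3, 0), 1)
    for (k in 1:3) {
      base <- img[, , k][annulus]
      img[, , k][annulus] <- base * (1 - ring_w) + ring_col[k] * ring_w
    }

    # sensor noise, clip, round
    img <- img + array(stats::rnorm(S * S * 3L, 0, 2.5), dim = dim(img))
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"

    structure(list(image = img, wound_mask = wound, true_pwat = true_pwat,
                   params = list(seed = seed, size = S, erythema = c_ery,
                                 necrosis = c_nec, roughness = c_rough,
                                 ring_chroma = c_ring, ring_darkening = c_dark,
                                 background_tone = bg_tone,
                                 ellipse = c(cx = cx, cy = cy, a = a, b = b,
                                             theta = theta))),
              class = "synthetic_sample")
  })
}

#' Generate a synthetic wound dataset
#'
#' Draws `n` severity scores from a truncated normal distribution (default
#' mean 15, sd 3, bounds \[2, 24\], matching the PWAT distribution of a
#' clinical chronic-wound population) and renders one sample per score with
#' a per-sample seed derived deterministically from the master seed.
#' Optionally writes the dataset to disk as PNG image/mask pairs, a
#' `scores.csv` table and a `manifest.json` with every generator parameter.
#'
#' @param n Number of samples.
#' @param seed Master seed; the dataset is a pure function of
#'   `(n, seed, score_distribution, size)`.
#' @param score_distribution List with `mean`, `sd`, `min`, `max`.
#' @param size Image side in pixels.
#' @param dir Output directory (created if missing); `NULL` keeps the
#'   samples in memory only.
#' @return List of class `synthetic_dataset`: `samples` (list of
#'   [generate_sample()] results), `scores` (data.frame `sample_id, pwat`),
#'   `manifest`, and when `dir` is given, `paths` (image/mask path vectors
#'   named by sample id).
#' @export
generate_dataset <- function(n, seed = 0L,
                             score_distribution = list(mean = 15, sd = 3,
                                                       min = 2, max = 24),
                             size = 256L, dir = NULL) {
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  sd_ <- score_distribution
  draws <- with_seed(seed, {
    scores <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        s <- stats::rnorm(1, sd_$mean, sd_$sd)
        if (s >= sd_$min && s <= sd_$max) break
      }
      scores[i] <- s
    }
    list(scores = scores,
         seeds = sample.int(.Machine$integer.max - 1L, n))
  })
  ids <- sprintf("sample_%04d", seq_len(n))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    samples[[i]] <- generate_sample(draws$seeds[i], draws$scores[i], size = size)
  }
  names(samples) <- ids
  scores <- data.frame(sample_id = ids, pwat = draws$scores,
                       stringsAsFactors = FALSE)
  manifest <- list(n = n, seed = seed, size = size,
                   score_distribution = sd_,
                   sample_seeds = draws$seeds,
                   channels = lapply(samples, function(s) {
                     s$params[c("erythema", "necrosis", "roughness",
                                "ring_chroma", "ring_darkening")]
                   }))
  out <- list(samples = samples, scores = scores, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    img_paths <- file.path(dir, paste0(ids, ".png"))
    mask_paths <- file.path(dir, paste0(ids, "_mask.png"))
    for (i in seq_len(n)) {
      write_image(samples[[i]]$image, img_paths[i])
      save_mask(samples[[i]]$wound_mask, mask_paths[i])
    }
    utils::write.csv(scores, file.path(dir, "scores.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    out$paths <- list(images = stats::setNames(img_paths, ids),
                      masks = stats::setNames(mask_paths, ids))
  }
  structure(out, class = "synthetic_dataset")
}

#' Feature groups read out by each generator channel
#'
#' Maps each of the generator's five severity channels to the group of
#' extracted features that are, by construction, its readouts. Features
#' within a group are definitionally coupled (e.g. a brightness change
#' moves every RGB mean together), so a sparse model selects a
#' data-dependent representative per group; across groups the channels are
#' statistically independent.
#'
#' @return Named list of character vectors of feature names.
#' @export
channel_feature_groups <- function() {
  chroma <- c("mean_H", "std_H", "mean_S", "std_S", "redness_rgb", "redness_hsv")
  brightness <- c("mean_R", "std_R", "mean_G", "std_G", "mean_B", "std_B",
                  "mean_V", "std_V", "sum_average", "sum_of_squares_variance",
                  "sum_variance", "entropy", "sum_entropy",
                  "angular_second_moment")
  texture <- c("contrast", "correlation", "inverse_difference_moment",
               "difference_variance", "difference_entropy",
               "info_measure_correlation_1", "info_measure_correlation_2")
  list(erythema = paste0("wound_", chroma),
       necrosis = paste0("wound_", c(brightness, texture[4:5])),
       roughness = paste0("wound_", texture[1:3]),
       ring_chroma = paste0("periwound_", chroma),
       ring_darkening = paste0("periwound_", c(brightness, texture)))
}

# Sum of `terms` random-direction sinusoids at spatial frequency ~`freq`
# cycles per image side, standardized to mean 0 / sd 1 over the grid.
field_sinusoid <- function(size, freq, terms = 6L) {
  S <- size
  rows <- matrix(seq_len(S), S, S) / S
  cols <- matrix(seq_len(S), S, S, byrow = TRUE) / S
  field <- matrix(0, S, S)
  for (k in seq_len(terms)) {
    f <- stats::runif(1, freq, 1.6 * freq)
    th <- stats::runif(1, 0, 2 * pi)
    ph <- stats::runif(1, 0, 2 * pi)
    field <- field + sin(2 * pi * f * (cos(th) * cols + sin(th) * rows) + ph)
  }
  (field - mean(field)) / stats::sd(field)
}
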