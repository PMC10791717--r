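#' Read an RGB photograph
#'
#' Returns an 8-bit RGB image as an integer array `height x width x 3` with
#' values in \[0, 255\]. PNG files are read natively; other formats (e.g.
#' JPEG) are read through EBImage when it is available. Greyscale rasters are
#' replicated across the three channels; an alpha channel is dropped.
#'
#' @param path Path to an image file.
#' @return Integer array `h x w x 3`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image '%s': no such file", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop(sprintf("reading '%s' requires the EBImage package for non-PNG formats", path),
           call. = FALSE)
    }
    img <- EBImage::readImage(path)
    d <- dim(img)
    raw <- if (length(d) == 2L) t(img@.Data) else aperm(img@.Data, c(2L, 1L, 3L))
  }
  if (length(dim(raw)) == 2L) {
    raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  } else if (dim(raw)[3L] > 3L) {
    raw <- raw[, , 1:3, drop = FALSE]
  }
  arr <- round(raw * 255)
  storage.mode(arr) <- "integer"
  validate_rgb_image(arr)
}

#' Write an RGB image as PNG
#'
#' @param image Integer array `h x w x 3`, values in \[0, 255\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image <- validate_rgb_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

validate_rgb_image <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3L] != 3L) {
    stop("image must be a height x width x 3 array", call. = FALSE)
  }
  if (d[1L] < 1L || d[2L] < 1L) stop("image must be non-empty", call. = FALSE)
  if (anyNA(image) || min(image) < 0 || max(image) > 255) {
    stop("image values must be in [0, 255]", call. = FALSE)
  }
  image
}

# Shared helper: check an image/mask pair and a non-empty region.
check_region <- function(image, mask) {
  image <- validate_rgb_image(image)
  mask <- as_binary_mask(mask)
  if (!all(dim(mask) == dim(image)[1:2])) {
    stop("mask and image dimensions differ", call. = FALSE)
  }
  if (!any(mask)) {
    stop(structure(class = c("pwat_empty_region", "error", "condition"),
                   list(message = "region is empty: no masked pixels",
                        call = NULL)))
  }
  list(image = image, mask = mask)
}
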