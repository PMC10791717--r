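#' Structuring element for binary morphology
#'
#' Builds a discrete elliptical (disk) structuring element of odd side
#' `size`. For the default `size = 3` this is the 5-pixel "plus"
#' \{(0,0), (+-1,0), (0,+-1)\}: the diagonal corners fall outside the
#' inscribed ellipse and are excluded. The origin (0,0) is always a member.
#'
#' @param size Odd positive integer side length (default 3).
#' @param shape Element shape; only `"ellipse"` is supported.
#' @return An object of class `struct_element`: a list with `shape`, `size`
#'   and `offsets`, a two-column integer matrix of (row, col) displacements.
#' @examples
#' struct_element(3)$offsets
#' @export
struct_element <- function(size = 3L, shape = "ellipse") {
  shape <- match.arg(shape, "ellipse")
  size <- as.integer(size)
  if (length(size) != 1L || is.na(size) || size < 1L || size %% 2L == 0L) {
    stop("`size` must be an odd positive integer", call. = FALSE)
  }
  r <- (size - 1L) / 2L
  dr <- rep(seq(-r, r), each = size)
  dc <- rep(seq(-r, r), times = size)
  if (r > 0) {
    keep <- (dr / r)^2 + (dc / r)^2 <= 1 + 1e-9
  } else {
    keep <- TRUE
  }
  offsets <- cbind(row = dr[keep], col = dc[keep])
  structure(list(shape = shape, size = c(size, size), offsets = offsets),
            class = "struct_element")
}

# Shift a logical matrix by (dr, dc): out[r, c] = m[r - dr, c - dc],
# with out-of-grid content FALSE. The workhorse of dilation/erosion.
shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  if (abs(dr) >= nr || abs(dc) >= nc) return(out)
  r_dst <- max(1L, 1L + dr):min(nr, nr + dr)
  c_dst <- max(1L, 1L + dc):min(nc, nc + dc)
  out[r_dst, c_dst] <- m[r_dst - dr, c_dst - dc, drop = FALSE]
  out
}

#' Binary dilation
#'
#' `out[p]` is true iff any `m[p - o]` is true for an offset `o` of the
#' element. Dilation never writes outside the grid (it is clipped at the
#' image borders).
#'
#' @param mask Logical matrix (TRUE = foreground).
#' @param kernel A [struct_element()].
#' @return Logical matrix of the same dimensions.
#' @export
dilate_mask <- function(mask, kernel = struct_element(3L)) {
  mask <- as_binary_mask(mask)
  off <- kernel$offsets
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_mask(mask, off[i, 1L], off[i, 2L])
  }
  out
}

#' Binary erosion
#'
#' `out[p]` is true iff every `m[p + o]` is true; neighbours that fall
#' outside the grid count as background, so erosion always removes a border
#' band of foreground touching the image edge.
#'
#' @inheritParams dilate_mask
#' @return Logical matrix of the same dimensions.
#' @export
erode_mask <- function(mask, kernel = struct_element(3L)) {
  mask <- as_binary_mask(mask)
  off <- kernel$offsets
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    # m[p + o] rewritten as a shift by -o; out-of-grid reads are FALSE
    out <- out & shift_mask(mask, -off[i, 1L], -off[i, 2L])
  }
  out
}

#' Derive the peri-wound mask from a wound mask
#'
#' The peri-wound region is the morphological gradient of the wound mask:
#' the set difference between its dilation and its erosion,
#' `(M %o+% k) - (M %o-% k)`. With the default 3x3 elliptical element this
#' is a thin ring straddling the wound boundary (roughly one pixel outside
#' and one inside). It is disjoint from the eroded mask by construction and
#' contained in the dilated mask. An empty wound mask yields an empty ring.
#'
#' @param wound Logical matrix, the wound-bed mask.
#' @param kernel A [struct_element()]; the default is the 3x3 ellipse.
#' @return Logical matrix: the peri-wound mask.
#' @examples
#' m <- matrix(FALSE, 20, 20); m[6:15, 6:15] <- TRUE
#' sum(derive_periwound_mask(m))  # 76-pixel ring
#' @export
derive_periwound_mask <- function(wound, kernel = struct_element(3L)) {
  wound <- as_binary_mask(wound)
  dilate_mask(wound, kernel) & !erode_mask(wound, kernel)
}

#' Load a binary mask from a PNG file
#'
#' Reads a single- or multi-channel 8-bit raster and binarizes its first
#' channel: a pixel is foreground iff its grey value strictly exceeds
#' `threshold`. Binarization is idempotent: loading a saved mask reproduces
#' it exactly.
#'
#' @param path Path to a PNG file.
#' @param threshold Integer grey level in \[0, 255\] (default 127).
#' @return Logical matrix (rows x cols as in the image).
#' @export
load_mask <- function(path, threshold = 127L) {
  if (threshold < 0 || threshold > 255) {
    stop("`threshold` must be in [0, 255]", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop(sprintf("cannot read mask file '%s': no such file", path), call. = FALSE)
  }
  raw <- tryCatch(png::readPNG(path), error = function(e) {
    stop(sprintf("cannot read mask file '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  if (length(raw) == 0L) stop(sprintf("empty raster in '%s'", path), call. = FALSE)
  grey <- round(raw * 255)
  grey > threshold
}

#' Save a binary mask as an 8-bit PNG (foreground 255, background 0)
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Pixel count and tight bounding box of a mask
#'
#' Coordinates are 0-based and the box is half-open:
#' `(row0, col0, row1, col1)` spans rows `row0 <= r < row1`. An empty mask
#' reports count 0 and the sentinel box `(0, 0, 0, 0)` rather than an error.
#'
#' @param mask Logical matrix.
#' @return List with `pixel_count` and `bounding_box`.
#' @export
mask_stats <- function(mask) {
  mask <- as_binary_mask(mask)
  n <- sum(mask)
  if (n == 0L) {
    return(list(pixel_count = 0L, bounding_box = c(0L, 0L, 0L, 0L)))
  }
  idx <- which(mask, arr.ind = TRUE)
  box <- c(min(idx[, 1L]) - 1L, min(idx[, 2L]) - 1L, max(idx[, 1L]), max(idx[, 2L]))
  list(pixel_count = as.integer(n), bounding_box = as.integer(box))
}

# Validate/coerce a mask argument to a strictly logical matrix.
as_binary_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  if (length(mask) == 0L) stop("mask must be non-empty", call. = FALSE)
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) {
      stop("mask values must be logical or 0/1", call. = FALSE)
    }
    mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  }
  mask
}
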