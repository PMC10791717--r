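#' The pinned 54-feature name list
#'
#' For each region (`wound`, then `periwound`): the 12 color statistics
#' (RGB then HSV means/standard deviations), the two erythema indices, and
#' the 13 canonical Haralick features, each prefixed by the region name.
#' This order is fixed: feature tables, trained models and predictions all
#' use it.
#'
#' @return Character vector of length 54.
#' @export
pwat_feature_names <- function() {
  per_region <- c("mean_R", "std_R", "mean_G", "std_G", "mean_B", "std_B",
                  "mean_H", "std_H", "mean_S", "std_S", "mean_V", "std_V",
                  "redness_rgb", "redness_hsv",
                  "angular_second_moment", "contrast", "correlation",
                  "sum_of_squares_variance", "inverse_difference_moment",
                  "sum_average", "sum_variance", "sum_entropy", "entropy",
                  "difference_variance", "difference_entropy",
                  "info_measure_correlation_1", "info_measure_correlation_2")
  c(paste0("wound_", per_region), paste0("periwound_", per_region))
}

#' Extract the 54-feature vector from a wound photograph
#'
#' Derives the peri-wound mask from the wound mask (dilation minus erosion
#' with the given structuring element), then computes, independently on the
#' wound and peri-wound regions, the 12 color statistics, the two erythema
#' indices and the 13 Haralick texture features. Pixels outside the dilated
#' wound mask never influence any feature.
#'
#' @param image Integer array `h x w x 3` in \[0, 255\].
#' @param wound Logical matrix: the wound-bed mask.
#' @param kernel Structuring element for the peri-wound derivation
#'   (default the 3x3 ellipse).
#' @param levels GLCM quantization depth (default 64).
#' @param distance GLCM pixel distance (default 1).
#' @return Named numeric vector of length 54, in [pwat_feature_names()]
#'   order.
#' @export
extract_features <- function(image, wound, kernel = struct_element(3L),
                             levels = 64L, distance = 1L) {
  image <- validate_rgb_image(image)
  wound <- as_binary_mask(wound)
  if (!any(wound)) {
    stop(structure(class = c("pwat_empty_region", "error", "condition"),
                   list(message = "wound mask is empty", call = NULL)))
  }
  periwound <- derive_periwound_mask(wound, kernel)
  if (!any(periwound)) {
    stop(structure(class = c("pwat_empty_region", "error", "condition"),
                   list(message = "derived peri-wound mask is empty", call = NULL)))
  }
  out <- c(region_features(image, wound, levels, distance),
           region_features(image, periwound, levels, distance))
  names(out) <- pwat_feature_names()
  if (!all(is.finite(out))) {
    stop("non-finite feature value extracted", call. = FALSE)
  }
  out
}

region_features <- function(image, mask, levels = 64L, distance = 1L) {
  c(region_color_summary(image, mask),
    haralick_region(image, mask, levels = levels, distance = distance))
}

#' Extract features for a directory of image/mask pairs
#'
#' Pairs photographs and masks by shared file stem (`<stem>.png` with
#' `<stem>_mask.png`, or identical stems across two directories). Samples
#' that fail extraction (empty regions, degenerate texture) are skipped
#' with a warning, not fatal.
#'
#' @param image_paths Named character vector of image paths (names are
#'   sample ids).
#' @param mask_paths Named character vector of mask paths, same names.
#' @param ... Passed to [extract_features()].
#' @return A data.frame: `sample_id` plus the 54 feature columns.
#' @export
extract_features_batch <- function(image_paths, mask_paths, ...) {
  ids <- intersect(names(image_paths), names(mask_paths))
  skipped <- setdiff(union(names(image_paths), names(mask_paths)), ids)
  for (s in skipped) warning(sprintf("sample '%s' has no image/mask pair; skipped", s))
  rows <- list()
  for (id in ids) {
    fv <- tryCatch(
      extract_features(read_image(image_paths[[id]]), load_mask(mask_paths[[id]]), ...),
      error = function(e) {
        warning(sprintf("sample '%s' skipped: %s", id, conditionMessage(e)))
        NULL
      })
    if (!is.null(fv)) rows[[id]] <- fv
  }
  if (length(rows) == 0L) {
    return(cbind(data.frame(sample_id = character(0)),
                 as.data.frame(matrix(numeric(0), 0, 54,
                                      dimnames = list(NULL, pwat_feature_names())))))
  }
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(sample_id = names(rows), stringsAsFactors = FALSE),
        out, row.names = NULL)
}

# Coerce a feature table (data.frame with optional sample_id column) to the
# 54-column numeric matrix in pinned order.
feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    features <- features[, setdiff(colnames(features), "sample_id"), drop = FALSE]
    features <- as.matrix(features)
  }
  if (is.null(dim(features))) features <- matrix(features, 1L,
                                                 dimnames = list(NULL, names(features)))
  nm <- pwat_feature_names()
  if (is.null(colnames(features)) || !setequal(colnames(features), nm)) {
    stop(structure(class = c("pwat_schema_error", "error", "condition"),
                   list(message = "feature columns do not match the pinned 54-feature schema",
                        call = NULL)))
  }
  features[, nm, drop = FALSE]
}
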