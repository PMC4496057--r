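#' Bundled multi-location survey metadata
#'
#' A small table describing the four-reef survey design the package's
#' defaults are calibrated to: per location, the evaluation-set size
#' (images and points per image), the reference-pool size, the recorded
#' reference annotation total, the image size in pixels and the imaged
#' area. Shipped as plain CSV under `extdata`.
#'
#' @return data frame with one row per location.
#' @export
survey_metadata <- function() {
  path <- system.file("extdata", "survey_metadata.csv",
                      package = "reefpoint", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Total manual point-annotation budget of a survey design
#'
#' @param n_images images per location.
#' @param points_per_image annotated points per image.
#' @param n_locations number of locations.
#' @param n_annotators number of annotators scoring every point.
#' @return total number of manual point annotations.
#' @export
annotation_budget <- function(n_images, points_per_image, n_locations = 1L,
                              n_annotators = 1L) {
  stopifnot(n_images >= 0, points_per_image >= 0, n_locations >= 1,
            n_annotators >= 1)
  n_images * points_per_image * n_locations * n_annotators
}

#' Pixel density of a photoquadrat
#'
#' @param image_px total image size in pixels.
#' @param area_cm2 imaged benthic area in square centimeters.
#' @return spatial resolution in pixels per square millimeter.
#' @export
pixel_density <- function(image_px, area_cm2) {
  stopifnot(image_px > 0, area_cm2 > 0)
  image_px / (area_cm2 * 100)
}

#' Validate survey metadata bookkeeping
#'
#' Recomputes, for each location, the evaluation and reference annotation
#' totals from images x points-per-image and the pixel density from image
#' size and imaged area, and compares the recorded reference total with
#' the product. A location whose recorded total differs from the product
#' (e.g. because some images carry fewer points) is flagged, not failed.
#'
#' @param meta data frame as returned by [survey_metadata()].
#' @param n_annotators annotators re-scoring the evaluation sets (for the
#'   manual-annotation budget).
#' @return list with `per_location` (the metadata plus computed columns
#'   `eval_total`, `ref_total_computed`, `ref_total_matches`,
#'   `px_per_mm2`) and `manual_annotation_total` over all locations and
#'   annotators.
#' @export
validate_survey_metadata <- function(meta = survey_metadata(),
                                     n_annotators = 6L) {
  required <- c("location", "eval_images", "eval_points_per_image",
                "ref_images", "ref_points_per_image",
                "ref_total_annotations", "image_px", "area_cm2")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    abort_reefpoint(sprintf("metadata lacks columns: %s",
                            paste(missing_cols, collapse = ", ")),
                    "format_error")
  }
  per <- meta
  per$eval_total <- annotation_budget(meta$eval_images,
                                      meta$eval_points_per_image)
  per$ref_total_computed <- annotation_budget(meta$ref_images,
                                              meta$ref_points_per_image)
  per$ref_total_matches <- per$ref_total_computed == meta$ref_total_annotations
  per$px_per_mm2 <- pixel_density(meta$image_px, meta$area_cm2)
  list(
    per_location = per,
    manual_annotation_total = sum(per$eval_total) * n_annotators
  )
}
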