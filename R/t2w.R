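# Semi-quantitative T2-weighted edema analysis: myocardium-to-skeletal-muscle
# signal-intensity ratios.  For dark-blood triple-inversion-recovery spin
# echo a classification cut-off of 1.9 may be used (a locally established
# value is preferred); the parametric pixel map flags ratios of 2 or higher.

#' Myocardium-to-skeletal-muscle SI ratio
#'
#' @param image numeric SI matrix.
#' @param region_mask logical mask of the myocardium (or a region of it).
#' @param skeletal_roi skeletal-muscle \code{contour_polygon} (or logical
#'   mask), ideally a large area of muscle close to the heart.
#' @param pixel_spacing mm/pixel.
#' @param min_pixels minimum skeletal ROI size (default 20).
#' @return mean SI(region) / mean SI(skeletal muscle).
#' @export
si_ratio <- function(image, region_mask, skeletal_roi, pixel_spacing = c(1, 1),
                     min_pixels = 20) {
  sk <- as_roi_mask(skeletal_roi, dim(image), pixel_spacing)
  if (sum(sk) < min_pixels)
    stop("skeletal ROI smaller than ", min_pixels, " pixels")
  if (any(sk & region_mask))
    stop("region and skeletal ROI overlap")
  skm <- mean(image[sk])
  if (skm <= 0) stop("invalid-reference error: skeletal muscle mean SI <= 0")
  mean(image[region_mask]) / skm
}

#' Classify an SI ratio as edema-positive
#'
#' @param ratio finite SI ratio.
#' @param cutoff decision threshold (default 1.9, the dark-blood TIRM
#'   starting point); the boundary classifies positive.
#' @param cutoff_provenance \code{"default"} or \code{"local"}, recorded in
#'   the result.
#' @return list(positive, ratio, cutoff, cutoff_provenance).
#' @export
edema_classify <- function(ratio, cutoff = 1.9,
                           cutoff_provenance = c("default", "local")) {
  stopifnot(is.finite(ratio))
  list(positive = ratio >= cutoff, ratio = ratio, cutoff = cutoff,
       cutoff_provenance = match.arg(cutoff_provenance))
}

#' Parametric SI-ratio pixel map
#'
#' Per-pixel ratio against the skeletal-muscle mean; myocardial pixels with a
#' ratio at or above \code{map_cutoff} are flagged for the colour overlay.
#'
#' @param image numeric SI matrix.
#' @param myo_mask logical myocardial mask.
#' @param skeletal_mean mean skeletal-muscle SI (> 0).
#' @param map_cutoff flagging threshold (default 2).
#' @return list(ratio = numeric matrix (NA outside myocardium),
#'   flagged = logical matrix, map_cutoff).
#' @export
ratio_map <- function(image, myo_mask, skeletal_mean, map_cutoff = 2) {
  stopifnot(skeletal_mean > 0)
  r <- matrix(NA_real_, nrow(image), ncol(image))
  r[myo_mask] <- image[myo_mask] / skeletal_mean
  list(ratio = r, flagged = !is.na(r) & r >= map_cutoff,
       map_cutoff = map_cutoff)
}
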