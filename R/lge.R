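# Late gadolinium enhancement quantification.
#
# Two semi-automatic thresholding families: the n-SD technique (threshold =
# remote mean + n SD; recommended starting points n = 5 for infarction, n = 3
# for myocarditis) and the FWHM technique (threshold = half the maximal
# signal within the scar core).  Hypoenhanced no-reflow cores enclosed by
# enhancement are counted as infarct.  LGE mass = total enhanced area x
# (slice thickness + gap) x 1.05 g/ml; per-segment transmural extent is
# reported in the five categories 0%, 1-25%, 26-50%, 51-75%, 76-100%.

TRANSMURALITY_BINS <- c("0%", "1-25%", "26-50%", "51-75%", "76-100%")

#' Recommended n for the n-SD LGE threshold
#' @param indication \code{"infarction"} (n = 5) or \code{"myocarditis"}
#'   (n = 3).
#' @return numeric n.
#' @export
nsd_default <- function(indication = c("infarction", "myocarditis")) {
  switch(match.arg(indication), infarction = 5, myocarditis = 3)
}

new_lge_mask <- function(pixels, threshold, method, n = NA_real_,
                         no_reflow_included = FALSE) {
  structure(list(pixels = pixels, threshold = threshold, method = method,
                 n = n, no_reflow_included = no_reflow_included),
            class = "lge_mask")
}

#' @export
print.lge_mask <- function(x, ...) {
  cat(sprintf("<lge_mask method=%s threshold=%.2f pixels=%d no_reflow=%s>\n",
              x$method, x$threshold, sum(x$pixels), x$no_reflow_included))
  invisible(x)
}

#' n-SD LGE mask
#'
#' Threshold = mean + n SD of the remote (normal, dark) myocardial reference
#' ROI; enhanced pixels are myocardial pixels with SI strictly above the
#' threshold.
#'
#' @param image numeric SI matrix.
#' @param myo_mask logical myocardial mask.
#' @param remote_roi remote-myocardium \code{contour_polygon} (or a logical
#'   mask); must cover at least \code{min_pixels} myocardial pixels.
#' @param n number of SDs (default 5, the infarction recommendation).
#' @param pixel_spacing mm/pixel for polygon rasterization.
#' @param min_pixels minimum reference size (default 20).
#' @return an \code{lge_mask}.
#' @export
nsd_mask <- function(image, myo_mask, remote_roi, n = nsd_default("infarction"),
                     pixel_spacing = c(1, 1), min_pixels = 20) {
  rmask <- as_roi_mask(remote_roi, dim(image), pixel_spacing) & myo_mask
  if (sum(rmask) < min_pixels)
    stop("unreliable-reference error: remote ROI smaller than ", min_pixels,
         " myocardial pixels")
  thr <- mean(image[rmask]) + n * stats::sd(image[rmask])
  new_lge_mask(myo_mask & image > thr, thr, "n_sd", n = n)
}

#' FWHM LGE mask
#'
#' Threshold = half of the maximal SI inside the operator-selected scar-core
#' ROI; enhanced pixels are myocardial pixels with SI at or above the
#' threshold (so the maximal pixel always belongs to its own mask).  A
#' warning is raised when the myocardium is so uniform that the whole ROI
#' exceeds the threshold.
#'
#' @param image numeric SI matrix.
#' @param myo_mask logical myocardial mask.
#' @param core_roi scar-core \code{contour_polygon} (or logical mask).
#' @param pixel_spacing mm/pixel.
#' @return an \code{lge_mask}.
#' @export
fwhm_mask <- function(image, myo_mask, core_roi, pixel_spacing = c(1, 1)) {
  cmask <- as_roi_mask(core_roi, dim(image), pixel_spacing) & myo_mask
  if (!any(cmask)) stop("empty core ROI")
  thr <- 0.5 * max(image[cmask])
  m <- myo_mask & image >= thr
  if (all(m[myo_mask]))
    warning("suspicious-uniform: entire myocardium above the half-maximum threshold")
  new_lge_mask(m, thr, "fwhm")
}

as_roi_mask <- function(roi, dm, pixel_spacing) {
  if (is.matrix(roi) && is.logical(roi)) roi
  else rasterize_contour(roi, dm, pixel_spacing)
}

#' Include enclosed no-reflow cores in an LGE mask
#'
#' Hypoenhanced regions fully enclosed in-plane by enhanced pixels are added
#' to the mask (hole filling restricted to the myocardium); idempotent and
#' mask-growing only.
#'
#' @param mask an \code{lge_mask}.
#' @param myo_mask logical myocardial mask.
#' @return the filled \code{lge_mask} with \code{no_reflow_included = TRUE}.
#' @export
fill_no_reflow <- function(mask, myo_mask) {
  m <- mask$pixels
  filled <- EBImage::fillHull(m * 1) > 0
  mask$pixels <- m | (filled & myo_mask)
  mask$no_reflow_included <- TRUE
  mask
}

#' LGE mass, percentage and per-segment transmurality
#'
#' LGE mass sums enhanced area x (thickness + gap) over slices, times the
#' myocardial density 1.05 g/ml.  Per-segment transmural extent is the mean
#' chord enhanced fraction over the segment's chords, binned into the five
#' reporting categories ("0%" only when exactly zero).
#'
#' @param masks list of \code{lge_mask}, one per analysed slice.
#' @param slices list of matching \code{\link{slice_geometry}}.
#' @param lv_mass_g total LV mass in g (> 0).
#' @param model optional \code{\link{aha_model}} for transmurality.
#' @param contours optional list (one per slice) of
#'   \code{list(endo =, epi =)} contour pairs, required with \code{model}.
#' @param n_chords chords per slice for transmurality (default 100).
#' @return list of class \code{lge_quantity}: \code{lge_grams},
#'   \code{lge_percent_of_lv_mass}, \code{per_segment_transmurality} (named
#'   character), \code{per_segment_fraction} (named numeric, percent).
#' @export
lge_quantity <- function(masks, slices, lv_mass_g, model = NULL,
                         contours = NULL, n_chords = 100) {
  if (lv_mass_g <= 0) stop("domain error: lv_mass_g must be > 0")
  stopifnot(length(masks) == length(slices))
  grams <- 0
  for (i in seq_along(masks)) {
    g <- slices[[i]]
    px_area <- prod(g$pixel_spacing_mm)
    grams <- grams + sum(masks[[i]]$pixels) * px_area *
      (g$thickness_mm + g$gap_mm) * MYOCARDIAL_DENSITY_G_PER_ML / 1000
  }
  res <- list(lge_grams = grams,
              lge_percent_of_lv_mass = 100 * grams / lv_mass_g,
              per_segment_transmurality = NULL,
              per_segment_fraction = NULL)
  if (!is.null(model)) {
    stopifnot(!is.null(contours))
    frac <- list()
    for (i in seq_along(masks)) {
      sl <- slices[[i]]
      key <- as.character(sl$index)
      if (!key %in% names(model$ring_of_slice)) next
      ch <- transmural_chords(contours[[i]]$endo, contours[[i]]$epi,
                              masks[[i]]$pixels, n_chords,
                              sl$pixel_spacing_mm)
      ctr <- polygon_centroid(contours[[i]]$epi)
      th <- (ch$angle_deg - model$rv_insertion_angle[[key]]) %% 360
      spans <- model$segment_spans[
        model$segment_spans$ring == model$ring_of_slice[[key]], ]
      for (k in seq_len(nrow(spans))) {
        sel <- th >= spans$start_deg[k] & th < spans$end_deg[k]
        id <- as.character(spans$segment_id[k])
        frac[[id]] <- c(frac[[id]], ch$enhanced_fraction[sel])
      }
    }
    pct <- vapply(frac, function(v) 100 * mean(v), numeric(1))
    res$per_segment_fraction <- pct
    res$per_segment_transmurality <-
      vapply(pct, transmurality_category, character(1))
  }
  class(res) <- "lge_quantity"
  res
}

#' Transmurality reporting category for an enhanced-fraction percentage
#' @param pct transmural extent in percent (0..100).
#' @return one of "0%", "1-25%", "26-50%", "51-75%", "76-100%".
#' @export
transmurality_category <- function(pct) {
  stopifnot(pct >= 0, pct <= 100)
  if (pct == 0) return("0%")
  TRANSMURALITY_BINS[1 + findInterval(pct, c(0, 25, 50, 75),
                                      left.open = TRUE)]
}

#' @export
print.lge_quantity <- function(x, ...) {
  cat(sprintf("LGE mass %.2f g (%.1f%% of LV mass)\n", x$lge_grams,
              x$lge_percent_of_lv_mass))
  if (!is.null(x$per_segment_transmurality)) {
    cat("per-segment transmurality:\n")
    for (s in names(x$per_segment_transmurality))
      cat(sprintf("  segment %s: %s\n", s, x$per_segment_transmurality[[s]]))
  }
  invisible(x)
}
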