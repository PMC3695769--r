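# AHA 16/17-segment model of the left-ventricular myocardium.
#
# Conventions (recorded in the model object so alternates are switchable):
#  - angles are measured counterclockwise (viewed from the apex) starting at
#    the anterior RV insertion point, which defines the anterior /
#    anteroseptal boundary;
#  - per ring, segments are numbered counterclockwise starting with the
#    anterior segment; basal ring ids 1-6, mid 7-12, apical 13-16, apex cap 17;
#  - a boundary angle belongs to the counterclockwise-following segment
#    (half-open spans [start, end)).

#' Build an AHA 16- or 17-segment model over a contour stack
#'
#' Slices carrying myocardium (both endo- and epicardial contours at the
#' reference phase) are partitioned basal-to-apex into basal / mid / apical
#' thirds; remainder slices go to the basal, then the mid ring.  Basal and mid
#' rings hold six 60-degree segments, the apical ring four 90-degree segments;
#' segment 17 (apical cap, full 360 degrees) exists only in the 17-segment
#' model and is never mapped to a short-axis slice automatically.
#'
#' @param stack a \code{\link{contour_stack}}.
#' @param rv_insertion_angles anterior RV insertion angle (degrees,
#'   counterclockwise from +x) -- a single value or one per usable slice.
#' @param n_segments 16 or 17.
#' @param phase reference phase used to find usable slices (default 0).
#' @param slice_indices optionally, the usable slices (0-based) given
#'   explicitly instead of being detected from the contours.
#' @return an object of class \code{aha_model} with fields
#'   \code{n_segments}, \code{ring_of_slice}, \code{rv_insertion_angle},
#'   \code{segment_spans}.
#' @export
build_aha_model <- function(stack, rv_insertion_angles, n_segments = 17,
                            phase = 0, slice_indices = NULL) {
  if (!n_segments %in% c(16L, 17L)) stop("n_segments must be 16 or 17")
  if (is.null(slice_indices)) {
    slice_indices <- Filter(function(i) {
      !is.null(stack_contour(stack, i, phase, "endocardial")) &&
        !is.null(stack_contour(stack, i, phase, "epicardial"))
    }, stack_slice_indices(stack))
  }
  slice_indices <- sort(as.integer(slice_indices))
  n <- length(slice_indices)
  if (n < 3)
    stop("insufficient-coverage error: need >= 3 slices with myocardium")
  base <- n %/% 3L + as.integer(n %% 3L >= 1L)
  mid  <- n %/% 3L + as.integer(n %% 3L >= 2L)
  ring <- rep(c("basal", "mid", "apical"), times = c(base, mid, n - base - mid))
  names(ring) <- as.character(slice_indices)
  ang <- rep(rv_insertion_angles, length.out = n)
  names(ang) <- as.character(slice_indices)
  spans <- rbind(
    data.frame(segment_id = 1:6,  ring = "basal",
               start_deg = (0:5) * 60, end_deg = (1:6) * 60),
    data.frame(segment_id = 7:12, ring = "mid",
               start_deg = (0:5) * 60, end_deg = (1:6) * 60),
    data.frame(segment_id = 13:16, ring = "apical",
               start_deg = (0:3) * 90, end_deg = (1:4) * 90))
  if (n_segments == 17L)
    spans <- rbind(spans, data.frame(segment_id = 17L, ring = "apical_cap",
                                     start_deg = 0, end_deg = 360))
  structure(list(n_segments = as.integer(n_segments), ring_of_slice = ring,
                 rv_insertion_angle = ang, segment_spans = spans),
            class = "aha_model")
}

#' @export
print.aha_model <- function(x, ...) {
  cat(sprintf("<aha_model %d segments, %d slices (%s)>\n", x$n_segments,
              length(x$ring_of_slice),
              paste(sprintf("%s:%d", c("basal", "mid", "apical"),
                            table(factor(x$ring_of_slice,
                                         c("basal", "mid", "apical")))),
                    collapse = " ")))
  invisible(x)
}

#' Segment ids that belong to one ring of an AHA model
#' @param model an \code{aha_model}.
#' @param ring one of "basal", "mid", "apical", "apical_cap".
#' @return integer segment ids.
#' @export
ring_segments <- function(model, ring) {
  model$segment_spans$segment_id[model$segment_spans$ring == ring]
}

#' Assign myocardial pixels to AHA segments
#'
#' Every TRUE pixel of the myocardial mask is assigned to exactly one segment
#' of the slice's ring, by its angle about the myocardial centroid measured
#' from the slice's RV insertion reference.  Boundary angles belong to the
#' counterclockwise-following segment.
#'
#' @param slice_mask logical myocardial pixel mask.
#' @param model an \code{aha_model}.
#' @param slice_index 0-based slice index (must have a ring assignment).
#' @param pixel_spacing length-2 mm/pixel.
#' @param centroid optional c(x, y) mm; default is the mask pixel centroid.
#' @return integer matrix of segment ids (NA outside the mask).
#' @export
assign_pixels_to_segments <- function(slice_mask, model, slice_index,
                                      pixel_spacing = c(1, 1),
                                      centroid = NULL) {
  key <- as.character(slice_index)
  if (!key %in% names(model$ring_of_slice))
    stop(sprintf("slice %d has no ring assignment", slice_index))
  ring <- model$ring_of_slice[[key]]
  if (ring == "apical_cap" && model$n_segments == 16L)
    stop("invalid-ring error: apical_cap requires the 17-segment model")
  if (!any(slice_mask)) stop("empty myocardial mask")
  xy <- mask_coords(slice_mask, pixel_spacing)
  if (is.null(centroid)) centroid <- colMeans(xy)
  theta <- (atan2(xy[, 2] - centroid[2], xy[, 1] - centroid[1]) * 180 / pi -
              model$rv_insertion_angle[[key]]) %% 360
  spans <- model$segment_spans[model$segment_spans$ring == ring, ]
  seg <- rep(NA_integer_, nrow(xy))
  for (k in seq_len(nrow(spans)))
    seg[theta >= spans$start_deg[k] & theta < spans$end_deg[k]] <-
      spans$segment_id[k]
  out <- matrix(NA_integer_, nrow(slice_mask), ncol(slice_mask))
  out[which(slice_mask)] <- seg
  out
}

#' Cast transmural chords across the myocardial wall
#'
#' Chords are cast at equal angular increments from the myocardial centroid,
#' running from the endocardial to the epicardial boundary.  When a pixel
#' mask is supplied, each chord carries the fraction of its length lying
#' inside the mask (\code{enhanced_fraction}), estimated by uniform sampling
#' along the chord; the denominator counts only samples landing on
#' myocardial pixels (rasterized between the two contours), so numerator and
#' denominator share the same edge quantization and a mask covering the
#' whole myocardium yields exactly 1.
#'
#' @param endo,epi endocardial / epicardial \code{contour_polygon}s; epi must
#'   enclose endo.
#' @param mask optional logical pixel mask (e.g. an LGE mask).
#' @param n_chords number of chords (>= 12; default 100).
#' @param pixel_spacing length-2 mm/pixel for mask lookup.
#' @param n_samples samples per chord for the mask fraction (default 200).
#' @return data.frame with one row per chord: \code{angle_deg},
#'   \code{endo_x/y}, \code{epi_x/y}, \code{length_mm},
#'   \code{enhanced_fraction}.
#' @export
transmural_chords <- function(endo, epi, mask = NULL, n_chords = 100,
                              pixel_spacing = c(1, 1), n_samples = 200) {
  if (n_chords < 12) stop("n_chords must be >= 12")
  check_encloses(epi, endo)
  ctr <- polygon_centroid(epi)
  myo <- if (!is.null(mask))
    myocardium_mask(endo, epi, dim(mask), pixel_spacing) else NULL
  angles <- seq(0, 360, length.out = n_chords + 1)[-(n_chords + 1)]
  res <- data.frame(angle_deg = angles, endo_x = NA_real_, endo_y = NA_real_,
                    epi_x = NA_real_, epi_y = NA_real_, length_mm = NA_real_,
                    enhanced_fraction = if (is.null(mask)) NA_real_ else 0)
  for (k in seq_along(angles)) {
    a <- angles[k]
    t_en <- ray_polygon_hits(ctr[1], ctr[2], a, endo)
    t_ep <- ray_polygon_hits(ctr[1], ctr[2], a, epi)
    if (length(t_en) == 0 || length(t_ep) == 0)
      stop("contour-topology error: chord ray misses a contour")
    r0 <- max(t_en); r1 <- max(t_ep)
    if (r1 <= r0) stop("contour-topology error: epi boundary inside endo")
    th <- a * pi / 180
    res$endo_x[k] <- ctr[1] + r0 * cos(th); res$endo_y[k] <- ctr[2] + r0 * sin(th)
    res$epi_x[k]  <- ctr[1] + r1 * cos(th); res$epi_y[k]  <- ctr[2] + r1 * sin(th)
    res$length_mm[k] <- r1 - r0
    if (!is.null(mask)) {
      tt <- r0 + (seq_len(n_samples) - 0.5) / n_samples * (r1 - r0)
      sxm <- ctr[1] + tt * cos(th); sym <- ctr[2] + tt * sin(th)
      cc <- round(sxm / pixel_spacing[1]) + 1L
      rr <- round(sym / pixel_spacing[2]) + 1L
      ok <- cc >= 1L & cc <= ncol(mask) & rr >= 1L & rr <= nrow(mask)
      inside <- in_myo <- logical(n_samples)
      inside[ok] <- mask[cbind(rr[ok], cc[ok])]
      in_myo[ok] <- myo[cbind(rr[ok], cc[ok])]
      res$enhanced_fraction[k] <- sum(inside & in_myo) / max(sum(in_myo), 1L)
    }
  }
  res
}

#' Split the myocardium into endocardial and epicardial halves
#'
#' Each myocardial pixel is classified by its transmural depth
#' d_endo / (d_endo + d_epi), where the distances are to the nearest point of
#' the endo- and epicardial boundaries; depth < 50\% puts the pixel in the
#' endocardial layer.  The two layers partition the myocardial mask.
#'
#' @inheritParams myocardium_mask
#' @return list with logical masks \code{endo_layer} and \code{epi_layer}.
#' @export
split_endo_epi_layers <- function(endo, epi, dim, pixel_spacing = c(1, 1)) {
  myo <- myocardium_mask(endo, epi, dim, pixel_spacing)
  out_en <- out_ep <- matrix(FALSE, dim[1], dim[2])
  if (any(myo)) {
    xy <- mask_coords(myo, pixel_spacing)
    d_en <- dist_to_polygon(xy[, 1], xy[, 2], endo)
    d_ep <- dist_to_polygon(xy[, 1], xy[, 2], epi)
    depth <- d_en / (d_en + d_ep)
    idx <- which(myo)
    out_en[idx[depth < 0.5]] <- TRUE
    out_ep[idx[depth >= 0.5]] <- TRUE
  }
  list(endo_layer = out_en, epi_layer = out_ep)
}
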