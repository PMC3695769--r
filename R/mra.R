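# MR angiography post-processing primitives: subtraction, maximum intensity
# projection, caliper lumen diameters, and the standardized nine-level
# aortic diameter report.

AORTA_LEVELS <- data.frame(
  level_id = 1:9,
  label = c("sinuses of Valsalva", "sinotubular junction",
            "mid-ascending aorta", "proximal to brachiocephalic trunk",
            "between left common carotid and left subclavian arteries",
            "distal to left subclavian artery", "mid-descending aorta",
            "diaphragm", "abdominal aorta above coeliac trunk"),
  requires_gating = c(TRUE, TRUE, rep(FALSE, 7)),
  stringsAsFactors = FALSE)

#' Create a 3D intensity volume
#' @param voxels 3D numeric array.
#' @param spacing_mm c(dx, dy, dz) voxel spacing in mm (> 0).
#' @return an object of class \code{volume3d}.
#' @export
volume3d <- function(voxels, spacing_mm = c(1, 1, 1)) {
  stopifnot(length(dim(voxels)) == 3, all(spacing_mm > 0))
  structure(list(voxels = voxels, spacing_mm = spacing_mm), class = "volume3d")
}

#' Subtract a pre-contrast from a post-contrast angiographic volume
#' @param post,pre \code{volume3d} objects with identical dimensions and
#'   spacing.
#' @return \code{volume3d} of voxelwise post - pre.
#' @export
subtract_mra <- function(post, pre) {
  if (!identical(dim(post$voxels), dim(pre$voxels)) ||
      !isTRUE(all.equal(post$spacing_mm, pre$spacing_mm)))
    stop("geometry error: volume dimensions/spacing mismatch")
  volume3d(post$voxels - pre$voxels, post$spacing_mm)
}

#' Maximum intensity projection of a 3D volume
#' @param volume a \code{volume3d}.
#' @param axis projection axis, 1..3.
#' @return 2D matrix of per-ray maxima.
#' @export
mip_projection <- function(volume, axis = 3L) {
  stopifnot(axis %in% 1:3)
  apply(volume$voxels, setdiff(1:3, axis), max)
}

#' Vessel diameter from a perpendicular cross-section
#'
#' Inner diameter: the widest caliper width of the lumen region, i.e. the
#' maximal distance between two boundary points of the convex hull of the
#' lumen cross-section (which must be taken perpendicular to the vessel
#' axis).  Outer diameter: lumen plus wall extent, measured along the same
#' direction as the widest inner diameter.
#'
#' @param lumen logical cross-section mask or a \code{contour_polygon}.
#' @param mode \code{"inner"} or \code{"outer"}.
#' @param wall_mask logical mask of the vessel wall (required for
#'   \code{"outer"}).
#' @param pixel_spacing mm/pixel for mask input.
#' @return diameter in mm.
#' @export
vessel_diameter <- function(lumen, mode = c("inner", "outer"),
                            wall_mask = NULL, pixel_spacing = c(1, 1)) {
  mode <- match.arg(mode)
  pts <- if (inherits(lumen, "contour_polygon")) cbind(lumen$x, lumen$y)
  else mask_coords(lumen, pixel_spacing)
  if (nrow(pts) == 0) stop("empty lumen mask")
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  d2 <- as.matrix(stats::dist(hull))
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  inner <- d2[ij[1], ij[2]]
  if (mode == "inner") return(inner)
  stopifnot(!is.null(wall_mask))
  u <- (hull[ij[2], ] - hull[ij[1], ]) / inner
  wpts <- rbind(pts, mask_coords(wall_mask, pixel_spacing))
  proj <- wpts %*% u
  max(proj) - min(proj)
}

#' Standardized multilevel aortic diameter report
#'
#' Produces the fixed nine-level table (sinuses of Valsalva through the
#' abdominal aorta above the coeliac trunk).  Sinus and sinotubular-junction
#' diameters are suppressed unless measured on ECG-gated acquisitions; for
#' the sinus level all three sinus-commissure dimensions may be supplied and
#' are reported individually.
#'
#' @param measurements data.frame with columns \code{level_id} (1-9),
#'   \code{inner_diameter_mm}, optional \code{outer_diameter_mm} and
#'   \code{gated} (logical).  Several rows per level are allowed for the
#'   sinus-commissure dimensions.
#' @return data.frame report with one row per measurement slot, all nine
#'   levels present (missing ones marked), and a \code{note} column.
#' @export
aorta_level_report <- function(measurements = NULL) {
  if (is.null(measurements))
    measurements <- data.frame(level_id = integer(0),
                               inner_diameter_mm = numeric(0))
  if (nrow(measurements) > 0 && !all(measurements$level_id %in% 1:9))
    stop("unknown aortic level id")
  if (is.null(measurements$outer_diameter_mm))
    measurements$outer_diameter_mm <- rep(NA_real_, nrow(measurements))
  if (is.null(measurements$gated))
    measurements$gated <- rep(FALSE, nrow(measurements))
  if (any(!is.na(measurements$outer_diameter_mm) &
          measurements$outer_diameter_mm < measurements$inner_diameter_mm))
    stop("outer diameter smaller than inner diameter")
  rows <- list()
  for (lv in 1:9) {
    cat_row <- AORTA_LEVELS[AORTA_LEVELS$level_id == lv, ]
    mm <- measurements[measurements$level_id == lv, , drop = FALSE]
    if (nrow(mm) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        level_id = lv, label = cat_row$label, inner_diameter_mm = NA_real_,
        outer_diameter_mm = NA_real_, reported = FALSE, note = "not measured")
      next
    }
    for (k in seq_len(nrow(mm))) {
      ok <- !cat_row$requires_gating || isTRUE(mm$gated[k])
      rows[[length(rows) + 1]] <- data.frame(
        level_id = lv, label = cat_row$label,
        inner_diameter_mm = if (ok) mm$inner_diameter_mm[k] else NA_real_,
        outer_diameter_mm = if (ok) mm$outer_diameter_mm[k] else NA_real_,
        reported = ok,
        note = if (ok) {
          if (nrow(mm) > 1) sprintf("sinus-commissure dimension %d of %d", k, nrow(mm))
          else ""
        } else "requires ECG gated acquisitions")
    }
  }
  do.call(rbind, rows)
}
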