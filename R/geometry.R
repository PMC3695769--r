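# Coordinate conventions used throughout the package:
#  - in-plane coordinates are in mm; x increases with matrix column, y with
#    matrix row; pixel centers sit at x = (col-1)*sx, y = (row-1)*sy
#  - angles are in degrees, measured counterclockwise from the +x axis
#  - slice 0 is the most basal slice; slice index increases toward the apex

CONTOUR_ROLES <- c("endocardial", "epicardial", "papillary", "blood_pool_roi",
                   "remote_roi", "skeletal_muscle_roi", "scar_core_roi",
                   "vessel_lumen", "generic")

#' Create a planar contour polygon
#'
#' A closed, simple polygon in mm coordinates with a semantic role.  The
#' polygon is implicitly closed (the last vertex connects back to the first).
#'
#' @param x,y numeric vertex coordinates in mm (at least 3 vertices).
#' @param role one of the recognised contour roles, e.g. \code{"endocardial"},
#'   \code{"epicardial"}, \code{"papillary"}, \code{"remote_roi"}.
#' @return an object of class \code{contour_polygon}.
#' @export
contour_polygon <- function(x, y, role = "generic") {
  role <- match.arg(role, CONTOUR_ROLES)
  if (length(x) != length(y))
    stop("invalid contour: x and y must have equal length")
  if (length(x) < 3L)
    stop("invalid contour: a polygon needs at least 3 vertices")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("invalid contour: non-finite vertex coordinates")
  p <- structure(list(x = as.numeric(x), y = as.numeric(y), role = role),
                 class = "contour_polygon")
  if (.shoelace(p$x, p$y) == 0)
    stop("invalid contour: enclosed area is zero")
  p
}

#' @export
print.contour_polygon <- function(x, ...) {
  cat(sprintf("<contour_polygon role=%s vertices=%d area=%.2f mm^2>\n",
              x$role, length(x$x), polygon_area(x)))
  invisible(x)
}

.shoelace <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Enclosed area of a contour polygon
#'
#' Shoelace area of the closed polygon, independent of vertex orientation.
#'
#' @param polygon a \code{contour_polygon}.
#' @return area in mm^2.
#' @export
polygon_area <- function(polygon) {
  stopifnot(inherits(polygon, "contour_polygon"))
  a <- .shoelace(polygon$x, polygon$y)
  if (a == 0) stop("invalid contour: degenerate polygon")
  a
}

#' Area centroid of a contour polygon
#' @param polygon a \code{contour_polygon}.
#' @return numeric c(x, y) in mm.
#' @export
polygon_centroid <- function(polygon) {
  x <- polygon$x; y <- polygon$y
  n <- length(x)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps)
    return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

#' Test points for inclusion in a polygon
#' @param px,py numeric point coordinates (mm).
#' @param polygon a \code{contour_polygon}.
#' @return logical vector (boundary points count as inside).
#' @export
points_in_polygon <- function(px, py, polygon) {
  pracma::inpolygon(px, py, polygon$x, polygon$y, boundary = TRUE)
}

#' Distance from points to a polygon boundary
#' @param px,py numeric point coordinates (mm).
#' @param polygon a \code{contour_polygon}.
#' @return numeric vector of Euclidean distances (mm) to the closed boundary.
#' @export
dist_to_polygon <- function(px, py, polygon) {
  vx <- polygon$x; vy <- polygon$y
  n <- length(vx)
  j <- c(2:n, 1L)
  d2 <- rep(Inf, length(px))
  for (k in seq_len(n)) {
    ax <- vx[k]; ay <- vy[k]
    bx <- vx[j[k]]; by <- vy[j[k]]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
    qx <- ax + t * dx; qy <- ay + t * dy
    d2 <- pmin(d2, (px - qx)^2 + (py - qy)^2)
  }
  sqrt(d2)
}

# Distances t > 0 along the ray origin + t*(cos a, sin a) at which the ray
# crosses polygon edges; sorted ascending.
ray_polygon_hits <- function(ox, oy, angle_deg, polygon) {
  th <- angle_deg * pi / 180
  dx <- cos(th); dy <- sin(th)
  vx <- polygon$x; vy <- polygon$y
  n <- length(vx)
  j <- c(2:n, 1L)
  ts <- numeric(0)
  for (k in seq_len(n)) {
    ex <- vx[j[k]] - vx[k]; ey <- vy[j[k]] - vy[k]
    den <- dx * ey - dy * ex
    if (abs(den) < 1e-12) next
    # solve o + t d = v_k + s e
    wx <- vx[k] - ox; wy <- vy[k] - oy
    t <- (wx * ey - wy * ex) / den
    s <- (wx * dy - wy * dx) / den
    # tolerance so a ray exactly through a shared vertex is caught by one
    # of the two adjacent edges despite rounding
    if (t > 1e-9 && s >= -1e-9 && s < 1 - 1e-9) ts <- c(ts, t)
  }
  sort(ts)
}

#' Slice geometry of a short-axis (or transaxial) image slice
#'
#' @param index 0-based slice index, 0 = most basal.
#' @param z_mm slice location along the stack axis (mm).
#' @param thickness_mm slice thickness (> 0 mm).
#' @param gap_mm interslice gap (>= 0 mm).
#' @param pixel_spacing_mm length-2 in-plane pixel spacing (mm/pixel).
#' @return an object of class \code{slice_geometry}.
#' @export
slice_geometry <- function(index, z_mm, thickness_mm, gap_mm = 0,
                           pixel_spacing_mm = c(1, 1)) {
  stopifnot(thickness_mm > 0, gap_mm >= 0, all(pixel_spacing_mm > 0),
            index >= 0)
  structure(list(index = as.integer(index), z_mm = z_mm,
                 thickness_mm = thickness_mm, gap_mm = gap_mm,
                 pixel_spacing_mm = rep(pixel_spacing_mm, length.out = 2)),
            class = "slice_geometry")
}

#' Study-level metadata
#'
#' Heart rate and body surface area are manually overridable inputs used for
#' cardiac output and indexed values.
#'
#' @param heart_rate_bpm heart rate, beats/min (> 0).
#' @param bsa_m2 body surface area, m^2 (> 0); may be NA when no indexing is
#'   requested.
#' @param acquisition_plane one of \code{"short_axis"}, \code{"transaxial"},
#'   \code{"long_axis"}.
#' @return an object of class \code{study_meta}.
#' @export
study_meta <- function(heart_rate_bpm = NA_real_, bsa_m2 = NA_real_,
                       acquisition_plane = "short_axis") {
  acquisition_plane <- match.arg(acquisition_plane,
                                 c("short_axis", "transaxial", "long_axis"))
  if (!is.na(heart_rate_bpm) && heart_rate_bpm <= 0)
    stop("heart_rate_bpm must be > 0")
  if (!is.na(bsa_m2) && bsa_m2 <= 0)
    stop("bsa_m2 must be > 0")
  structure(list(heart_rate_bpm = heart_rate_bpm, bsa_m2 = bsa_m2,
                 acquisition_plane = acquisition_plane),
            class = "study_meta")
}

#' Multi-slice, multi-phase contour container
#'
#' Holds the slice geometry of a stack together with the contours drawn on
#' each (slice, phase) and the study metadata.  Contours are added with
#' \code{\link{stack_add_contour}}.
#'
#' @param slices list of \code{\link{slice_geometry}} objects.
#' @param n_phases number of cardiac phases (>= 1).
#' @param meta a \code{\link{study_meta}}.
#' @return an object of class \code{contour_stack}.
#' @export
contour_stack <- function(slices, n_phases = 1L, meta = study_meta()) {
  stopifnot(length(slices) >= 1, n_phases >= 1)
  idx <- vapply(slices, function(s) s$index, integer(1))
  if (anyDuplicated(idx)) stop("duplicate slice indices")
  slices <- slices[order(idx)]
  structure(list(slices = slices, contours = list(),
                 n_phases = as.integer(n_phases), meta = meta),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  cat(sprintf("<contour_stack slices=%d phases=%d contours=%d plane=%s>\n",
              length(x$slices), x$n_phases, length(x$contours),
              x$meta$acquisition_plane))
  invisible(x)
}

#' Add a contour to a stack
#' @param stack a \code{contour_stack}.
#' @param slice 0-based slice index (must exist in the stack).
#' @param phase 0-based phase index.
#' @param polygon a \code{contour_polygon}; its role keys the lookup.
#' @return the updated stack.
#' @export
stack_add_contour <- function(stack, slice, phase, polygon) {
  stopifnot(inherits(stack, "contour_stack"),
            inherits(polygon, "contour_polygon"))
  if (!slice %in% stack_slice_indices(stack))
    stop(sprintf("slice %d not present in stack", slice))
  if (phase < 0 || phase >= stack$n_phases)
    stop(sprintf("phase %d outside 0..%d", phase, stack$n_phases - 1L))
  stack$contours[[length(stack$contours) + 1L]] <-
    list(slice = as.integer(slice), phase = as.integer(phase), polygon = polygon)
  stack
}

#' @rdname stack_add_contour
#' @export
stack_slice_indices <- function(stack) {
  vapply(stack$slices, function(s) s$index, integer(1))
}

#' Retrieve contours from a stack
#'
#' \code{stack_contours} returns all matching polygons (possibly several, e.g.
#' papillary); \code{stack_contour} returns the single match or \code{NULL}.
#'
#' @param stack a \code{contour_stack}.
#' @param slice,phase 0-based indices.
#' @param role contour role to match.
#' @return list of \code{contour_polygon} (or one / NULL for
#'   \code{stack_contour}).
#' @export
stack_contours <- function(stack, slice, phase, role) {
  out <- list()
  for (e in stack$contours)
    if (e$slice == slice && e$phase == phase && e$polygon$role == role)
      out[[length(out) + 1L]] <- e$polygon
  out
}

#' @rdname stack_contours
#' @export
stack_contour <- function(stack, slice, phase, role) {
  cs <- stack_contours(stack, slice, phase, role)
  if (length(cs) == 0) return(NULL)
  if (length(cs) > 1) stop(sprintf("multiple '%s' contours on slice %d phase %d",
                                   role, slice, phase))
  cs[[1]]
}

#' Slice geometry lookup by index
#' @param stack a \code{contour_stack}.
#' @param slice 0-based slice index.
#' @return the \code{slice_geometry}.
#' @export
stack_slice <- function(stack, slice) {
  for (s in stack$slices) if (s$index == slice) return(s)
  stop(sprintf("slice %d not present in stack", slice))
}

#' Rasterize a contour polygon onto a pixel grid
#'
#' Pixel-center-in-polygon test: pixel (row, col) has center
#' x = (col-1)*sx, y = (row-1)*sy.
#'
#' @param polygon a \code{contour_polygon}.
#' @param dim c(nrow, ncol) of the target grid.
#' @param pixel_spacing length-2 mm/pixel.
#' @return logical matrix mask.
#' @export
rasterize_contour <- function(polygon, dim, pixel_spacing = c(1, 1)) {
  nr <- dim[1]; nc <- dim[2]
  sx <- pixel_spacing[1]; sy <- pixel_spacing[2]
  cx <- rep((seq_len(nc) - 1) * sx, each = nr)
  cy <- rep((seq_len(nr) - 1) * sy, times = nc)
  matrix(points_in_polygon(cx, cy, polygon), nr, nc)
}

#' Myocardial mask between endo- and epicardial contours
#' @inheritParams rasterize_contour
#' @param endo,epi endocardial and epicardial \code{contour_polygon}s (epi
#'   must enclose endo).
#' @return logical matrix mask of the myocardium.
#' @export
myocardium_mask <- function(endo, epi, dim, pixel_spacing = c(1, 1)) {
  check_encloses(epi, endo)
  rasterize_contour(epi, dim, pixel_spacing) &
    !rasterize_contour(endo, dim, pixel_spacing)
}

check_encloses <- function(outer, inner) {
  if (!all(points_in_polygon(inner$x, inner$y, outer)))
    stop("contour-topology error: inner contour not enclosed by outer contour")
  invisible(TRUE)
}

# coordinates (mm) of every TRUE pixel of a mask
mask_coords <- function(mask, pixel_spacing = c(1, 1)) {
  ij <- which(mask, arr.ind = TRUE)
  cbind(x = (ij[, 2] - 1) * pixel_spacing[1],
        y = (ij[, 1] - 1) * pixel_spacing[2])
}
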