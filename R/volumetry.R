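# Bi-ventricular volumetry by Simpson slice summation, LV mass, area-length
# volumes and linear dimensions.
#
# Simpson summation: volume = sum over contoured slices of cross-sectional
# area x (slice thickness + interslice gap); the same step is applied at the
# stack ends.  Myocardial specific density: 1.05 g/ml.

MYOCARDIAL_DENSITY_G_PER_ML <- 1.05

#' Blood volume contributed by one slice at one phase
#'
#' Endocardial area times (thickness + gap).  Papillary polygons are
#' subtracted from the blood pool when \code{papillary_mode =
#' "included_in_myocardium"}, and left in the blood pool (common clinical
#' practice) when \code{"included_in_blood"}.
#'
#' @param stack a \code{\link{contour_stack}}.
#' @param slice,phase 0-based indices.
#' @param papillary_mode \code{"included_in_blood"} or
#'   \code{"included_in_myocardium"}.
#' @return volume in ml.
#' @export
slice_blood_volume <- function(stack, slice, phase,
                               papillary_mode = c("included_in_blood",
                                                  "included_in_myocardium")) {
  papillary_mode <- match.arg(papillary_mode)
  endo <- stack_contour(stack, slice, phase, "endocardial")
  if (is.null(endo))
    stop(sprintf("missing-contour error: no endocardial contour on slice %d phase %d",
                 slice, phase))
  a <- polygon_area(endo)
  if (papillary_mode == "included_in_myocardium") {
    for (p in stack_contours(stack, slice, phase, "papillary"))
      a <- a - polygon_area(p)
    a <- max(a, 0)
  }
  g <- stack_slice(stack, slice)
  a * (g$thickness_mm + g$gap_mm) / 1000
}

# total blood volume of one phase over the given slices (ml)
phase_total_volume <- function(stack, phase, slices, papillary_mode) {
  sum(vapply(slices, function(s)
    slice_blood_volume(stack, s, phase, papillary_mode), numeric(1)))
}

#' Select global end-diastolic and end-systolic phases
#'
#' One single phase is chosen for ED (largest summed blood volume across all
#' contoured slices) and one for ES (smallest); the same phase applies to
#' every slice.  Phases with incomplete contour coverage (fewer contoured
#' slices than the best-covered phase) are excluded with a warning.  Ties are
#' broken toward the earlier phase.
#'
#' @param stack a \code{\link{contour_stack}}.
#' @param papillary_mode passed to \code{\link{slice_blood_volume}}.
#' @return list(ed_phase, es_phase, volumes_ml) with per-phase totals (NA for
#'   excluded phases).
#' @export
select_global_ed_es <- function(stack, papillary_mode = "included_in_blood") {
  phases <- seq_len(stack$n_phases) - 1L
  cover <- lapply(phases, function(ph)
    Filter(function(s) !is.null(stack_contour(stack, s, ph, "endocardial")),
           stack_slice_indices(stack)))
  n_cov <- lengths(cover)
  full <- max(n_cov)
  if (full == 0) stop("no phase has endocardial contours")
  usable <- which(n_cov == full)
  if (length(usable) < length(phases))
    warning(sprintf("excluded %d phase(s) with incomplete contour coverage",
                    length(phases) - length(usable)))
  if (length(usable) < 2) stop("need >= 2 phases with complete contours")
  vols <- rep(NA_real_, length(phases))
  for (i in usable)
    vols[i] <- phase_total_volume(stack, phases[i], cover[[i]], papillary_mode)
  list(ed_phase = phases[which.max(vols)], es_phase = phases[which.min(vols)],
       volumes_ml = vols)
}

#' Classify a basal (or apical) slice for inclusion in volume and mass
#'
#' Implements the basal-descent rule: a basal slice whose blood pool is less
#' than half surrounded by myocardium at end-diastole, and whose cavity area
#' expands from ED to ES, is left atrium and excluded entirely.  A slice with
#' myocardium but no discernible blood pool contributes to mass only (a
#' crescent of basal myocardium, or the apical myocardial cap).
#'
#' @param stack a \code{\link{contour_stack}}.
#' @param slice 0-based slice index.
#' @param ed_phase,es_phase global phase indices.
#' @param myo_adjacency_threshold fraction of the endocardial perimeter that
#'   must be adjacent to myocardium (default 0.5).
#' @param adjacency_dist_mm distance within which an endocardial boundary
#'   point counts as adjacent to the epicardial contour (default 3 mm).
#' @return list(classification, reason); classification is one of
#'   \code{"ventricular_blood_and_mass"}, \code{"atrium_exclude"},
#'   \code{"mass_only_crescent"}, \code{"apical_mass_only"}.
#' @export
classify_basal_slice <- function(stack, slice, ed_phase, es_phase,
                                 myo_adjacency_threshold = 0.5,
                                 adjacency_dist_mm = 3) {
  endo_ed <- stack_contour(stack, slice, ed_phase, "endocardial")
  epi_ed  <- stack_contour(stack, slice, ed_phase, "epicardial")
  idx <- stack_slice_indices(stack)
  if (is.null(endo_ed)) {
    if (is.null(epi_ed))
      return(list(classification = "ventricular_blood_and_mass",
                  reason = "no contours on slice; nothing to classify"))
    if (slice == max(idx))
      return(list(classification = "apical_mass_only",
                  reason = "apical myocardium without cavity: mass only"))
    return(list(classification = "mass_only_crescent",
                reason = "myocardial crescent without blood pool: mass only"))
  }
  frac <- if (is.null(epi_ed)) 0 else
    myocardial_adjacency_fraction(endo_ed, epi_ed, adjacency_dist_mm)
  endo_es <- stack_contour(stack, slice, es_phase, "endocardial")
  expanding <- !is.null(endo_es) &&
    polygon_area(endo_es) > polygon_area(endo_ed)
  if (frac < myo_adjacency_threshold && expanding)
    return(list(classification = "atrium_exclude",
                reason = sprintf(paste0("blood pool %.0f%% surrounded by ",
                                        "myocardium (<%.0f%%) and expanding in systole: atrium"),
                                 100 * frac, 100 * myo_adjacency_threshold)))
  list(classification = "ventricular_blood_and_mass",
       reason = sprintf("%.0f%% surrounded by myocardium", 100 * frac))
}

# fraction of endocardial boundary sample points adjacent to the epicardial
# contour (inside it, or within dist_mm of its boundary)
myocardial_adjacency_fraction <- function(endo, epi, dist_mm = 3,
                                          n_samples = 256) {
  pts <- sample_polygon_boundary(endo, n_samples)
  adj <- points_in_polygon(pts[, 1], pts[, 2], epi) |
    (dist_to_polygon(pts[, 1], pts[, 2], epi) <= dist_mm)
  mean(adj)
}

# n points uniformly (by arc length) on the closed polygon boundary
sample_polygon_boundary <- function(polygon, n) {
  x <- c(polygon$x, polygon$x[1]); y <- c(polygon$y, polygon$y[1])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  cs <- c(0, cumsum(seg))
  tt <- seq(0, cs[length(cs)], length.out = n + 1)[-(n + 1)]
  k <- findInterval(tt, cs, rightmost.closed = TRUE)
  k[k >= length(cs)] <- length(cs) - 1L
  w <- (tt - cs[k]) / pmax(seg[k], .Machine$double.eps)
  cbind(x[k] + w * (x[k + 1] - x[k]), y[k] + w * (y[k + 1] - y[k]))
}

#' Left-ventricular mass at one phase
#'
#' Mass = (total epicardial volume - total endocardial volume) x 1.05 g/ml,
#' each volume the Simpson sum of slice areas x (thickness + gap).  Slices
#' with an epicardial contour only (basal crescent / apical cap) contribute
#' wall volume with zero cavity.  Papillary polygons are added to the
#' myocardium when \code{papillary_mode = "included_in_myocardium"}.
#'
#' @param stack a \code{\link{contour_stack}}.
#' @param phase 0-based phase index (conventionally end-diastole).
#' @param papillary_mode see \code{\link{slice_blood_volume}}.
#' @param exclude_slices slices excluded from mass (e.g. atrial slices).
#' @return mass in g.
#' @export
lv_mass <- function(stack, phase, papillary_mode = "included_in_blood",
                    exclude_slices = integer(0)) {
  papillary_mode <- match.arg(papillary_mode,
                              c("included_in_blood", "included_in_myocardium"))
  wall_ml <- 0
  any_epi <- FALSE
  for (s in setdiff(stack_slice_indices(stack), exclude_slices)) {
    epi <- stack_contour(stack, s, phase, "epicardial")
    if (is.null(epi)) next
    any_epi <- TRUE
    endo <- stack_contour(stack, s, phase, "endocardial")
    a_epi <- polygon_area(epi)
    a_endo <- if (is.null(endo)) 0 else polygon_area(endo)
    if (a_endo > a_epi)
      stop(sprintf("contour-topology error: endocardial area exceeds epicardial on slice %d", s))
    a_wall <- a_epi - a_endo
    if (papillary_mode == "included_in_myocardium")
      for (p in stack_contours(stack, s, phase, "papillary"))
        a_wall <- a_wall + polygon_area(p)
    g <- stack_slice(stack, s)
    wall_ml <- wall_ml + a_wall * (g$thickness_mm + g$gap_mm) / 1000
  }
  if (!any_epi) stop("missing-contour error: no epicardial contours at phase")
  wall_ml * MYOCARDIAL_DENSITY_G_PER_ML
}

new_volumetry_result <- function(chamber, edv, esv, ed_phase, es_phase, meta,
                                 mass = NA_real_, papillary_mode = NA_character_,
                                 method = "simpson_stack") {
  sv <- edv - esv
  ef <- 100 * sv / edv
  hr <- meta$heart_rate_bpm
  bsa <- meta$bsa_m2
  co <- if (is.na(hr)) NA_real_ else sv * hr / 1000
  idx <- function(v) if (is.na(bsa)) NA_real_ else v / bsa
  structure(list(chamber = chamber, edv_ml = edv, esv_ml = esv, sv_ml = sv,
                 ef_pct = ef, co_l_min = co, mass_g = mass,
                 edvi_ml_m2 = idx(edv), esvi_ml_m2 = idx(esv),
                 svi_ml_m2 = idx(sv),
                 ci_l_min_m2 = if (is.na(co)) NA_real_ else idx(co),
                 massi_g_m2 = if (is.na(mass)) NA_real_ else idx(mass),
                 ed_phase = ed_phase, es_phase = es_phase,
                 papillary_mode = papillary_mode, method = method,
                 mass_computed = !is.na(mass),
                 reference_range = ""),
            class = "volumetry_result")
}

#' @export
print.volumetry_result <- function(x, ...) {
  cat(sprintf("%s volumetry (%s, papillary %s)\n", toupper(x$chamber),
              x$method, x$papillary_mode))
  cat(sprintf("  EDV %.1f ml  ESV %.1f ml  SV %.1f ml  EF %.1f%%\n",
              x$edv_ml, x$esv_ml, x$sv_ml, x$ef_pct))
  if (!is.na(x$co_l_min)) cat(sprintf("  CO %.2f L/min\n", x$co_l_min))
  if (x$mass_computed) cat(sprintf("  mass %.1f g\n", x$mass_g))
  else cat(sprintf("  mass: not computed for %s\n", toupper(x$chamber)))
  invisible(x)
}

#' Full left-ventricular assessment
#'
#' Simpson summation over slices classified as ventricular blood-and-mass
#' (outflow-tract contours count as blood), with the global ED/ES phase
#' selection, basal/apical slice classification, mass at ED, and derived
#' values (SV, EF, CO and BSA-indexed values).
#'
#' @param stack a \code{\link{contour_stack}} (short-axis).
#' @param papillary_mode \code{"included_in_blood"} (default) or
#'   \code{"included_in_myocardium"}; recorded in the result.
#' @param es_phase_override optional caller-supplied ES phase (e.g. from
#'   aortic valve closure); logged in the result method tag.
#' @return a \code{volumetry_result}.
#' @export
lv_assessment <- function(stack, papillary_mode = c("included_in_blood",
                                                    "included_in_myocardium"),
                          es_phase_override = NULL) {
  papillary_mode <- match.arg(papillary_mode)
  sel <- select_global_ed_es(stack, papillary_mode)
  ed <- sel$ed_phase
  es <- if (is.null(es_phase_override)) sel$es_phase else as.integer(es_phase_override)
  chamber_assessment(stack, "lv", ed, es, papillary_mode, compute_mass = TRUE)
}

#' Full right-ventricular assessment
#'
#' Same Simpson path as the LV (trabeculations are assumed smoothed into the
#' blood pool by the supplied contours).  RV mass is not computed in routine
#' assessment; the result carries an explicit not-computed marker, not zero.
#'
#' @param stack a \code{\link{contour_stack}} (short-axis or transaxial).
#' @param papillary_mode see \code{\link{lv_assessment}}.
#' @return a \code{volumetry_result} with \code{mass_computed = FALSE}.
#' @export
rv_assessment <- function(stack, papillary_mode = "included_in_blood") {
  sel <- select_global_ed_es(stack, papillary_mode)
  chamber_assessment(stack, "rv", sel$ed_phase, sel$es_phase, papillary_mode,
                     compute_mass = FALSE)
}

chamber_assessment <- function(stack, chamber, ed, es, papillary_mode,
                               compute_mass) {
  idx <- stack_slice_indices(stack)
  cls <- lapply(idx, function(s) {
    if (s %in% c(min(idx), sort(idx)[min(2, length(idx))], max(idx)))
      classify_basal_slice(stack, s, ed, es)$classification
    else "ventricular_blood_and_mass"
  })
  names(cls) <- as.character(idx)
  blood_slices <- idx[cls == "ventricular_blood_and_mass" &
                        vapply(idx, function(s)
                          !is.null(stack_contour(stack, s, ed, "endocardial")),
                          logical(1))]
  excl <- idx[cls == "atrium_exclude"]
  edv <- phase_total_volume(stack, ed, blood_slices, papillary_mode)
  esv <- phase_total_volume(stack, es,
                            Filter(function(s)
                              !is.null(stack_contour(stack, s, es, "endocardial")),
                              blood_slices),
                            papillary_mode)
  mass <- if (compute_mass)
    tryCatch(lv_mass(stack, ed, papillary_mode, exclude_slices = excl),
             error = function(e) NA_real_)
  else NA_real_
  new_volumetry_result(chamber, edv, esv, ed, es, stack$meta, mass,
                       papillary_mode)
}

#' Area-length ventricular volume from long-axis views
#'
#' Single long-axis equation: V = 0.85 A^2 / L; biplane: V = 0.85 A1 A2 / L,
#' with planimetered cavity areas in cm^2 and the cavity length (midpoint of
#' the mitral annular line to the apical tip) in cm.  The result is tagged
#' with the method so reports can carry the mandated mention of the analysis
#' technique.
#'
#' @param mode \code{"single"} or \code{"biplane"}.
#' @param area1 LV cavity area, cm^2 (4-chamber view).
#' @param area2 second cavity area, cm^2 (2-chamber view; biplane only).
#' @param length LV length, cm.
#' @return volume in ml, with attribute \code{method}.
#' @export
area_length_volume <- function(mode = c("single", "biplane"), area1,
                               area2 = NULL, length) {
  mode <- match.arg(mode)
  if (area1 <= 0 || length <= 0) stop("domain error: non-positive input")
  v <- if (mode == "single") 0.85 * area1^2 / length
  else {
    if (is.null(area2) || area2 <= 0) stop("domain error: biplane needs area2 > 0")
    0.85 * area1 * area2 / length
  }
  structure(v, method = paste0("area_length_", mode))
}

#' LV/RV stroke-volume consistency check
#'
#' In the absence of shunt or significant valvular regurgitation the two
#' stroke volumes should be nearly equal, so the LV value can be used to
#' validate the RV value.
#'
#' @param lv_sv,rv_sv stroke volumes in ml (> 0).
#' @param tolerance_fraction relative-difference tolerance (default 0.10);
#'   the boundary counts as consistent.
#' @return list(relative_difference, consistent, note).
#' @export
stroke_volume_consistency <- function(lv_sv, rv_sv, tolerance_fraction = 0.10) {
  stopifnot(lv_sv > 0, rv_sv > 0)
  d <- abs(lv_sv - rv_sv) / lv_sv
  list(relative_difference = d, consistent = d <= tolerance_fraction,
       note = "LV stroke volume may be used to validate the RV value in the absence of shunt or regurgitation")
}

#' Cavity diameter and wall thicknesses along a direction
#'
#' Distances are measured along the stated direction through the cavity
#' centroid: the cavity diameter between the two endocardial intersections,
#' and the septal / lateral wall thickness between the endo- and epicardial
#' intersections on each side.  The "septal" value is the wall on the ray at
#' \code{direction}; "lateral" on the opposite ray.
#'
#' @param endo,epi endocardial and epicardial \code{contour_polygon}s.
#' @param direction angle in degrees (counterclockwise from +x).
#' @return list(cavity_diameter_mm, septal_wall_mm, lateral_wall_mm).
#' @export
linear_dimensions <- function(endo, epi, direction = 0) {
  check_encloses(epi, endo)
  ctr <- polygon_centroid(endo)
  d1 <- .wall_hits(ctr, direction, endo, epi)
  d2 <- .wall_hits(ctr, direction + 180, endo, epi)
  list(cavity_diameter_mm = d1$endo + d2$endo,
       septal_wall_mm = d1$epi - d1$endo,
       lateral_wall_mm = d2$epi - d2$endo)
}

.wall_hits <- function(ctr, ang, endo, epi) {
  t_en <- ray_polygon_hits(ctr[1], ctr[2], ang, endo)
  t_ep <- ray_polygon_hits(ctr[1], ctr[2], ang, epi)
  if (length(t_en) == 0 || length(t_ep) == 0)
    stop("geometry error: direction line misses a contour")
  list(endo = max(t_en), epi = max(t_ep))
}
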