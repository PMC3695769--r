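# Semi-quantitative first-pass perfusion analysis.
#
# SI-time curves are extracted per AHA segment (optionally split into
# endocardial/epicardial layers) plus one LV blood-pool curve.  Curve
# features follow the standard semi-quantitative set: maximal upslope (least
# squares over a sliding window), upslope normalized to the LV blood pool,
# time to peak, and the upslope integral from contrast arrival to peak.
# Contrast arrival is detected at baseline + 2 SD(baseline).
#
# The rule-based classifier separates inducible perfusion defects from dark
# banding (Gibbs ringing) artifacts: a defect begins at/after myocardial
# contrast arrival, persists beyond peak enhancement for more than 4 RR
# intervals, is more than one pixel wide, never dips below baseline, and is
# present at stress but not rest; dark banding begins with contrast arrival
# in the LV blood pool, lasts fewer than 6 RR intervals, is about one pixel
# wide, dips below baseline, and runs along the phase-encoding direction.

#' Construct a signal-intensity-time curve
#'
#' @param roi_id segment id (integer) or \code{"lv_blood_pool"}.
#' @param times_ms frame trigger times in ms (strictly increasing); with the
#'   typical one-frame-per-RR acquisition, frame index differences are RR
#'   intervals.
#' @param si mean ROI signal intensity per frame (arbitrary units).
#' @param n_baseline_frames number of pre-contrast frames (>= 1).
#' @return an object of class \code{si_curve}.
#' @export
si_curve <- function(roi_id, times_ms, si, n_baseline_frames = 3L) {
  stopifnot(length(times_ms) == length(si), n_baseline_frames >= 1,
            all(diff(times_ms) > 0))
  structure(list(roi_id = roi_id, times_ms = as.numeric(times_ms),
                 si = as.numeric(si),
                 n_baseline_frames = as.integer(n_baseline_frames)),
            class = "si_curve")
}

#' Extract per-segment SI curves from a dynamic perfusion series
#'
#' Contours drawn on one reference frame are propagated to all frames (the
#' series is assumed registered).  Returns one curve per AHA segment of the
#' slice's ring -- or per (segment, layer) when \code{layers = "endo_epi"} --
#' plus one LV blood-pool curve.  Papillary/exclusion polygons are removed
#' from the myocardial ROI.  Segments left empty after exclusions are
#' flagged (\code{empty = TRUE}), not silently dropped.
#'
#' @param frames numeric array \code{[row, col, frame]}.
#' @param times_ms frame trigger times, ms.
#' @param endo,epi reference-frame myocardial contours.
#' @param blood_roi LV blood-pool \code{contour_polygon}.
#' @param model an \code{\link{aha_model}}.
#' @param slice_index slice of the series within the model.
#' @param layers \code{"none"} or \code{"endo_epi"}.
#' @param exclude list of polygons excluded from the myocardium.
#' @param pixel_spacing mm/pixel.
#' @param n_baseline_frames pre-contrast frames carried into every curve.
#' @return list with \code{curves} (list of \code{si_curve}),
#'   \code{blood} (\code{si_curve}), \code{segment_map}, \code{myo_mask},
#'   \code{flagged} (ids of empty segments).
#' @export
extract_si_curves <- function(frames, times_ms, endo, epi, blood_roi, model,
                              slice_index, layers = c("none", "endo_epi"),
                              exclude = list(), pixel_spacing = c(1, 1),
                              n_baseline_frames = 5L) {
  layers <- match.arg(layers)
  dm <- dim(frames)[1:2]
  myo <- myocardium_mask(endo, epi, dm, pixel_spacing)
  for (p in exclude) myo <- myo & !rasterize_contour(p, dm, pixel_spacing)
  segmap <- assign_pixels_to_segments(myo, model, slice_index, pixel_spacing)
  blood_mask <- rasterize_contour(blood_roi, dm, pixel_spacing)
  nfr <- dim(frames)[3]
  fm <- matrix(frames, prod(dm), nfr)   # pixels x frames
  roi_mean <- function(mask) {
    idx <- which(mask)
    if (length(idx) == 0) return(NULL)
    colMeans(fm[idx, , drop = FALSE])
  }
  lay <- if (layers == "endo_epi")
    split_endo_epi_layers(endo, epi, dm, pixel_spacing) else NULL
  segs <- ring_segments(model, model$ring_of_slice[[as.character(slice_index)]])
  curves <- list(); flagged <- integer(0)
  for (s in segs) {
    smask <- !is.na(segmap) & segmap == s
    rois <- if (is.null(lay)) list(mask = smask)
    else list(endo = smask & lay$endo_layer, epi = smask & lay$epi_layer)
    for (ln in names(rois)) {
      m <- roi_mean(rois[[ln]])
      id <- if (is.null(lay)) s else paste0(s, "_", ln)
      if (is.null(m)) { flagged <- c(flagged, s); next }
      curves[[as.character(id)]] <- si_curve(s, times_ms, m, n_baseline_frames)
    }
  }
  blood <- si_curve("lv_blood_pool", times_ms, roi_mean(blood_mask),
                    n_baseline_frames)
  list(curves = curves, blood = blood, segment_map = segmap, myo_mask = myo,
       flagged = unique(flagged))
}

#' Semi-quantitative features of one SI curve
#'
#' Baseline is the mean of the first \code{n_baseline_frames}; contrast
#' arrival is the first later frame exceeding baseline + 2 SD(baseline);
#' the maximal upslope is the largest least-squares slope over any
#' \code{upslope_window} consecutive frames between arrival and peak
#' (exhaustive search); time to peak is peak frame minus arrival frame; the
#' upslope integral is the trapezoidal area under SI - baseline from arrival
#' to peak.
#'
#' @param curve an \code{\link{si_curve}}.
#' @param blood optional LV blood-pool \code{si_curve} for upslope
#'   normalization.
#' @param upslope_window sliding-window length in frames (default 5, min 3;
#'   shrunk when arrival..peak holds fewer frames).
#' @param arrival_min_run consecutive supra-threshold frames required to call
#'   contrast arrival (default 2; 1 reproduces the bare first-crossing rule).
#' @return list of class \code{perfusion_features}: \code{baseline_si},
#'   \code{baseline_sd}, \code{arrival_frame}, \code{peak_frame},
#'   \code{max_upslope} (SI/frame), \code{max_upslope_per_s},
#'   \code{normalized_upslope}, \code{time_to_peak_frames},
#'   \code{time_to_peak_s}, \code{upslope_integral}.  Frames are 1-based.
#' @export
curve_features <- function(curve, blood = NULL, upslope_window = 5L,
                           arrival_min_run = 2L) {
  stopifnot(inherits(curve, "si_curve"), upslope_window >= 3)
  si <- curve$si; nb <- curve$n_baseline_frames; n <- length(si)
  base <- mean(si[seq_len(nb)])
  bsd <- stats::sd(si[seq_len(nb)])
  if (nb == 1L) bsd <- 0
  above <- si > base + 2 * bsd & seq_len(n) > nb
  arr <- NA_integer_
  for (i in which(above)) {
    run <- seq.int(i, min(n, i + arrival_min_run - 1L))
    if (all(above[run])) { arr <- i; break }
  }
  if (is.na(arr))
    stop("no-contrast-arrival error: curve never exceeds baseline + 2 SD")
  peak <- arr - 1L + which.max(si[arr:n])
  w <- min(upslope_window, max(2L, peak - arr + 1L))
  slope_frames <- slope_s <- -Inf
  for (st in arr:max(arr, peak - w + 1L)) {
    en <- min(st + w - 1L, n)
    if (en - st + 1L < 2L) next
    ii <- st:en
    sl <- stats::cov(ii, si[ii]) / stats::var(ii)
    if (sl > slope_frames) {
      slope_frames <- sl
      slope_s <- stats::cov(curve$times_ms[ii] / 1000, si[ii]) /
        stats::var(curve$times_ms[ii] / 1000)
    }
  }
  norm_up <- NA_real_
  if (!is.null(blood)) {
    bf <- curve_features(blood, NULL, upslope_window)
    norm_up <- slope_frames / bf$max_upslope
  }
  integ <- if (peak > arr)
    pracma::trapz(arr:peak, si[arr:peak] - base) else 0
  structure(list(baseline_si = base, baseline_sd = bsd,
                 arrival_frame = arr, peak_frame = peak,
                 max_upslope = slope_frames, max_upslope_per_s = slope_s,
                 normalized_upslope = norm_up,
                 time_to_peak_frames = peak - arr,
                 time_to_peak_s = (curve$times_ms[peak] - curve$times_ms[arr]) / 1000,
                 upslope_integral = integ),
            class = "perfusion_features")
}

#' Myocardial perfusion reserve index
#'
#' Ratio of the stress to rest blood-pool-normalized maximal upslopes.
#'
#' @param stress,rest \code{perfusion_features} with
#'   \code{normalized_upslope} set.
#' @return MPRI (dimensionless).
#' @export
mpri <- function(stress, rest) {
  if (is.na(rest$normalized_upslope) || rest$normalized_upslope == 0)
    stop("undefined-ratio error: rest normalized upslope is zero")
  stress$normalized_upslope / rest$normalized_upslope
}

# --- rule-based defect / artifact classification -------------------------

#' Classify per-segment perfusion findings
#'
#' Applies the rule-based decision table to per-segment hypoenhancement
#' evidence computed from stress and rest endocardial-layer curves, plus the
#' per-segment geometry (deficit width in pixels, alignment with the
#' phase-encode direction) and the LGE status.  Hypoenhancement is detected
#' where a segment's layer SI falls below \code{hypo_factor} times the ring
#' median at the same frame.
#'
#' Labels: \code{inducible_defect} -- begins at/after myocardial contrast
#' arrival, persists more than \code{defect_persist_rr} RR beyond peak
#' enhancement, wider than one pixel, never below baseline, present at
#' stress only.  \code{dark_banding_artifact} -- begins at LV blood-pool
#' arrival before myocardial arrival, total duration under
#' \code{artifact_max_rr} RR, about one pixel wide, dips below baseline,
#' aligned with the phase-encode direction (stress-only dark banding alone is
#' never called a defect).  Matched stress/rest hypoenhancement with LGE in
#' the same segment is labelled \code{normal} with a scar-match note;
#' anything else hypoenhanced is \code{indeterminate}.
#'
#' @param stress_curves,rest_curves named lists (by segment id) of
#'   endocardial-layer \code{\link{si_curve}}s.
#' @param stress_blood,rest_blood LV blood-pool curves.
#' @param width_px named numeric: deficit width in pixels per segment at
#'   stress (0 when no subthreshold pixels).
#' @param aligned_pe named logical: segment deficit aligned with the
#'   phase-encode direction.
#' @param lge_present named logical: LGE in the segment.
#' @param hypo_factor ring-median fraction defining hypoenhancement
#'   (default 0.75).
#' @param defect_persist_rr defect persistence bound, RR (strict >, default 4).
#' @param artifact_max_rr artifact duration bound, RR (strict <, default 6).
#' @param onset_tol_frames tolerance for "begins at blood-pool arrival".
#' @return data.frame with one row per segment: \code{segment}, \code{label},
#'   the boolean criteria, and \code{note}.
#' @export
classify_segment_finding <- function(stress_curves, rest_curves,
                                     stress_blood, rest_blood,
                                     width_px, aligned_pe, lge_present,
                                     hypo_factor = 0.75,
                                     defect_persist_rr = 4,
                                     artifact_max_rr = 6,
                                     onset_tol_frames = 1L) {
  segs <- names(stress_curves)
  ev_s <- hypo_evidence(stress_curves, stress_blood, hypo_factor)
  ev_r <- hypo_evidence(rest_curves, rest_blood, hypo_factor)
  out <- data.frame(segment = as.integer(segs), label = NA_character_,
                    hypo_stress = unname(unlist(ev_s$hypo[segs])),
                    hypo_rest = unname(unlist(ev_r$hypo[segs])),
                    onset_at_blood_arrival = FALSE,
                    before_myo_arrival = FALSE,
                    persists_beyond_peak_gt = FALSE, short_lived = FALSE,
                    width_gt_1px = unname(width_px[segs] > 1),
                    width_approx_1px = unname(width_px[segs] >= 1 & width_px[segs] <= 1),
                    below_baseline = FALSE,
                    aligned_phase_encode = unname(aligned_pe[segs]),
                    lge_present = unname(lge_present[segs]),
                    note = "", stringsAsFactors = FALSE)
  for (i in seq_along(segs)) {
    s <- segs[i]
    if (!ev_s$hypo[[s]]) { out$label[i] <- "normal"; next }
    onset <- ev_s$onset[[s]]
    out$onset_at_blood_arrival[i] <-
      abs(onset - ev_s$blood_arrival) <= onset_tol_frames
    out$before_myo_arrival[i] <- onset < ev_s$myo_arrival
    out$persists_beyond_peak_gt[i] <-
      ev_s$beyond_peak[[s]] > defect_persist_rr
    out$short_lived[i] <- ev_s$duration[[s]] < artifact_max_rr
    out$below_baseline[i] <- ev_s$below_baseline[[s]]
    artifact_like <- out$onset_at_blood_arrival[i] &&
      out$before_myo_arrival[i] && out$short_lived[i] &&
      out$width_approx_1px[i] && out$below_baseline[i] &&
      out$aligned_phase_encode[i]
    defect_like <- !out$before_myo_arrival[i] &&
      out$persists_beyond_peak_gt[i] && out$width_gt_1px[i] &&
      !out$below_baseline[i]
    if (artifact_like) {
      out$label[i] <- "dark_banding_artifact"
      out$note[i] <- "dark banding at stress alone is not diagnostic of a defect"
    } else if (defect_like && !ev_r$hypo[[s]]) {
      out$label[i] <- "inducible_defect"
    } else if (defect_like && ev_r$hypo[[s]] && lge_present[[s]]) {
      out$label[i] <- "normal"
      out$note[i] <- "matched stress/rest hypoenhancement with LGE: scar, identify from LGE images"
    } else {
      out$label[i] <- "indeterminate"
    }
  }
  out
}

# per-segment hypoenhancement evidence from endocardial-layer curves
hypo_evidence <- function(curves, blood, hypo_factor) {
  segs <- names(curves)
  simat <- do.call(rbind, lapply(curves, `[[`, "si"))
  med <- apply(simat, 2, stats::median)
  nb <- curves[[1]]$n_baseline_frames
  bf <- curve_features(blood)
  myo_global <- si_curve("myo", curves[[1]]$times_ms, colMeans(simat), nb)
  mf <- tryCatch(curve_features(myo_global), error = function(e) NULL)
  myo_arrival <- if (is.null(mf)) Inf else mf$arrival_frame
  myo_peak <- if (is.null(mf)) Inf else mf$peak_frame
  hypo <- onset <- dur <- beyond <- below <- stats::setNames(vector("list", length(segs)), segs)
  for (s in segs) {
    si <- curves[[s]]$si
    base <- mean(si[seq_len(nb)])
    bsd <- if (nb > 1) stats::sd(si[seq_len(nb)]) else 0
    h <- si < hypo_factor * med
    hypo[[s]] <- any(h)
    onset[[s]] <- if (any(h)) which(h)[1] else NA_integer_
    dur[[s]] <- sum(h)
    beyond[[s]] <- sum(h & seq_along(si) > myo_peak)
    below[[s]] <- min(si) < base - max(2 * bsd, 1e-6)
  }
  list(hypo = hypo, onset = onset, duration = dur, beyond_peak = beyond,
       below_baseline = below, blood_arrival = bf$arrival_frame,
       myo_arrival = myo_arrival, myo_peak = myo_peak)
}

#' Deficit width in pixels within each segment
#'
#' At the given frame, pixels of the myocardial mask falling below
#' \code{hypo_factor} times the median myocardial pixel SI are marked; the
#' per-segment width is the longest contiguous radial run of marked pixels
#' through any marked pixel (stepping one pixel at a time toward and away
#' from the myocardial centroid) -- i.e. the transmural thickness of the
#' deficit in pixels.
#'
#' @param frame_img numeric matrix, one dynamic frame.
#' @param segment_map integer matrix from
#'   \code{\link{assign_pixels_to_segments}}.
#' @param myo_mask logical myocardial mask.
#' @param pixel_spacing mm/pixel.
#' @param hypo_factor threshold fraction of the myocardial median.
#' @return named numeric vector of widths (pixels) per segment id.
#' @export
deficit_width_px <- function(frame_img, segment_map, myo_mask,
                             pixel_spacing = c(1, 1), hypo_factor = 0.75) {
  thr <- hypo_factor * stats::median(frame_img[myo_mask])
  below_mat <- myo_mask & frame_img < thr
  xy_all <- mask_coords(myo_mask, pixel_spacing)
  ctr <- colMeans(xy_all)
  segs <- sort(unique(segment_map[!is.na(segment_map)]))
  out <- stats::setNames(numeric(length(segs)), segs)
  if (!any(below_mat)) return(out)
  px <- mean(pixel_spacing)
  is_below <- function(x, y) {
    cc <- round(x / pixel_spacing[1]) + 1L
    rr <- round(y / pixel_spacing[2]) + 1L
    cc >= 1L && cc <= ncol(below_mat) && rr >= 1L && rr <= nrow(below_mat) &&
      below_mat[rr, cc]
  }
  ij <- which(below_mat, arr.ind = TRUE)
  for (k in seq_len(nrow(ij))) {
    s <- segment_map[ij[k, 1], ij[k, 2]]
    if (is.na(s)) next
    x0 <- (ij[k, 2] - 1) * pixel_spacing[1]
    y0 <- (ij[k, 1] - 1) * pixel_spacing[2]
    u <- c(x0 - ctr[1], y0 - ctr[2])
    u <- u / max(sqrt(sum(u^2)), .Machine$double.eps)
    run <- 1
    for (d in c(-1, 1)) {
      step <- 1
      while (is_below(x0 + d * step * px * u[1], y0 + d * step * px * u[2])) {
        run <- run + 1
        step <- step + 1
      }
    }
    key <- as.character(s)
    out[key] <- max(out[key], run)
  }
  out
}

#' Full stress/rest perfusion classification of one slice
#'
#' Convenience pipeline: extracts endocardial-layer segment curves from both
#' series, measures the deficit width and phase-encode alignment at the
#' frame of maximal deficit, and applies
#' \code{\link{classify_segment_finding}}.
#'
#' @param stress_frames,rest_frames arrays \code{[row, col, frame]}.
#' @param times_ms frame times.
#' @param endo,epi,blood_roi reference contours.
#' @param model an \code{\link{aha_model}}; \code{slice_index} the slice.
#' @param phase_encode_deg phase-encode axis, degrees.
#' @param lge_present named logical per segment (default all FALSE).
#' @param pixel_spacing mm/pixel.
#' @param ... passed to \code{\link{classify_segment_finding}}.
#' @return the classification data.frame (see
#'   \code{\link{classify_segment_finding}}).
#' @export
classify_perfusion_study <- function(stress_frames, rest_frames, times_ms,
                                     endo, epi, blood_roi, model, slice_index,
                                     phase_encode_deg = 90,
                                     lge_present = NULL,
                                     pixel_spacing = c(1, 1), ...) {
  ex_s <- extract_si_curves(stress_frames, times_ms, endo, epi, blood_roi,
                            model, slice_index, layers = "endo_epi",
                            pixel_spacing = pixel_spacing)
  ex_r <- extract_si_curves(rest_frames, times_ms, endo, epi, blood_roi,
                            model, slice_index, layers = "endo_epi",
                            pixel_spacing = pixel_spacing)
  pick_layer <- function(ex, layer) {
    nm <- grep(paste0("_", layer, "$"), names(ex$curves), value = TRUE)
    stats::setNames(ex$curves[nm], sub(paste0("_", layer, "$"), "", nm))
  }
  sc <- pick_layer(ex_s, "endo"); rc <- pick_layer(ex_r, "endo")
  segs <- names(sc)
  if (is.null(lge_present))
    lge_present <- stats::setNames(rep(FALSE, length(segs)), segs)
  # per segment, width measured at that segment's frame of maximal deficit
  simat <- do.call(rbind, lapply(sc, `[[`, "si"))
  med <- apply(simat, 2, stats::median)
  deficit <- sweep(-simat, 2, med, "+")   # median - si
  widths <- stats::setNames(numeric(length(segs)), segs)
  for (i in seq_along(segs)) {
    if (max(deficit[i, ]) <= 0) next
    fr <- which.max(deficit[i, ])
    w <- deficit_width_px(stress_frames[, , fr], ex_s$segment_map,
                          ex_s$myo_mask, pixel_spacing)
    widths[i] <- w[[segs[i]]]
  }
  aligned <- stats::setNames(segment_pe_alignment(ex_s$segment_map,
                                                  phase_encode_deg,
                                                  pixel_spacing)[segs], segs)
  classify_segment_finding(sc, rc, ex_s$blood, ex_r$blood, widths, aligned,
                           lge_present, ...)
}

# TRUE for segments whose angular center lies within 45 degrees of the
# phase-encode axis (mod 180)
segment_pe_alignment <- function(segment_map, phase_encode_deg,
                                 pixel_spacing = c(1, 1)) {
  myo <- !is.na(segment_map)
  xy <- mask_coords(myo, pixel_spacing)
  ctr <- colMeans(xy)
  th <- atan2(xy[, 2] - ctr[2], xy[, 1] - ctr[1])
  seg <- segment_map[which(myo)]
  segs <- sort(unique(seg))
  out <- stats::setNames(logical(length(segs)), segs)
  for (s in segs) {
    a <- th[seg == s]
    ca <- (atan2(mean(sin(a)), mean(cos(a))) * 180 / pi) %% 360
    d <- abs(((ca - phase_encode_deg) %% 180))
    out[as.character(s)] <- min(d, 180 - d) <= 45
  }
  out
}
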