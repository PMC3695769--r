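# Phase-contrast flow quantification.
#
# Velocities are in cm/s within a window of width 2xVENC; velocities beyond
# the VENC alias by wrapping.  Per-frame flux integrates ROI pixel velocity
# over the lumen area; antegrade / retrograde volumes are trapezoidal time
# integrals of the positive / negative flux over one cardiac cycle.  The
# worked aliasing example: a true 175 cm/s peak recorded as -125 cm/s at
# VENC 150 is recovered by moving the window to (-100, +200).

#' Construct a velocity-encoded frame series
#'
#' @param velocity list of numeric matrices (cm/s), one per frame.
#' @param magnitude optional list of magnitude matrices.
#' @param pixel_area_mm2 in-plane pixel area, mm^2.
#' @param trigger_times_ms frame trigger times, ms (increasing).
#' @param rr_ms RR interval, ms.
#' @param venc velocity-encoding limit, cm/s.
#' @param te_ms echo time, ms.
#' @param rois vessel-lumen \code{contour_polygon} -- one, or a list per
#'   frame.
#' @param velocity_window c(lower, upper) cm/s; defaults to (-venc, venc);
#'   width must equal 2 venc.
#' @param pixel_spacing mm/pixel for ROI rasterization.
#' @return an object of class \code{velocity_series}.
#' @export
velocity_series <- function(velocity, magnitude = NULL, pixel_area_mm2,
                            trigger_times_ms, rr_ms, venc, te_ms = NA_real_,
                            rois = NULL, velocity_window = c(-venc, venc),
                            pixel_spacing = c(1, 1)) {
  stopifnot(length(velocity) == length(trigger_times_ms),
            all(diff(trigger_times_ms) > 0), pixel_area_mm2 > 0, venc > 0)
  if (abs(diff(velocity_window) - 2 * venc) > 1e-9)
    stop("invalid-window error: window width must equal 2 x VENC")
  if (!is.null(rois) && inherits(rois, "contour_polygon"))
    rois <- rep(list(rois), length(velocity))
  structure(list(velocity = velocity, magnitude = magnitude,
                 pixel_area_mm2 = pixel_area_mm2,
                 trigger_times_ms = trigger_times_ms, rr_ms = rr_ms,
                 venc = venc, te_ms = te_ms, rois = rois,
                 velocity_window = velocity_window,
                 pixel_spacing = rep(pixel_spacing, length.out = 2)),
            class = "velocity_series")
}

#' Shift the velocity dynamic range to recover aliased velocities
#'
#' Each velocity v is re-expressed as v + 2 VENC k with the unique integer k
#' placing it inside [lower, upper); values already inside are unchanged.
#'
#' @param series a \code{\link{velocity_series}}.
#' @param new_window c(lower, upper) cm/s, width exactly 2 VENC.
#' @return the series with re-windowed velocities.
#' @export
shift_velocity_window <- function(series, new_window) {
  if (abs(diff(new_window) - 2 * series$venc) > 1e-9)
    stop("invalid-window error: window width must equal 2 x VENC")
  lo <- new_window[1]; w <- 2 * series$venc
  series$velocity <- lapply(series$velocity, function(v) lo + (v - lo) %% w)
  series$velocity_window <- new_window
  series
}

#' Background phase-offset correction
#'
#' \code{stationary_fit}: a first-order 2D polynomial (a + b x + c y) is
#' fitted per frame to the velocities of the stationary-tissue mask and
#' subtracted from the whole frame.  \code{phantom}: the per-pixel temporal
#' mean of a geometrically matched static-phantom series is subtracted.
#'
#' @param series a \code{\link{velocity_series}}.
#' @param method \code{"stationary_fit"} or \code{"phantom"}.
#' @param stationary_mask logical matrix (>= \code{min_pixels} pixels,
#'   excluding the vessel ROI).
#' @param phantom_series a \code{velocity_series} from a static phantom.
#' @param min_pixels minimum stationary mask size (default 100).
#' @return the corrected series.
#' @export
background_offset_correction <- function(series,
                                         method = c("stationary_fit", "phantom"),
                                         stationary_mask = NULL,
                                         phantom_series = NULL,
                                         min_pixels = 100) {
  method <- match.arg(method)
  if (method == "stationary_fit") {
    stopifnot(!is.null(stationary_mask))
    if (sum(stationary_mask) < min_pixels)
      stop("unreliable-fit error: stationary mask under ", min_pixels, " pixels")
    nr <- nrow(stationary_mask); nc <- ncol(stationary_mask)
    X <- cbind(1, rep(seq_len(nc), each = nr), rep(seq_len(nr), times = nc))
    sel <- which(stationary_mask)
    series$velocity <- lapply(series$velocity, function(v) {
      beta <- stats::lm.fit(X[sel, , drop = FALSE], v[sel])$coefficients
      v - matrix(X %*% beta, nr, nc)
    })
  } else {
    stopifnot(!is.null(phantom_series))
    off <- Reduce(`+`, phantom_series$velocity) / length(phantom_series$velocity)
    series$velocity <- lapply(series$velocity, function(v) v - off)
  }
  series
}

#' Per-frame flux curve from a velocity series
#'
#' Frame flux = sum over lumen-ROI pixels of velocity x pixel area, in ml/s
#' (positive = antegrade under the caller's declared sign convention).
#'
#' @param series a \code{\link{velocity_series}} with ROI(s) set.
#' @return object of class \code{flow_curve}: \code{flux_ml_per_s},
#'   \code{trigger_times_ms}, \code{rr_ms}.
#' @export
flow_curve <- function(series) {
  if (is.null(series$rois)) stop("no vessel ROI in series")
  flux <- vapply(seq_along(series$velocity), function(i) {
    m <- rasterize_contour(series$rois[[i]], dim(series$velocity[[i]]),
                           series$pixel_spacing)
    if (!any(m)) stop("empty ROI on frame ", i)
    # cm/s x mm^2 = 10 mm^3/s = 0.01 ml/s
    sum(series$velocity[[i]][m]) * series$pixel_area_mm2 * 0.01
  }, numeric(1))
  structure(list(flux_ml_per_s = flux,
                 trigger_times_ms = series$trigger_times_ms,
                 rr_ms = series$rr_ms),
            class = "flow_curve")
}

#' Flow volumes and derived clinical parameters
#'
#' Antegrade and retrograde volumes are trapezoidal time integrals of the
#' positive and negative flux over one cardiac cycle (the last interval
#' closes the RR cycle back to the first frame).  Derived values: net =
#' antegrade - retrograde; regurgitant fraction = 100 retrograde/antegrade;
#' CO = net x HR / 1000; CI = CO / BSA.  Optional extras: lung flow split
#' from RPA and LPA net volumes; atrioventricular regurgitant volume by
#' method A (direct diastolic AV inflow minus systolic semilunar forward
#' volume) and method B (cine stroke volume minus semilunar forward volume).
#'
#' @param curve a \code{\link{flow_curve}}.
#' @param meta a \code{\link{study_meta}} (heart rate, BSA).
#' @param rpa_net_ml,lpa_net_ml optional pulmonary branch net volumes.
#' @param av_diastolic_inflow_ml,semilunar_forward_ml,cine_sv_ml optional
#'   inputs for the AV-regurgitation methods.
#' @return object of class \code{flow_result}.
#' @export
flow_volumes_and_derived <- function(curve, meta = study_meta(),
                                     rpa_net_ml = NULL, lpa_net_ml = NULL,
                                     av_diastolic_inflow_ml = NULL,
                                     semilunar_forward_ml = NULL,
                                     cine_sv_ml = NULL) {
  q <- curve$flux_ml_per_s
  t <- curve$trigger_times_ms
  # close the cycle: repeat frame 1 at t[1] + RR
  qq <- c(q, q[1]); tt <- c(t, t[1] + curve$rr_ms) / 1000
  dt <- diff(tt)
  tr <- function(v) sum((utils::head(v, -1) + utils::tail(v, -1)) / 2 * dt)
  ante <- tr(pmax(qq, 0))
  retro <- tr(pmax(-qq, 0))
  net <- ante - retro
  rf <- if (ante > 0) 100 * retro / ante else NA_real_
  hr <- meta$heart_rate_bpm
  co <- if (is.na(hr)) NA_real_ else net * hr / 1000
  ci <- if (is.na(co) || is.na(meta$bsa_m2)) NA_real_ else co / meta$bsa_m2
  res <- list(antegrade_ml = ante, retrograde_ml = retro, net_ml = net,
              regurgitant_fraction_pct = rf, cardiac_output_l_min = co,
              cardiac_index_l_min_m2 = ci)
  if (!is.null(rpa_net_ml) && !is.null(lpa_net_ml)) {
    res$right_lung_pct <- 100 * rpa_net_ml / (rpa_net_ml + lpa_net_ml)
    res$left_lung_pct <- 100 * lpa_net_ml / (rpa_net_ml + lpa_net_ml)
  }
  if (!is.null(av_diastolic_inflow_ml) && !is.null(semilunar_forward_ml))
    res$av_regurgitant_ml_method_a <-
      av_diastolic_inflow_ml - semilunar_forward_ml
  if (!is.null(cine_sv_ml) && !is.null(semilunar_forward_ml))
    res$av_regurgitant_ml_method_b <- cine_sv_ml - semilunar_forward_ml
  structure(res, class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("flow: antegrade %.1f ml, retrograde %.1f ml, net %.1f ml",
              x$antegrade_ml, x$retrograde_ml, x$net_ml))
  if (!is.na(x$regurgitant_fraction_pct))
    cat(sprintf(", RF %.1f%%", x$regurgitant_fraction_pct))
  cat("\n")
  if (!is.na(x$cardiac_output_l_min))
    cat(sprintf("  CO %.2f L/min", x$cardiac_output_l_min))
  if (!is.na(x$cardiac_index_l_min_m2))
    cat(sprintf("  CI %.2f L/min/m2", x$cardiac_index_l_min_m2))
  cat("\n")
  invisible(x)
}

#' Peak velocity within the vessel ROI
#'
#' \code{single_pixel}: the largest absolute pixel velocity over all ROI
#' pixels and frames.  \code{neighborhood_mean}: the largest absolute mean of
#' the n x n block centered at each ROI pixel (block clipped to the ROI).
#' The mode is recorded because interpretation depends on the technique.
#'
#' @param series a \code{\link{velocity_series}} with ROI(s).
#' @param mode \code{"single_pixel"} or \code{"neighborhood_mean"}.
#' @param neighborhood odd block size for the averaged mode (default 3).
#' @return list(peak_velocity_cm_s, frame, peak_mode).
#' @export
peak_velocity <- function(series, mode = c("single_pixel", "neighborhood_mean"),
                          neighborhood = 3L) {
  mode <- match.arg(mode)
  stopifnot(neighborhood %% 2 == 1)
  best <- -Inf; best_frame <- NA_integer_; best_signed <- NA_real_
  h <- (neighborhood - 1L) %/% 2L
  for (i in seq_along(series$velocity)) {
    v <- series$velocity[[i]]
    m <- rasterize_contour(series$rois[[i]], dim(v), series$pixel_spacing)
    if (!any(m)) next
    if (mode == "single_pixel") {
      idx <- which(m)
      j <- idx[which.max(abs(v[idx]))]
      val <- v[j]
    } else {
      ij <- which(m, arr.ind = TRUE)
      val <- 0; vmax <- -Inf
      for (k in seq_len(nrow(ij))) {
        r0 <- max(1L, ij[k, 1] - h); r1 <- min(nrow(v), ij[k, 1] + h)
        c0 <- max(1L, ij[k, 2] - h); c1 <- min(ncol(v), ij[k, 2] + h)
        blk_m <- m[r0:r1, c0:c1]
        mu <- mean(v[r0:r1, c0:c1][blk_m])
        if (abs(mu) > vmax) { vmax <- abs(mu); val <- mu }
      }
    }
    if (abs(val) > best) { best <- abs(val); best_frame <- i; best_signed <- val }
  }
  list(peak_velocity_cm_s = best_signed, frame = best_frame, peak_mode = mode)
}

#' Quality-control checks for a phase-contrast series
#'
#' Flags raised: echo time above 3.5 ms (accuracy bound for high-velocity
#' jets); suspected aliasing (at least \code{min_alias_pixels} ROI pixels
#' within \code{alias_edge_frac} of the velocity-window edge -- edge pixels
#' near the vessel wall are usually, but not always, outside the lumen, so
#' the count is taken over the ROI interior); poor velocity contrast (peak
#' below 40\% of the VENC).
#'
#' @param series a \code{\link{velocity_series}}.
#' @param alias_edge_frac window-edge proximity fraction (default 0.02).
#' @param min_alias_pixels pixel count triggering the aliasing flag
#'   (default 3).
#' @return list(te_warning, aliasing_warning, poor_contrast_warning,
#'   messages).
#' @export
qc_checks <- function(series, alias_edge_frac = 0.02, min_alias_pixels = 3L) {
  msgs <- character(0)
  te_warn <- !is.na(series$te_ms) && series$te_ms > 3.5
  if (te_warn)
    msgs <- c(msgs, sprintf("TE %.2f ms exceeds the 3.5 ms accuracy bound",
                            series$te_ms))
  lo <- series$velocity_window[1]; up <- series$velocity_window[2]
  tol <- alias_edge_frac * 2 * series$venc
  n_edge <- 0L; peak <- 0
  for (i in seq_along(series$velocity)) {
    v <- series$velocity[[i]]
    if (!is.null(series$rois)) {
      m <- rasterize_contour(series$rois[[i]], dim(v), series$pixel_spacing)
      v <- v[m]
    }
    n_edge <- n_edge + sum(v <= lo + tol | v >= up - tol)
    peak <- max(peak, max(abs(v)))
  }
  alias_warn <- n_edge >= min_alias_pixels
  if (alias_warn)
    msgs <- c(msgs, sprintf("%d ROI pixels within %.0f%% of the velocity window edge: aliasing suspected",
                            n_edge, 100 * alias_edge_frac))
  poor <- peak < 0.4 * series$venc
  if (poor)
    msgs <- c(msgs, sprintf("peak %.1f cm/s under 40%% of VENC %.0f cm/s: poor velocity contrast",
                            peak, series$venc))
  list(te_warning = te_warn, aliasing_warning = alias_warn,
       poor_contrast_warning = poor, messages = msgs)
}
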