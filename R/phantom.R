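# Synthetic phantom generator.
#
# Every analysis module's inputs can be generated here with analytic ground
# truth (the truth manifest is computed from the generating parameters,
# never by the analysis code under test).  All randomness is seeded;
# regeneration with the same scenario and seed is bit-identical.

circle_polygon <- function(cx, cy, r, role = "generic", n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour_polygon(cx + r * cos(th), cy + r * sin(th), role)
}

ellipse_polygon <- function(cx, cy, a, b, role = "generic", n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour_polygon(cx + a * cos(th), cy + b * sin(th), role)
}

#' Ellipsoidal two-phase ventricle phantom
#'
#' Builds a short-axis contour stack of an ellipsoidal ventricle (long axis
#' along the slice direction) whose in-plane semi-axes cycle between the
#' end-diastolic and end-systolic values, with a uniform-thickness
#' epicardial shell.  Truth volumes come from the closed-form ellipsoid
#' volume 4/3 pi a b c; truth mass from the shell volume times 1.05 g/ml.
#'
#' @param ed_semi_axes c(a, b, c) mm at end-diastole (c = long semi-axis).
#' @param es_semi_axes c(a, b, c) mm at end-systole (componentwise <= ED).
#' @param wall_thickness_mm epicardial shell thickness (> 0).
#' @param slice_thickness_mm,gap_mm slice geometry; the integration step is
#'   their sum.
#' @param n_phases cardiac phases; ED at phase 0, ES at phase
#'   \code{n_phases \%/\% 2} (cosine interpolation between them).
#' @param papillary_area_mm2 total papillary cross-section per slice
#'   (two disks; 0 disables).
#' @param heart_rate_bpm,bsa_m2 study metadata.
#' @param center_mm in-plane ventricle center.
#' @param n_vertices polygon vertices per contour.
#' @return list(stack, truth); truth holds \code{edv_ml}, \code{esv_ml},
#'   \code{sv_ml}, \code{ef_pct}, \code{mass_g}, \code{myo_volume_ml},
#'   \code{ed_phase}, \code{es_phase}.
#' @export
ellipsoid_ventricle_stack <- function(ed_semi_axes = c(25, 25, 45),
                                      es_semi_axes = c(17, 17, 45),
                                      wall_thickness_mm = 8,
                                      slice_thickness_mm = 8, gap_mm = 2,
                                      n_phases = 12L,
                                      papillary_area_mm2 = 0,
                                      heart_rate_bpm = 70, bsa_m2 = 1.9,
                                      center_mm = c(40, 40),
                                      n_vertices = 144L) {
  stopifnot(wall_thickness_mm > 0, all(es_semi_axes <= ed_semi_axes))
  step <- slice_thickness_mm + gap_mm
  c_ed <- ed_semi_axes[3]
  n_slices <- max(3L, floor(2 * c_ed / step))
  z <- -c_ed + (seq_len(n_slices) - 0.5) * step   # slice centers, base at -c
  slices <- lapply(seq_len(n_slices), function(k)
    slice_geometry(k - 1L, z[k], slice_thickness_mm, gap_mm))
  meta <- study_meta(heart_rate_bpm, bsa_m2, "short_axis")
  stack <- contour_stack(slices, n_phases, meta)
  es_phase <- n_phases %/% 2L
  w_of <- function(ph) (1 - cos(2 * pi * ph / n_phases)) / 2
  for (ph in seq_len(n_phases) - 1L) {
    ax <- ed_semi_axes + (es_semi_axes - ed_semi_axes) * w_of(ph)
    for (k in seq_len(n_slices)) {
      u2 <- 1 - z[k]^2 / ax[3]^2
      if (u2 > 0) {
        a_in <- ax[1] * sqrt(u2); b_in <- ax[2] * sqrt(u2)
        if (a_in > 1 && b_in > 1) {
          stack <- stack_add_contour(stack, k - 1L, ph,
            ellipse_polygon(center_mm[1], center_mm[2], a_in, b_in,
                            "endocardial", n_vertices))
          stack <- stack_add_contour(stack, k - 1L, ph,
            ellipse_polygon(center_mm[1], center_mm[2],
                            a_in + wall_thickness_mm, b_in + wall_thickness_mm,
                            "epicardial", n_vertices))
          if (papillary_area_mm2 > 0) {
            r_pap <- sqrt(papillary_area_mm2 / (2 * pi))
            for (s in c(-1, 1))
              stack <- stack_add_contour(stack, k - 1L, ph,
                circle_polygon(center_mm[1] + s * a_in / 2, center_mm[2],
                               r_pap, "papillary", 64L))
          }
        }
      }
    }
  }
  vol_ml <- function(ax) 4 / 3 * pi * prod(ax) / 1000
  # analytic myocardial shell: slice-wise epi area minus endo area x step,
  # using the same offset-ellipse construction as the contours
  myo_ml <- 0
  ax <- ed_semi_axes
  for (k in seq_len(n_slices)) {
    u2 <- 1 - z[k]^2 / ax[3]^2
    if (u2 > 0) {
      a_in <- ax[1] * sqrt(u2); b_in <- ax[2] * sqrt(u2)
      if (a_in > 1 && b_in > 1)
        myo_ml <- myo_ml + pi * ((a_in + wall_thickness_mm) *
                                   (b_in + wall_thickness_mm) - a_in * b_in) *
          step / 1000
    }
  }
  truth <- list(edv_ml = vol_ml(ed_semi_axes), esv_ml = vol_ml(es_semi_axes),
                sv_ml = vol_ml(ed_semi_axes) - vol_ml(es_semi_axes),
                ef_pct = 100 * (1 - vol_ml(es_semi_axes) / vol_ml(ed_semi_axes)),
                myo_volume_ml = myo_ml,
                mass_g = myo_ml * MYOCARDIAL_DENSITY_G_PER_ML,
                ed_phase = 0L, es_phase = es_phase)
  list(stack = stack, truth = truth)
}

gamma_variate <- function(t, t0, tp, alpha = 3) {
  u <- pmax(t - t0, 0) / tp
  ifelse(u > 0, u^alpha * exp(alpha * (1 - u)), 0)
}

#' First-pass perfusion phantom (stress + rest dynamic series)
#'
#' Pixelwise SI is built from gamma-variate first-pass curves: an LV
#' blood-pool disk, a myocardial annulus whose amplitude scales with the
#' stress/rest flow, an optional stress-only subendocardial defect of stated
#' width and amplitude factor, and an optional one-pixel dark band starting
#' at blood-pool contrast arrival, below baseline, aligned with the
#' phase-encode direction.  Truth labels per segment are recorded.
#'
#' @param seed RNG seed.
#' @param n_frames dynamic frames (one per RR interval).
#' @param grid image size (pixels, 1 mm spacing).
#' @param rest_amp,stress_amp myocardial enhancement amplitudes; their ratio
#'   is the true perfusion reserve.
#' @param blood_amp blood-pool amplitude; \code{baseline} pre-contrast SI.
#' @param defect list(segments, factor, width_px) or NULL: stress-only
#'   subendocardial amplitude reduction.
#' @param artifact list(segments, duration_rr, band_si) or NULL: transient
#'   dark band (1 pixel, from blood-pool arrival).
#' @param noise_sd Gaussian pixel noise SD (0 = noiseless).
#' @param phase_encode_deg phase-encode axis (degrees).
#' @param rr_ms RR interval.
#' @return list(stress_frames, rest_frames, times_ms, endo, epi, blood_roi,
#'   model, slice_index, phase_encode_deg, truth).
#' @export
perfusion_curve_set <- function(seed = 1L, n_frames = 40L, grid = 49L,
                                rest_amp = 50, stress_amp = 100,
                                blood_amp = 300, baseline = 50,
                                defect = list(segments = 8L, factor = 0.5,
                                              width_px = 3),
                                artifact = list(segments = 7L,
                                                duration_rr = 4L,
                                                band_si = 0),
                                noise_sd = 0, phase_encode_deg = 90,
                                rr_ms = 800) {
  set.seed(seed)
  ctr <- (grid - 1) / 2
  r_endo <- 9; r_epi <- 15; r_blood <- 6
  t0_b <- 8; tp_b <- 7; t0_m <- 11; tp_m <- 8
  endo <- circle_polygon(ctr, ctr, r_endo, "endocardial")
  epi <- circle_polygon(ctr, ctr, r_epi, "epicardial")
  blood_roi <- circle_polygon(ctr, ctr, r_blood, "blood_pool_roi")
  # three-slice dummy stack so the model has basal/mid/apical rings; the
  # dynamic series is the mid slice (segments 7-12)
  slices <- lapply(0:2, function(i) slice_geometry(i, i * 10, 8, 2))
  stack <- contour_stack(slices, 1L, study_meta(70, 1.9))
  model <- build_aha_model(stack, rv_insertion_angles = phase_encode_deg,
                           n_segments = 16, slice_indices = 0:2)
  slice_index <- 1L
  xg <- matrix(rep(0:(grid - 1), each = grid), grid, grid)   # x by column
  yg <- matrix(rep(0:(grid - 1), times = grid), grid, grid)  # y by row
  rr <- sqrt((xg - ctr)^2 + (yg - ctr)^2)
  th <- (atan2(yg - ctr, xg - ctr) * 180 / pi - phase_encode_deg) %% 360
  seg_of <- matrix(NA_integer_, grid, grid)
  myo <- rr >= r_endo & rr < r_epi
  seg_of[myo] <- 7L + (floor(th[myo] / 60) %% 6L)
  blood <- rr < r_blood
  times <- seq_len(n_frames)
  gb <- gamma_variate(times, t0_b, tp_b)
  gm <- gamma_variate(times, t0_m, tp_m)
  mk <- function(amp_myo, with_defect, with_artifact) {
    fr <- array(30, dim = c(grid, grid, n_frames))
    amp_px <- matrix(0, grid, grid)
    amp_px[myo] <- amp_myo
    if (with_defect && !is.null(defect)) {
      dsel <- myo & seg_of %in% defect$segments &
        rr < r_endo + defect$width_px
      amp_px[dsel] <- amp_myo * defect$factor
    }
    band <- if (with_artifact && !is.null(artifact))
      myo & seg_of %in% artifact$segments & rr < r_endo + 1
    else matrix(FALSE, grid, grid)
    band_frames <- if (is.null(artifact)) integer(0)
    else seq(t0_b + 1, length.out = artifact$duration_rr)
    for (t in times) {
      img <- matrix(30, grid, grid)
      img[myo] <- baseline + amp_px[myo] * gm[t]
      img[blood] <- baseline + blood_amp * gb[t]
      if (with_artifact && t %in% band_frames) img[band] <- artifact$band_si
      if (noise_sd > 0) img <- img + matrix(stats::rnorm(grid^2, 0, noise_sd),
                                            grid, grid)
      fr[, , t] <- img
    }
    fr
  }
  stress <- mk(stress_amp, TRUE, TRUE)
  rest <- mk(rest_amp, FALSE, FALSE)
  labels <- stats::setNames(rep("normal", 6), as.character(7:12))
  if (!is.null(defect))
    labels[as.character(defect$segments)] <- "inducible_defect"
  if (!is.null(artifact))
    labels[as.character(artifact$segments)] <- "dark_banding_artifact"
  truth <- list(labels = labels, mpri = stress_amp / rest_amp,
                seed = seed, blood_arrival_frame = t0_b + 1,
                myo_arrival_frame = t0_m + 1)
  list(stress_frames = stress, rest_frames = rest, times_ms = times * rr_ms,
       endo = endo, epi = epi, blood_roi = blood_roi, model = model,
       slice_index = slice_index, phase_encode_deg = phase_encode_deg,
       truth = truth)
}

#' Late-gadolinium-enhancement phantom image
#'
#' Gaussian remote myocardium, a bright lesion sector of stated transmural
#' fraction, and an optional enclosed hypoenhanced (no-reflow) core.  Truth
#' lesion and core masks are recorded from the construction.
#'
#' @param seed RNG seed.
#' @param grid image size (pixels, 1 mm spacing).
#' @param r_endo,r_epi myocardial annulus radii (mm).
#' @param remote_mean,remote_sd remote myocardium SI distribution.
#' @param lesion_si lesion SI (constant before noise).
#' @param lesion_angle_deg angular span c(from, to) of the lesion sector.
#' @param transmural_fraction fraction of wall thickness enhanced, from the
#'   endocardium.
#' @param core_radius_px no-reflow core radius (0 disables); the core is
#'   placed at mid-lesion with SI \code{core_si}.
#' @param core_si core SI.
#' @param blood_si,background_si surrounding intensities.
#' @return list(image, myo_mask, lesion_mask, core_mask, endo, epi,
#'   remote_roi, core_roi, truth).
#' @export
lge_phantom_image <- function(seed = 1L, grid = 61L, r_endo = 10, r_epi = 20,
                              remote_mean = 100, remote_sd = 10,
                              lesion_si = 400, lesion_angle_deg = c(10, 110),
                              transmural_fraction = 0.4,
                              core_radius_px = 0, core_si = 30,
                              blood_si = 150, background_si = 20) {
  set.seed(seed)
  stopifnot(transmural_fraction >= 0, transmural_fraction <= 1)
  ctr <- (grid - 1) / 2
  xg <- matrix(rep(0:(grid - 1), each = grid), grid, grid)
  yg <- matrix(rep(0:(grid - 1), times = grid), grid, grid)
  rr <- sqrt((xg - ctr)^2 + (yg - ctr)^2)
  th <- (atan2(yg - ctr, xg - ctr) * 180 / pi) %% 360
  myo <- rr >= r_endo & rr < r_epi
  in_sector <- th >= lesion_angle_deg[1] & th < lesion_angle_deg[2]
  lesion <- myo & in_sector &
    rr < r_endo + transmural_fraction * (r_epi - r_endo)
  core <- matrix(FALSE, grid, grid)
  if (core_radius_px > 0) {
    mid_a <- mean(lesion_angle_deg) * pi / 180
    mid_r <- r_endo + transmural_fraction * (r_epi - r_endo) / 2
    cx <- ctr + mid_r * cos(mid_a); cy <- ctr + mid_r * sin(mid_a)
    core <- lesion & sqrt((xg - cx)^2 + (yg - cy)^2) < core_radius_px
    lesion_wo_core <- lesion & !core
  } else lesion_wo_core <- lesion
  img <- matrix(background_si, grid, grid)
  img[rr < r_endo] <- blood_si
  img[myo] <- remote_mean + stats::rnorm(sum(myo), 0, remote_sd)
  img[lesion_wo_core] <- lesion_si + stats::rnorm(sum(lesion_wo_core), 0, remote_sd)
  img[core] <- core_si
  endo <- circle_polygon(ctr, ctr, r_endo, "endocardial")
  epi <- circle_polygon(ctr, ctr, r_epi, "epicardial")
  remote_ctr_a <- (mean(lesion_angle_deg) + 180) %% 360 * pi / 180
  remote_roi <- circle_polygon(ctr + (r_endo + r_epi) / 2 * cos(remote_ctr_a),
                               ctr + (r_endo + r_epi) / 2 * sin(remote_ctr_a),
                               (r_epi - r_endo) / 2 - 0.5, "remote_roi")
  # scar-core ROI for FWHM placed off the no-reflow core (which sits at the
  # sector mid-angle), still well inside the enhanced region
  roi_a <- (lesion_angle_deg[1] + 0.15 * diff(lesion_angle_deg)) * pi / 180
  core_roi <- circle_polygon(ctr + (r_endo + 1.5) * cos(roi_a),
                             ctr + (r_endo + 1.5) * sin(roi_a), 1.6,
                             "scar_core_roi")
  list(image = img, myo_mask = myo, lesion_mask = lesion & !core,
       core_mask = core, endo = endo, epi = epi, remote_roi = remote_roi,
       core_roi = core_roi,
       truth = list(transmural_fraction = transmural_fraction,
                    transmurality_category =
                      transmurality_category(100 * transmural_fraction),
                    lesion_px = sum(lesion & !core), core_px = sum(core),
                    seed = seed))
}

#' Multi-echo T2* decay phantom
#'
#' Per-pixel SI follows sqrt((S0 exp(-TE/T2*))^2 + floor^2) with optional
#' Rician noise; the returned decay curve is the ROI mean per echo, as
#' measured from a full-thickness septal ROI.
#'
#' @param seed RNG seed.
#' @param s0 equilibrium signal.
#' @param t2star_ms true T2*.
#' @param te_ms echo times (default 8 echoes, 2..16 ms).
#' @param noise_floor background signal floor (absolute SI units).
#' @param rician_sd per-channel Rician noise SD (0 = noiseless).
#' @param n_pixels ROI size in pixels.
#' @return list(curve (a \code{\link{decay_curve}}), truth).
#' @export
t2star_series <- function(seed = 1L, s0 = 1000, t2star_ms = 30,
                          te_ms = seq(2, 16, by = 2), noise_floor = 0,
                          rician_sd = 0, n_pixels = 100L) {
  set.seed(seed)
  s <- s0 * exp(-te_ms / t2star_ms)
  d <- sqrt(s^2 + noise_floor^2)
  si <- if (rician_sd > 0) {
    vapply(d, function(dk) {
      n1 <- stats::rnorm(n_pixels, 0, rician_sd)
      n2 <- stats::rnorm(n_pixels, 0, rician_sd)
      mean(sqrt((dk + n1)^2 + n2^2))
    }, numeric(1))
  } else d
  list(curve = decay_curve(te_ms, si),
       truth = list(s0 = s0, t2star_ms = t2star_ms,
                    noise_floor = noise_floor, seed = seed))
}

#' Phase-contrast flow phantom
#'
#' A circular vessel with a uniform or parabolic velocity profile and a
#' per-frame peak-velocity waveform; optional velocity aliasing (wrapping
#' into the VENC window) and an optional planar background offset.  Truth
#' volumes integrate the analytic mean velocity times the analytic lumen
#' area over the cycle.
#'
#' @param seed RNG seed.
#' @param radius_mm vessel radius.
#' @param grid image size (pixels, 1 mm spacing).
#' @param waveform peak velocity (cm/s) per frame; default a systolic pulse
#'   with mild diastolic reversal over 20 frames.
#' @param profile \code{"uniform"} or \code{"parabolic"}.
#' @param venc cm/s.
#' @param alias wrap velocities into (-venc, venc] when TRUE.
#' @param offset c(a, b, c): planar background a + b x + c y (cm/s, x/y in
#'   mm).
#' @param noise_sd Gaussian velocity noise SD.
#' @param rr_ms RR interval.
#' @param heart_rate_bpm,bsa_m2 metadata for derived parameters.
#' @return list(series (a \code{\link{velocity_series}}), stationary_mask,
#'   truth).
#' @export
flow_phantom_frames <- function(seed = 1L, radius_mm = 12, grid = 41L,
                                waveform = NULL, profile = c("uniform", "parabolic"),
                                venc = 150, alias = FALSE,
                                offset = c(0, 0, 0), noise_sd = 0,
                                rr_ms = 800, heart_rate_bpm = 75, bsa_m2 = 1.9) {
  profile <- match.arg(profile)
  set.seed(seed)
  n_frames <- if (is.null(waveform)) 20L else length(waveform)
  if (is.null(waveform)) {
    ph <- seq_len(n_frames)
    waveform <- ifelse(ph <= 8, 120 * sin(pi * ph / 8), -8)
  }
  ctr <- (grid - 1) / 2
  xg <- matrix(rep(0:(grid - 1), each = grid), grid, grid)
  yg <- matrix(rep(0:(grid - 1), times = grid), grid, grid)
  rr_px <- sqrt((xg - ctr)^2 + (yg - ctr)^2)
  lumen <- rr_px < radius_mm
  shape <- matrix(0, grid, grid)
  shape[lumen] <- if (profile == "uniform") 1
  else 1 - (rr_px[lumen] / radius_mm)^2
  frames <- lapply(seq_len(n_frames), function(i) {
    v <- waveform[i] * shape +
      offset[1] + offset[2] * xg + offset[3] * yg
    if (noise_sd > 0) v <- v + matrix(stats::rnorm(grid^2, 0, noise_sd),
                                      grid, grid)
    if (alias) ((v + venc) %% (2 * venc)) - venc else v
  })
  roi <- circle_polygon(ctr, ctr, radius_mm, "vessel_lumen", 90)
  trigger <- (seq_len(n_frames) - 1) * rr_ms / n_frames
  series <- velocity_series(frames, pixel_area_mm2 = 1,
                            trigger_times_ms = trigger, rr_ms = rr_ms,
                            venc = venc, te_ms = 3.0, rois = roi)
  mean_factor <- if (profile == "uniform") 1 else 0.5
  area_mm2 <- pi * radius_mm^2
  flux <- waveform * mean_factor * area_mm2 * 0.01   # ml/s
  qq <- c(flux, flux[1]); tt <- c(trigger, trigger[1] + rr_ms) / 1000
  dt <- diff(tt)
  tr <- function(v) sum((utils::head(v, -1) + utils::tail(v, -1)) / 2 * dt)
  truth <- list(antegrade_ml = tr(pmax(qq, 0)), retrograde_ml = tr(pmax(-qq, 0)),
                net_ml = tr(qq),
                rf_pct = 100 * tr(pmax(-qq, 0)) / tr(pmax(qq, 0)),
                peak_velocity_cm_s = max(abs(waveform)),
                aliased = alias, offset = offset, seed = seed)
  list(series = series, stationary_mask = rr_px > radius_mm + 3,
       truth = truth)
}
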