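mk_series <- function(frames, venc = 150, roi = NULL, te = 3,
                      trigger = NULL, rr = 800) {
  n <- length(frames)
  if (is.null(trigger)) trigger <- (seq_len(n) - 1) * rr / n
  velocity_series(frames, pixel_area_mm2 = 1, trigger_times_ms = trigger,
                  rr_ms = rr, venc = venc, te_ms = te, rois = roi)
}

test_that("velocity window shifting inverts aliasing by 2 VENC steps", {
  v <- matrix(c(-125, 50, -150, 149), 2, 2)
  s <- mk_series(list(v))
  # worked example: true 175 recorded as -125 at VENC 150
  s2 <- shift_velocity_window(s, c(-100, 200))
  expect_equal(s2$velocity[[1]][1, 1], 175)
  expect_equal(s2$velocity[[1]][2, 1], 50)      # already inside: unchanged
  expect_equal(s2$velocity[[1]][1, 2], 150)     # -150 wraps to +150
  # round trip back to the default window is the identity on in-window values
  s3 <- shift_velocity_window(shift_velocity_window(s, c(-150, 150)),
                              c(-150, 150))
  expect_equal(s3$velocity[[1]], s$velocity[[1]])
  expect_error(shift_velocity_window(s, c(-100, 100)), "invalid-window")
})

test_that("background offset correction removes constant and planar offsets", {
  fp <- flow_phantom_frames(seed = 1, offset = c(2, 0, 0))
  cc <- background_offset_correction(fp$series, "stationary_fit",
                                     fp$stationary_mask)
  expect_lt(max(abs(cc$velocity[[10]][fp$stationary_mask])), 1e-9)

  fpl <- flow_phantom_frames(seed = 2, offset = c(1.5, 0.04, -0.07))
  cl <- background_offset_correction(fpl$series, "stationary_fit",
                                     fpl$stationary_mask)
  ref <- flow_phantom_frames(seed = 2, offset = c(0, 0, 0))
  for (k in c(1, 7, 15))
    expect_equal(cl$velocity[[k]], ref$series$velocity[[k]], tolerance = 1e-9)

  # phantom-series method: identical offset series leaves zero residual
  ph_off <- flow_phantom_frames(seed = 3, waveform = rep(0, 8),
                                offset = c(1.5, 0.04, -0.07))
  tgt <- flow_phantom_frames(seed = 3, waveform = c(100, 80, 60, 40, 20, 0, 0, 0),
                             offset = c(1.5, 0.04, -0.07))
  cp <- background_offset_correction(tgt$series, "phantom",
                                     phantom_series = ph_off$series)
  clean <- flow_phantom_frames(seed = 3, waveform = c(100, 80, 60, 40, 20, 0, 0, 0))
  expect_equal(cp$velocity[[1]], clean$series$velocity[[1]], tolerance = 1e-9)

  expect_error(background_offset_correction(fp$series, "stationary_fit",
                                            matrix(TRUE, 5, 5)),
               "unreliable-fit")
})

test_that("flux integrates ROI velocity and is linear in velocity and area", {
  # 20x20-pixel square ROI at 1 mm spacing: exactly 4 cm^2
  roi <- contour_polygon(c(-0.5, 19.5, 19.5, -0.5), c(-0.5, -0.5, 19.5, 19.5),
                         "vessel_lumen")
  v <- matrix(50, 30, 30)
  s <- mk_series(list(v), roi = roi)
  fc <- flow_curve(s)
  expect_equal(fc$flux_ml_per_s, 200)
  # linearity in velocity
  s2 <- mk_series(list(2 * v), roi = roi)
  expect_equal(flow_curve(s2)$flux_ml_per_s, 400)
  # parabolic profile: mean velocity is half the peak
  fp <- flow_phantom_frames(seed = 1, profile = "parabolic",
                            waveform = rep(100, 4), radius_mm = 12.6156)
  fx <- flow_curve(fp$series)$flux_ml_per_s
  expect_lt(abs(fx[1] - 250) / 250, 0.05)
})

test_that("volumes, RF and derived parameters follow the printed formulas", {
  # triangle-free synthetic flux: 100 ml antegrade, 25 ml retrograde
  fr <- structure(list(flux_ml_per_s = c(rep(200, 5), rep(-50, 5)),
                       trigger_times_ms = seq(0, 900, by = 100), rr_ms = 1000),
                  class = "flow_curve")
  # piecewise-constant-ish flux integrates by trapezoid; check the identities
  out <- flow_volumes_and_derived(fr, study_meta(70, 2.0))
  expect_equal(out$net_ml, out$antegrade_ml - out$retrograde_ml)
  expect_equal(out$regurgitant_fraction_pct,
               100 * out$retrograde_ml / out$antegrade_ml)
  expect_equal(out$cardiac_output_l_min, out$net_ml * 70 / 1000)
  expect_equal(out$cardiac_index_l_min_m2, out$cardiac_output_l_min / 2)

  # reversing the sign swaps antegrade and retrograde exactly
  rev <- fr; rev$flux_ml_per_s <- -fr$flux_ml_per_s
  out_r <- flow_volumes_and_derived(rev, study_meta(70, 2.0))
  expect_equal(out_r$antegrade_ml, out$retrograde_ml)
  expect_equal(out_r$retrograde_ml, out$antegrade_ml)

  # lung split and AV-regurgitation methods
  out2 <- flow_volumes_and_derived(fr, study_meta(70, 2.0),
                                   rpa_net_ml = 60, lpa_net_ml = 40,
                                   av_diastolic_inflow_ml = 95,
                                   semilunar_forward_ml = 80,
                                   cine_sv_ml = 100)
  expect_equal(out2$right_lung_pct, 60)
  expect_equal(out2$left_lung_pct, 40)
  expect_equal(out2$av_regurgitant_ml_method_a, 15)
  expect_equal(out2$av_regurgitant_ml_method_b, 20)
})

test_that("phantom round trip recovers truth, including after aliasing and offset", {
  fp <- flow_phantom_frames(seed = 4)
  out <- flow_volumes_and_derived(flow_curve(fp$series), study_meta(75, 1.9))
  expect_lt(abs(out$net_ml - fp$truth$net_ml) / fp$truth$net_ml, 0.05)
  expect_equal(out$regurgitant_fraction_pct, fp$truth$rf_pct, tolerance = 0.01)
  pv <- peak_velocity(fp$series)
  expect_equal(pv$peak_velocity_cm_s, fp$truth$peak_velocity_cm_s)

  # aliased acquisition: unwrap by moving the window, then equal results
  fa <- flow_phantom_frames(seed = 4, waveform = c(175, 160, 120, 60, -10, -10),
                            alias = TRUE, venc = 150)
  un <- shift_velocity_window(fa$series, c(-100, 200))
  expect_equal(peak_velocity(un)$peak_velocity_cm_s, 175)
  ref <- flow_phantom_frames(seed = 4, waveform = c(175, 160, 120, 60, -10, -10))
  out_a <- flow_volumes_and_derived(flow_curve(un), study_meta(75, 1.9))
  out_ref <- flow_volumes_and_derived(flow_curve(ref$series), study_meta(75, 1.9))
  expect_equal(out_a$net_ml, out_ref$net_ml, tolerance = 1e-9)

  # planar offset + correction: machine-precision recovery
  fo <- flow_phantom_frames(seed = 5, offset = c(1, 0.03, -0.02))
  co <- background_offset_correction(fo$series, "stationary_fit",
                                     fo$stationary_mask)
  clean <- flow_phantom_frames(seed = 5)
  expect_equal(flow_curve(co)$flux_ml_per_s,
               flow_curve(clean$series)$flux_ml_per_s, tolerance = 1e-9)
})

test_that("peak velocity modes match hand arithmetic and the brute-force oracle", {
  v <- matrix(150, 15, 15)
  v[8, 8] <- 200
  roi <- contour_polygon(c(1, 13, 13, 1), c(1, 1, 13, 13), "vessel_lumen")
  s <- mk_series(list(v), roi = roi, venc = 300)
  expect_equal(peak_velocity(s, "single_pixel")$peak_velocity_cm_s, 200)
  expect_equal(peak_velocity(s, "neighborhood_mean", 3)$peak_velocity_cm_s,
               (200 + 8 * 150) / 9)
  # neighborhood spanning the whole ROI degenerates to the ROI mean
  s_small <- mk_series(list(v), roi = contour_polygon(c(6.5, 8.5, 8.5, 6.5),
                                                      c(6.5, 6.5, 8.5, 8.5),
                                                      "vessel_lumen"),
                       venc = 300)
  expect_equal(peak_velocity(s_small, "neighborhood_mean", 9)$peak_velocity_cm_s,
               mean(c(200, rep(150, 3))))

  # random maps vs brute force
  set.seed(9)
  frames <- lapply(1:3, function(i) matrix(rnorm(225, 0, 60), 15, 15))
  s2 <- mk_series(frames, roi = roi, venc = 300)
  mask <- rasterize_contour(roi, c(15, 15))
  expect_equal(peak_velocity(s2, "neighborhood_mean", 3)$peak_velocity_cm_s,
               oracle_neighborhood_peak(frames, mask, 3), tolerance = 1e-12)
  expect_equal(peak_velocity(s2, "single_pixel")$peak_velocity_cm_s,
               {vv <- unlist(lapply(frames, function(f) f[mask]))
                vv[which.max(abs(vv))]})
})

test_that("QC flags TE, suspected aliasing and poor velocity contrast", {
  roi <- contour_polygon(c(1, 13, 13, 1), c(1, 1, 13, 13), "vessel_lumen")
  ok <- mk_series(list(matrix(100, 15, 15)), roi = roi, te = 3.4)
  expect_false(qc_checks(ok)$te_warning)
  hot <- mk_series(list(matrix(100, 15, 15)), roi = roi, te = 3.6)
  expect_true(qc_checks(hot)$te_warning)

  clipped <- matrix(100, 15, 15); clipped[6:8, 6:8] <- 150
  s <- mk_series(list(clipped), roi = roi)
  expect_true(qc_checks(s)$aliasing_warning)

  weak <- mk_series(list(matrix(50, 15, 15)), roi = roi, venc = 400)
  expect_true(qc_checks(weak)$poor_contrast_warning)
  expect_false(qc_checks(mk_series(list(matrix(100, 15, 15)), roi = roi,
                                   venc = 150))$poor_contrast_warning)
})
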