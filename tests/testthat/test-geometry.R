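test_that("polygon area is exact, orientation-free and rotation-invariant", {
  sq <- contour_polygon(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_equal(polygon_area(sq), 100)
  sq_cw <- contour_polygon(rev(c(0, 10, 10, 0)), rev(c(0, 0, 10, 10)))
  expect_equal(polygon_area(sq_cw), 100)

  circ <- make_circle(30, 30, 20, n = 256)
  expect_lt(abs(polygon_area(circ) - pi * 400) / (pi * 400), 0.001)

  # cyclic re-indexing and reflection leave the area unchanged
  for (k in c(3, 57, 200)) {
    rot <- contour_polygon(c(circ$x[k:256], circ$x[1:(k - 1)]),
                           c(circ$y[k:256], circ$y[1:(k - 1)]))
    expect_equal(polygon_area(rot), polygon_area(circ))
  }
  refl <- contour_polygon(-circ$x, circ$y)
  expect_equal(polygon_area(refl), polygon_area(circ))

  expect_error(contour_polygon(c(0, 1), c(0, 0)), "3 vertices")
  expect_error(contour_polygon(c(0, 1, 2), c(0, 0, 0)), "zero")
})

test_that("AHA model partitions slices into thirds with basal-first remainder", {
  mk_stack <- function(n) {
    slices <- lapply(seq_len(n) - 1L, function(i) slice_geometry(i, i * 10, 8, 2))
    contour_stack(slices, 1L, study_meta(70, 1.9))
  }
  m9 <- build_aha_model(mk_stack(9), 0, 17, slice_indices = 0:8)
  expect_equal(as.integer(table(factor(m9$ring_of_slice,
                                      c("basal", "mid", "apical")))), c(3L, 3L, 3L))
  m10 <- build_aha_model(mk_stack(10), 0, 17, slice_indices = 0:9)
  expect_equal(as.integer(table(factor(m10$ring_of_slice,
                                       c("basal", "mid", "apical")))), c(4L, 3L, 3L))
  m11 <- build_aha_model(mk_stack(11), 0, 17, slice_indices = 0:10)
  expect_equal(as.integer(table(factor(m11$ring_of_slice,
                                       c("basal", "mid", "apical")))), c(4L, 4L, 3L))

  expect_equal(sort(m9$segment_spans$segment_id), 1:17)
  m16 <- build_aha_model(mk_stack(9), 0, 16, slice_indices = 0:8)
  expect_equal(sort(m16$segment_spans$segment_id), 1:16)
  # per ring the spans cover exactly 360 degrees and are disjoint
  for (ring in c("basal", "mid", "apical")) {
    sp <- m9$segment_spans[m9$segment_spans$ring == ring, ]
    expect_equal(sum(sp$end_deg - sp$start_deg), 360)
    sp <- sp[order(sp$start_deg), ]
    expect_true(all(diff(c(sp$start_deg, 360)) == sp$end_deg - sp$start_deg))
  }
  expect_error(build_aha_model(mk_stack(3), 0, 17, slice_indices = 0:1),
               "insufficient-coverage")
})

test_that("pixel-to-segment assignment partitions the mask and matches brute force", {
  slices <- lapply(0:2, function(i) slice_geometry(i, i * 10, 8, 2))
  stack <- contour_stack(slices, 1L, study_meta(70, 1.9))
  insertion <- 37  # arbitrary non-axis-aligned reference
  model <- build_aha_model(stack, insertion, 17, slice_indices = 0:2)

  g <- grid_xy(81); ctr <- 40
  rr <- sqrt((g$x - ctr)^2 + (g$y - ctr)^2)
  annulus <- rr >= 12 & rr < 20
  seg <- assign_pixels_to_segments(annulus, model, 0)   # basal ring

  # partition: every mask pixel assigned, nothing outside
  expect_true(all(!is.na(seg[annulus])))
  expect_true(all(is.na(seg[!annulus])))
  expect_true(all(seg[annulus] %in% 1:6))

  # symmetry: roughly equal 60-degree bins
  counts <- table(seg[annulus])
  expect_lt(max(counts) - min(counts), 0.1 * mean(counts))

  # brute-force oracle: per-pixel angle binning from scratch
  ij <- which(annulus, arr.ind = TRUE)
  px <- ij[, 2] - 1; py <- ij[, 1] - 1
  cx <- mean(px); cy <- mean(py)
  th <- (atan2(py - cy, px - cx) * 180 / pi - insertion) %% 360
  expect_equal(unname(seg[which(annulus)]), unname(1L + (floor(th / 60) %% 6L)))

  # boundary angle belongs to the counterclockwise-following segment: with a
  # 45-degree insertion, the pixel exactly on the diagonal starts segment 1
  model45 <- build_aha_model(stack, 45, 17, slice_indices = 0:2)
  m <- matrix(FALSE, 81, 81)
  m[ctr + 11, ctr + 11] <- TRUE   # (x, y) = (10, 10) from centre: angle 45
  seg1 <- assign_pixels_to_segments(m, model45, 0, centroid = c(ctr, ctr))
  expect_equal(seg1[ctr + 11, ctr + 11], 1L)
  # one degree clockwise of the boundary falls in the previous segment
  m2 <- matrix(FALSE, 81, 81)
  m2[ctr + 1, ctr + 15] <- TRUE   # angle 0, i.e. -45 relative: segment 6
  seg6 <- assign_pixels_to_segments(m2, model45, 0, centroid = c(ctr, ctr))
  expect_equal(seg6[ctr + 1, ctr + 15], 6L)

  # apical ring: four 90-degree segments, near-equal occupancy
  sega <- assign_pixels_to_segments(annulus, model, 2)
  expect_true(all(sega[annulus] %in% 13:16))
  ca <- table(sega[annulus])
  expect_lt(max(ca) - min(ca), 0.05 * mean(ca))

  m16 <- build_aha_model(stack, 0, 16, slice_indices = 0:2)
  m16$ring_of_slice[["2"]] <- "apical_cap"
  expect_error(assign_pixels_to_segments(annulus, m16, 2), "invalid-ring")
})

test_that("transmural chords recover analytic annulus fractions and are monotone", {
  endo <- make_circle(40, 40, 20, "endocardial", 144)
  epi <- make_circle(40, 40, 30, "epicardial", 144)
  g <- grid_xy(81)
  rr <- sqrt((g$x - 40)^2 + (g$y - 40)^2)
  myo <- rr >= 20 & rr < 30

  ch_full <- transmural_chords(endo, epi, myocardium_mask(endo, epi, c(81, 81)), 48)
  expect_true(all(ch_full$enhanced_fraction == 1))
  ch_empty <- transmural_chords(endo, epi, matrix(FALSE, 81, 81), 48)
  expect_true(all(ch_empty$enhanced_fraction == 0))

  # 0.5 mm pixels: per-chord quantization stays within one pixel of wall
  gf <- grid_xy(161)
  rf <- 0.5 * sqrt((gf$x - 80)^2 + (gf$y - 80)^2)
  inner40 <- rf >= 20 & rf < 24   # inner 40% of the 10 mm wall
  ch40 <- transmural_chords(endo, epi, inner40, 48,
                            pixel_spacing = c(0.5, 0.5))
  expect_true(all(abs(ch40$enhanced_fraction - 0.40) <= 0.1))
  expect_lt(abs(mean(ch40$enhanced_fraction) - 0.40), 0.02)

  # monotone: enlarging the mask never decreases any chord's fraction
  inner60 <- rf >= 20 & rf < 26
  ch60 <- transmural_chords(endo, epi, inner60, 48,
                            pixel_spacing = c(0.5, 0.5))
  expect_true(all(ch60$enhanced_fraction >= ch40$enhanced_fraction))

  expect_error(transmural_chords(epi, endo, myo, 48), "not enclosed")
  expect_error(transmural_chords(endo, epi, myo, 8), ">= 12")
})

test_that("endo/epi layer split matches the nearest-boundary-distance oracle", {
  endo <- make_circle(30, 30, 20, "endocardial", 144)
  epi <- make_circle(30, 30, 30, "epicardial", 144)
  sp <- split_endo_epi_layers(endo, epi, c(61, 61))
  myo <- myocardium_mask(endo, epi, c(61, 61))
  # partition of the myocardium
  expect_true(all(xor(sp$endo_layer[myo], sp$epi_layer[myo])))
  expect_false(any(sp$endo_layer & !myo) || any(sp$epi_layer & !myo))
  # concentric circles: boundary at the midwall radius 25 mm
  g <- grid_xy(61)
  rr <- sqrt((g$x - 30)^2 + (g$y - 30)^2)
  expect_true(all(rr[sp$endo_layer] < 25.01))
  expect_true(all(rr[sp$epi_layer] > 24.6))

  # eccentric endocardium: per-pixel agreement with the brute-force oracle
  endo_e <- make_circle(33, 30, 18, "endocardial", 144)
  sp_e <- split_endo_epi_layers(endo_e, epi, c(61, 61))
  orc <- oracle_layer_split(endo_e, epi, c(61, 61))
  expect_equal(sp_e$endo_layer, orc$endo_layer)
  expect_equal(sp_e$epi_layer, orc$epi_layer)
})

test_that("contour stack bookkeeping validates slices, phases and topology", {
  slices <- list(slice_geometry(0, 0, 8, 2), slice_geometry(1, 10, 8, 2))
  st <- contour_stack(slices, 2L, study_meta(60, 1.8))
  endo <- make_circle(30, 30, 15, "endocardial")
  st <- stack_add_contour(st, 0, 0, endo)
  expect_error(stack_add_contour(st, 5, 0, endo), "not present")
  expect_error(stack_add_contour(st, 0, 2, endo), "outside")
  expect_equal(stack_contour(st, 0, 0, "endocardial")$x, endo$x)
  expect_null(stack_contour(st, 1, 0, "endocardial"))
  expect_error(slice_geometry(0, 0, -1, 0), "thickness")
  expect_error(study_meta(-10), "heart_rate")
})
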