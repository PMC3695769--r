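mk_single_slice_stack <- function(endo_area_mm2, thickness = 8, gap = 2,
                                  pap_areas = numeric(0), n_phases = 1) {
  st <- contour_stack(list(slice_geometry(0, 0, thickness, gap)), n_phases,
                      study_meta(70, 2.0))
  side <- sqrt(endo_area_mm2)
  st <- stack_add_contour(st, 0, 0, square_poly(side, "endocardial", 40, 40))
  for (a in pap_areas)
    st <- stack_add_contour(st, 0, 0, square_poly(sqrt(a), "papillary", 40, 40))
  st
}

test_that("slice blood volume follows area x (thickness + gap) and papillary mode", {
  st <- mk_single_slice_stack(1000)
  expect_equal(slice_blood_volume(st, 0, 0, "included_in_blood"), 10)
  stp <- mk_single_slice_stack(1000, pap_areas = c(60, 40))
  expect_equal(slice_blood_volume(stp, 0, 0, "included_in_myocardium"), 9)
  expect_equal(slice_blood_volume(stp, 0, 0, "included_in_blood"), 10)
  expect_error(slice_blood_volume(contour_stack(list(slice_geometry(0, 0, 8, 2)),
                                                1, study_meta()), 0, 0),
               "missing-contour")
})

test_that("global ED/ES phases are the summed-volume extremes with earliest tie-break", {
  slices <- list(slice_geometry(0, 0, 8, 2))
  st <- contour_stack(slices, 6L, study_meta(70, 2.0))
  vols <- c(150, 130, 90, 60, 80, 120) * 100  # mm^2 so ml = area/100
  for (ph in 0:5)
    st <- stack_add_contour(st, 0, ph, square_poly(sqrt(vols[ph + 1]),
                                                   "endocardial", 40, 40))
  sel <- select_global_ed_es(st)
  expect_equal(sel$ed_phase, 0L)
  expect_equal(sel$es_phase, 3L)

  # tie for the minimum resolves to the earlier phase
  st2 <- contour_stack(slices, 3L, study_meta(70, 2.0))
  for (ph in 0:2)
    st2 <- stack_add_contour(st2, 0, ph, square_poly(sqrt(c(200, 100, 100)[ph + 1] * 100),
                                                     "endocardial", 40, 40))
  expect_equal(select_global_ed_es(st2)$es_phase, 1L)
})

test_that("basal slice classification implements the atrial-exclusion rule", {
  # full annulus, shrinking in systole: ventricular
  st <- contour_stack(list(slice_geometry(0, 0, 8, 2),
                           slice_geometry(1, 10, 8, 2)), 2L, study_meta(70, 2))
  st <- stack_add_contour(st, 0, 0, make_circle(40, 40, 25, "endocardial"))
  st <- stack_add_contour(st, 0, 0, make_circle(40, 40, 32, "epicardial"))
  st <- stack_add_contour(st, 0, 1, make_circle(40, 40, 20, "endocardial"))
  st <- stack_add_contour(st, 0, 1, make_circle(40, 40, 32, "epicardial"))
  expect_equal(classify_basal_slice(st, 0, 0, 1)$classification,
               "ventricular_blood_and_mass")

  # only a 40% myocardial arc and cavity expanding in systole: atrium
  arc <- function(frac) {
    th <- seq(0, 2 * pi * frac, length.out = 40)
    contour_polygon(c(40 + 26 * cos(th), 40 + 33 * rev(cos(th))),
                    c(40 + 26 * sin(th), 40 + 33 * rev(sin(th))), "epicardial")
  }
  st2 <- contour_stack(list(slice_geometry(0, 0, 8, 2),
                            slice_geometry(1, 10, 8, 2)), 2L, study_meta(70, 2))
  st2 <- stack_add_contour(st2, 0, 0, make_circle(40, 40, 25, "endocardial"))
  st2 <- stack_add_contour(st2, 0, 0, arc(0.40))
  st2 <- stack_add_contour(st2, 0, 1, make_circle(40, 40, 27, "endocardial"))
  cl <- classify_basal_slice(st2, 0, 0, 1)
  expect_equal(cl$classification, "atrium_exclude")

  # myocardial crescent without blood pool: mass only
  st3 <- contour_stack(list(slice_geometry(0, 0, 8, 2),
                            slice_geometry(1, 10, 8, 2)), 2L, study_meta(70, 2))
  st3 <- stack_add_contour(st3, 0, 0, arc(0.35))
  expect_equal(classify_basal_slice(st3, 0, 0, 1)$classification,
               "mass_only_crescent")
  # same situation on the most apical slice: apical mass only
  st4 <- contour_stack(list(slice_geometry(0, 0, 8, 2),
                            slice_geometry(1, 10, 8, 2)), 2L, study_meta(70, 2))
  st4 <- stack_add_contour(st4, 1, 0, make_circle(40, 40, 8, "epicardial"))
  expect_equal(classify_basal_slice(st4, 1, 0, 1)$classification,
               "apical_mass_only")
})

test_that("derived volumetry values follow their defining formulas", {
  r <- cmrpost:::new_volumetry_result("lv", 150, 60, 0L, 5L,
                                      study_meta(70, 2.0), mass = 100,
                                      papillary_mode = "included_in_blood")
  expect_equal(r$sv_ml, 90)
  expect_equal(r$ef_pct, 60)
  expect_equal(r$co_l_min, 6.3)
  expect_equal(r$edvi_ml_m2, 75)
  expect_equal(r$ci_l_min_m2, 3.15)
})

test_that("Simpson volume of a sphere phantom converges with slice refinement", {
  truth <- 4 / 3 * pi * 30^3 / 1000
  errs <- sapply(c(10, 5, 2.5), function(th) {
    ph <- ellipsoid_ventricle_stack(ed_semi_axes = c(30, 30, 30),
                                    es_semi_axes = c(30, 30, 30),
                                    wall_thickness_mm = 8,
                                    slice_thickness_mm = th, gap_mm = 0,
                                    n_phases = 2, n_vertices = 360)
    sel <- select_global_ed_es(ph$stack)
    v <- sum(sapply(stack_slice_indices(ph$stack), function(s)
      slice_blood_volume(ph$stack, s, sel$ed_phase)))
    abs(v - truth) / truth
  })
  expect_lt(errs[1], 0.02)
  expect_true(all(diff(errs) < 0))
})

test_that("LV assessment recovers phantom truth and RV carries a not-computed mass", {
  ph <- ellipsoid_ventricle_stack()
  lv <- lv_assessment(ph$stack)
  expect_equal(lv$ed_phase, ph$truth$ed_phase)
  expect_equal(lv$es_phase, ph$truth$es_phase)
  expect_lt(abs(lv$edv_ml - ph$truth$edv_ml) / ph$truth$edv_ml, 0.02)
  expect_lt(abs(lv$ef_pct - ph$truth$ef_pct), 1)
  expect_lt(abs(lv$mass_g - ph$truth$mass_g) / ph$truth$mass_g, 0.02)
  expect_equal(lv$papillary_mode, "included_in_blood")

  rv <- rv_assessment(ph$stack)
  expect_equal(rv$edv_ml, lv$edv_ml)   # identical contours, same math path
  expect_equal(rv$ef_pct, lv$ef_pct)
  expect_false(rv$mass_computed)
  expect_true(is.na(rv$mass_g))
})

test_that("LV mass applies the 1.05 g/ml density to the wall volume", {
  # epi 100 ml, endo 50 ml over a 10 mm step
  st <- contour_stack(list(slice_geometry(0, 0, 8, 2)), 1, study_meta(70, 2))
  st <- stack_add_contour(st, 0, 0, square_poly(sqrt(10000), "epicardial", 60, 60))
  st <- stack_add_contour(st, 0, 0, square_poly(sqrt(5000), "endocardial", 60, 60))
  expect_equal(lv_mass(st, 0), 52.5)

  # endo == epi everywhere: zero wall
  st0 <- contour_stack(list(slice_geometry(0, 0, 8, 2)), 1, study_meta(70, 2))
  st0 <- stack_add_contour(st0, 0, 0, square_poly(50, "epicardial", 60, 60))
  st0 <- stack_add_contour(st0, 0, 0, square_poly(50, "endocardial", 60, 60))
  expect_equal(lv_mass(st0, 0), 0)

  # papillary tissue moves between blood and myocardium conservatively
  stp <- mk_single_slice_stack(1000, pap_areas = 100)
  stp <- stack_add_contour(stp, 0, 0, square_poly(sqrt(2000), "epicardial", 40, 40))
  dv <- slice_blood_volume(stp, 0, 0, "included_in_blood") -
    slice_blood_volume(stp, 0, 0, "included_in_myocardium")
  dm <- lv_mass(stp, 0, "included_in_myocardium") -
    lv_mass(stp, 0, "included_in_blood")
  expect_equal(dm, dv * 1.05)

  # mass / myocardial volume is the density constant for any phantom:
  # recompute the Simpson wall volume from the same polygons independently
  ph <- ellipsoid_ventricle_stack()
  m <- lv_mass(ph$stack, 0)
  wall_ml <- sum(sapply(stack_slice_indices(ph$stack), function(s) {
    epi <- stack_contour(ph$stack, s, 0, "epicardial")
    endo <- stack_contour(ph$stack, s, 0, "endocardial")
    if (is.null(epi)) return(0)
    g <- stack_slice(ph$stack, s)
    (polygon_area(epi) - polygon_area(endo)) * (g$thickness_mm + g$gap_mm) / 1000
  }))
  expect_equal(m / wall_ml, 1.05, tolerance = 1e-12)
  expect_equal(ph$truth$mass_g / ph$truth$myo_volume_ml, 1.05)
})

test_that("EF is invariant under uniform contour scaling", {
  ph <- ellipsoid_ventricle_stack()
  scaled <- ph$stack
  scaled$contours <- lapply(scaled$contours, function(e) {
    e$polygon$x <- e$polygon$x * 1.7; e$polygon$y <- e$polygon$y * 1.7; e
  })
  expect_equal(lv_assessment(scaled)$ef_pct, lv_assessment(ph$stack)$ef_pct,
               tolerance = 1e-10)
})

test_that("area-length volumes reproduce the printed equations", {
  expect_equal(as.numeric(area_length_volume("single", 30, length = 8)), 95.625)
  expect_equal(as.numeric(area_length_volume("biplane", 30, 20, 8)), 63.75)
  expect_error(area_length_volume("single", -1, length = 8), "domain")
  expect_error(area_length_volume("biplane", 30, length = 8), "domain")
  expect_equal(attr(area_length_volume("single", 30, length = 8), "method"),
               "area_length_single")

  # exact ellipse input vs the analytic prolate spheroid: ratio 0.85/(8/3pi)
  a <- 4; b <- 2
  v_formula <- as.numeric(area_length_volume("single", pi * a * b, length = 2 * a))
  v_spheroid <- 4 / 3 * pi * a * b^2
  expect_equal(v_formula / v_spheroid, 0.85 * 3 * pi / 8, tolerance = 1e-12)
  expect_lt(abs(v_formula / v_spheroid - 1), 0.002)
})

test_that("stroke-volume consistency uses a relative rule with inclusive boundary", {
  expect_true(stroke_volume_consistency(80, 78)$consistent)
  expect_equal(stroke_volume_consistency(80, 78)$relative_difference, 0.025)
  r <- stroke_volume_consistency(80, 50)
  expect_false(r$consistent)
  expect_equal(r$relative_difference, 0.375)
  expect_true(stroke_volume_consistency(80, 72, 0.10)$consistent)  # boundary
})

test_that("linear dimensions match annulus geometry and a ray-casting oracle", {
  endo <- make_circle(40, 40, 25, "endocardial", 144)
  epi <- make_circle(40, 40, 35, "epicardial", 144)
  for (ang in c(0, 30, 115)) {
    d <- linear_dimensions(endo, epi, ang)
    expect_equal(d$cavity_diameter_mm, 50, tolerance = 0.01)
    expect_equal(d$septal_wall_mm, 10, tolerance = 0.01)
    expect_equal(d$lateral_wall_mm, 10, tolerance = 0.01)
  }
  ell <- make_ellipse(40, 40, 30, 20, "endocardial", 144)
  epi2 <- make_ellipse(40, 40, 36, 26, "epicardial", 144)
  expect_equal(linear_dimensions(ell, epi2, 0)$cavity_diameter_mm, 60,
               tolerance = 0.02)

  # eccentric annulus vs dense point-marching oracle along the ray
  endo_e <- make_circle(43, 40, 20, "endocardial", 360)
  epi_e <- make_circle(40, 40, 32, "epicardial", 360)
  d <- linear_dimensions(endo_e, epi_e, 25)
  ctr <- polygon_centroid(endo_e)
  march <- function(ang) {
    t <- seq(0, 60, by = 0.001)
    px <- ctr[1] + t * cos(ang * pi / 180); py <- ctr[2] + t * sin(ang * pi / 180)
    inside_en <- points_in_polygon(px, py, endo_e)
    inside_ep <- points_in_polygon(px, py, epi_e)
    c(endo = t[max(which(inside_en))], epi = t[max(which(inside_ep))])
  }
  f <- march(25); b <- march(205)
  expect_equal(d$cavity_diameter_mm, unname(f["endo"] + b["endo"]), tolerance = 0.01)
  expect_equal(d$septal_wall_mm, unname(f["epi"] - f["endo"]), tolerance = 0.01)
  expect_equal(d$lateral_wall_mm, unname(b["epi"] - b["endo"]), tolerance = 0.01)
})
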