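test_that("the centerline of a symmetric straight cone lies on its axis", {
  gs <- generate_spine_profile(spine_gen_params(tip_angle = 50,
                                                structural_curvature = 0))
  cl <- extract_centerline(gs$profile, 200L)
  # the generator builds the cone along x = 0
  expect_lt(max(abs(cl[, 1L])), 1e-4 * 3.22)
})

test_that("n_stations = 2 returns only the base midpoint and apex", {
  gs <- generate_spine_profile(spine_gen_params())
  cl <- extract_centerline(gs$profile, 2L)
  expect_identical(nrow(cl), 2L)
  expect_equal(cl[2L, ], unname(gs$profile$vertices[gs$profile$tip_index, ]),
               tolerance = 1e-12)
})

test_that("the traced centerline recovers the generative arc", {
  gs <- generate_spine_profile(spine_gen_params(tip_angle = 30,
                                                structural_curvature = 80))
  cl <- extract_centerline(gs$profile, 200L)
  R <- gs$ground_truth$arc_radius
  # generative arc center is at (-R, 0)
  dev <- sqrt((cl[, 1L] + R)^2 + cl[, 2L]^2) - R
  expect_lt(max(abs(dev)), 0.02 * 3.22)
})

test_that("tip angle of an exact wedge is recovered", {
  # isoceles triangle with a 30 degree apex, apex down at the origin
  half <- tan(pi / 12)
  t_up <- seq(0.05, 3, length.out = 60)
  tri <- rbind(c(0, 0),
               cbind(half * t_up, t_up),
               cbind(-half * rev(t_up), rev(t_up)))
  prof <- spine_profile(tri, 1L)
  expect_equal(measure_tip_angle(prof, cap_exclusion = 0),
               30, tolerance = 0.5)
})

test_that("tip angle is stable across flank windows on a hooked spine", {
  # base width chosen so the flanks stay straight through the widest window
  gs <- generate_spine_profile(spine_gen_params(tip_angle = 45,
                                                structural_curvature = 95,
                                                base_width = 0.55 * 3.22))
  vals <- vapply(c(0.10, 0.15, 0.20),
                 function(w) measure_tip_angle(gs$profile, flank_window = w),
                 numeric(1))
  expect_lt(max(vals) - min(vals), 3)
  expect_equal(mean(vals), 45, tolerance = 3)
})

test_that("tip radius of curvature matches the generated cap exactly", {
  for (rn in c(0.025, 0.08)) {
    gs <- generate_spine_profile(
      spine_gen_params(tip_angle = 40, structural_curvature = 0,
                       tip_roc = rn * 3.22, base_width = 0.8))
    r <- measure_tip_roc(gs$profile)
    expect_equal(r$tip_roc_norm, rn, tolerance = 0.005)
    expect_true(r$reliable)
  }
})

test_that("an oversized fixed cap window on a cone is flagged unreliable", {
  gs <- generate_spine_profile(spine_gen_params(tip_angle = 30,
                                                structural_curvature = 0,
                                                tip_roc = 0.02))
  r <- measure_tip_roc(gs$profile, cap_window = 0.5, adaptive = FALSE)
  expect_false(r$reliable)
  # with the same window a true semicircular cap of that size would fit
  # with tiny residuals; the wedge flanks force a large relative rmse
  expect_gt(r$rmse / r$tip_roc, 0.02)
})

test_that("structural curvature recovers straight, curved and extreme spines", {
  g0 <- generate_spine_profile(spine_gen_params(tip_angle = 40,
                                                structural_curvature = 0))
  expect_lte(as.numeric(measure_structural_curvature(g0$profile)), 5)
  for (sc in c(16.89, 90, 109.69)) {
    gs <- generate_spine_profile(spine_gen_params(tip_angle = 45,
                                                  structural_curvature = sc))
    expect_equal(as.numeric(measure_structural_curvature(gs$profile)), sc,
                 tolerance = 5)
  }
})

test_that("metrics are invariant under rigid motion and equivariant under scaling", {
  gs <- generate_spine_profile(spine_gen_params(tip_angle = 35,
                                                structural_curvature = 55,
                                                tip_roc = 0.09))
  base_ta <- measure_tip_angle(gs$profile)
  base_roc <- measure_tip_roc(gs$profile)
  base_sc <- as.numeric(measure_structural_curvature(gs$profile))
  set.seed(11)
  for (rep in 1:3) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    shift <- runif(2, -5, 5)
    v2 <- sweep(gs$profile$vertices %*% R, 2L, -shift)
    p2 <- spine_profile(v2, gs$profile$tip_index, check = FALSE)
    expect_equal(measure_tip_angle(p2), base_ta, tolerance = 1e-6)
    expect_equal(measure_tip_roc(p2)$tip_roc, base_roc$tip_roc,
                 tolerance = 1e-6 * base_roc$tip_roc)
    expect_equal(as.numeric(measure_structural_curvature(p2)), base_sc,
                 tolerance = 0.2)
  }
  # uniform scaling: tip_roc scales linearly, angles and normalised radius
  # are invariant
  p3 <- spine_profile(2.5 * gs$profile$vertices, gs$profile$tip_index,
                      check = FALSE)
  expect_equal(measure_tip_angle(p3), base_ta, tolerance = 1e-6)
  r3 <- measure_tip_roc(p3)
  expect_equal(r3$tip_roc, 2.5 * base_roc$tip_roc,
               tolerance = 1e-6 * base_roc$tip_roc)
  expect_equal(r3$tip_roc_norm, base_roc$tip_roc_norm, tolerance = 1e-9)
  expect_equal(as.numeric(measure_structural_curvature(p3)), base_sc,
               tolerance = 0.2)
})

test_that("morphotype thresholds classify the canonical cases", {
  cone <- generate_spine_profile(spine_gen_params(tip_angle = 50,
                                                  structural_curvature = 0))
  cl <- extract_centerline(cone$profile)
  mt <- classify_morphotype(list(aspect_ratio = 0.6,
                                 structural_curvature = 0), cl)
  expect_false(mt$elongate)   # aspect ratio over 50% = short
  expect_false(mt$hooked)
  expect_false(mt$wavy)
  expect_true(mt$conical)

  hook <- generate_spine_profile(spine_gen_params(tip_angle = 40,
                                                  structural_curvature = 109.7))
  clh <- extract_centerline(hook$profile)
  mth <- classify_morphotype(list(aspect_ratio = 0.2,
                                  structural_curvature = 109.7), clh,
                             lateral_compression = 0.5)
  expect_true(mth$elongate)
  expect_true(mth$hooked)
  expect_false(mth$conical)

  wavy <- generate_spine_profile(spine_gen_params(tip_angle = 30,
                                                  structural_curvature = 5,
                                                  waviness = 0.4))
  clw <- extract_centerline(wavy$profile)
  mtw <- classify_morphotype(list(aspect_ratio = 0.2,
                                  structural_curvature = 5), clw)
  expect_true(mtw$wavy)
})

test_that("spine_metrics assembles a complete per-spine row", {
  gs <- generate_spine_profile(spine_gen_params(tip_angle = 45,
                                                structural_curvature = 70))
  mesh <- generate_spine_mesh(gs$profile, 0.9, n_stations = 48L,
                              n_around = 16L)
  row <- spine_metrics(gs$profile, mesh, spine_id = "demo")
  expect_identical(row$spine_id, "demo")
  expect_equal(row$tip_angle_deg, 45, tolerance = 2)
  expect_equal(row$structural_curvature_deg, 70, tolerance = 5)
  expect_gt(row$volume_mm3, 0)
  expect_true(row$hooked)
})
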