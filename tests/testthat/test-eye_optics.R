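test_that("interommatidial angle recovers pitch/R on circular arcs", {
  # spec'd reference case: R = 0.5 mm, pitch = 0.02 mm, two rows per step
  pr <- eye_profile(oracle_arc_points(0.5, 0.02 / 0.5, 21), apex_index = 11L)
  expect_equal(interommatidial_angle(pr), 0.02 / 0.5 * 180 / pi,
               tolerance = 1e-9)
  expect_equal(round(interommatidial_angle(pr), 4), 2.2918)

  # parameter sweep: any radius, pitch ratio, and step recovers the
  # per-facet angle
  for (R in c(0.1, 0.5, 2)) {
    for (ratio in c(0.01, 0.05, 0.2)) {
      step <- ratio
      pr <- eye_profile(oracle_arc_points(R, step, 15), apex_index = 8L)
      truth <- step * 180 / pi
      for (s in 1:3) {
        est <- interommatidial_angle(pr, rows_per_step = s)
        expect_equal(est, truth, tolerance = 1e-9)
      }
    }
  }
})

test_that("geometric estimators are invariant under rigid motion and scale", {
  set.seed(11)
  for (rep in 1:10) {
    R <- runif(1, 0.1, 2); step <- runif(1, 0.02, 0.15); n <- 15L
    rot <- runif(1, 0, 2 * pi); shift <- runif(2, -5, 5)
    scale <- runif(1, 0.2, 5)
    base <- eye_profile(oracle_arc_points(R, step, n), apex_index = 8L)
    moved <- eye_profile(oracle_arc_points(R, step, n, rot, shift, scale),
                         apex_index = 8L)
    expect_equal(interommatidial_angle(moved), interommatidial_angle(base),
                 tolerance = 1e-9)
    expect_equal(visual_field_span(moved), visual_field_span(base),
                 tolerance = 1e-9)
  }
  # doubling all coordinates leaves the angle unchanged
  pr <- eye_profile(oracle_arc_points(0.5, 0.04, 11), apex_index = 6L)
  pr2 <- eye_profile(oracle_arc_points(0.5, 0.04, 11, scale = 2),
                     apex_index = 6L)
  expect_equal(interommatidial_angle(pr2), interommatidial_angle(pr),
               tolerance = 1e-12)
})

test_that("flat or truncated profiles raise geometric errors", {
  flat <- eye_profile(cbind(seq(0, 1, length.out = 7), 0.5))
  expect_error(interommatidial_angle(flat),
               class = "ommatidics_degenerate_geometry")
  expect_error(visual_field_span(flat),
               class = "ommatidics_degenerate_geometry")
  pr <- eye_profile(oracle_arc_points(0.5, 0.05, 9), apex_index = 5L)
  expect_error(interommatidial_angle(pr, apex_index = 2, rows_per_step = 3),
               "too close")
})

test_that("replicate averaging combines apex choices and names failures", {
  pr <- eye_profile(oracle_arc_points(0.5, 0.05, 15), apex_index = 8L)
  r <- replicate_dphi(pr, c(7L, 8L, 9L))
  # on a perfect circle all replicates agree
  expect_equal(r$mean_deg, 0.05 * 180 / pi, tolerance = 1e-9)
  expect_equal(length(r$replicates_deg), 3L)
  expect_equal(r$mean_deg, mean(r$replicates_deg))

  # a degenerate replicate is reported with its index
  mix <- rbind(oracle_arc_points(0.5, 0.05, 9),
               cbind(seq(0.6, 1, length.out = 5), -0.3))
  prm <- eye_profile(mix)
  expect_error(replicate_dphi(prm, c(5L, 12L)), "replicate 2")
})

test_that("visual field span equals the generating arc angle", {
  # 100 degrees, even division
  n <- 21L; span <- 100 * pi / 180
  pr <- eye_profile(oracle_arc_points(1, span / (n - 1), n))
  expect_equal(visual_field_span(pr), 100, tolerance = 1e-9)
  # semicircle
  pr180 <- eye_profile(oracle_arc_points(1, pi / 20, 21L))
  expect_equal(visual_field_span(pr180), 180, tolerance = 1e-9)
  # the widest observed pale-species span regime
  pr128 <- eye_profile(oracle_arc_points(0.4, 128 * pi / 180 / 18, 19L))
  expect_equal(visual_field_span(pr128), 128, tolerance = 1e-9)
})

test_that("eye parameter is the product of D and the angle in radians", {
  expect_equal(eye_parameter(20, 0.05 * 180 / pi), 1, tolerance = 1e-12)
  expect_equal(eye_parameter(1, 180 / pi), 1, tolerance = 1e-12)
  # species-mean regime: lowest observed rho
  expect_equal(round(eye_parameter(13.71, 3.803), 2), 0.91)
  # degree/radian invariance at the interface
  set.seed(3)
  for (rep in 1:20) {
    D <- runif(1, 5, 30); rad <- runif(1, 0.01, 0.2)
    expect_equal(eye_parameter(D, rad * 180 / pi), D * rad,
                 tolerance = 1e-12)
  }
  expect_error(eye_parameter(0, 1), "positive")
})

test_that("facet area and the derived ratios follow the circular-facet formula", {
  expect_equal(facet_area(2), pi)
  expect_equal(facet_area(0), 0)
  expect_equal(round(facet_area(14.42), 2), 163.31)
  expect_error(facet_area(-1), "nonnegative")

  expect_equal(round(sensitivity_fold(20.81, 14.42), 3), 2.083)
  expect_equal(sensitivity_fold(7, 7), 1)
  expect_equal(round(sensitivity_fold(22.78, 18.49), 3), 1.518)
  # fold is exactly the squared diameter ratio (same areas cancel pi/4)
  expect_equal(sensitivity_fold(20.81, 14.42),
               facet_area(20.81) / facet_area(14.42), tolerance = 1e-12)

  expect_equal(round(diameter_ratio(20.81, 14.42), 2), 1.44)
  expect_equal(round(diameter_ratio(17.76, 13.42), 2), 1.32)
  expect_equal(diameter_ratio(5, 5), 1)
  expect_error(diameter_ratio(1, 0), "nonzero")
})

test_that("relative eye size, regional D, and centroid D are simple means/ratios", {
  expect_equal(round(relative_eye_size(0.0662, 2.0), 4), 0.0331)
  expect_equal(relative_eye_size(0, 2), 0)
  expect_equal(relative_eye_size(0.05, 1), 0.05)
  expect_error(relative_eye_size(0.05, 0), "positive")

  expect_equal(regional_facet_diameter(60), 20)
  expect_equal(regional_facet_diameter(0.0633, 1000), 21.1)
  expect_error(regional_facet_diameter(-1), "positive")

  expect_equal(centroid_facet_diameter(c(20, 20, 20, 20)), 20)
  expect_equal(centroid_facet_diameter(c(19, 20, 21, 22)), 20.5)
  expect_error(centroid_facet_diameter(c(19, 20, 21)), "exactly 4")
})

test_that("measure_eye assembles a consistent optics summary", {
  sim <- synth_eye_profile(eye_sim_spec(radius_R = 0.5, facet_pitch = 0.02,
                                        span_deg = 100))
  res <- measure_eye(sim$profile, D_um = 20,
                     apex_indices = sim$profile$apex_index + (-1:1))
  expect_equal(res$dphi_deg, sim$truth$dphi_deg, tolerance = 1e-9)
  expect_equal(res$span_deg, sim$truth$span_deg, tolerance = 1e-9)
  expect_equal(res$eye_parameter_rho,
               res$D_um * res$dphi_deg * pi / 180, tolerance = 1e-12)
  expect_equal(res$facet_area_um2, pi / 4 * res$D_um^2, tolerance = 1e-12)
})
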