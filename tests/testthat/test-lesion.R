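test_that("threshold-crossing depth is exact on a synthetic linear profile", {
  d <- seq(0.25, 4, by = 0.25)
  e <- 536 * (1 - d / 4) # crosses 268 V/cm at exactly 2 mm
  expect_equal(pfasim:::depth_from_profile(d, e, 268), 2, tolerance = 1e-12)
  # no sample above threshold -> depth 0
  expect_identical(pfasim:::depth_from_profile(d, e, 1e6), 0)
  # threshold below every sample -> deepest sampled depth (E > 0 everywhere)
  e_pos <- 536 * (1 - d / 5)
  expect_identical(pfasim:::depth_from_profile(d, e_pos, 1e-6), 4)
})

test_that("sub-voxel interpolation locates a smooth crossing to better than a tenth of the spacing", {
  h <- 0.25
  d <- seq(h, 6, by = h)
  e <- 600 * exp(-d)
  true_depth <- log(600 / 268)
  expect_lt(abs(pfasim:::depth_from_profile(d, e, 268) - true_depth), h / 10)
})

test_that("lesion depth is monotone in voltage and zero below onset", {
  fm <- test_field()
  v <- seq(100, 2500, by = 200)
  depths <- vapply(v, function(vv) lesion_depth_at(fm, vv)$depth_mm, numeric(1))
  expect_true(all(diff(depths) >= 0))
  expect_identical(lesion_depth_at(fm, 1)$depth_mm, 0) # 1 V cannot electroporate
  expect_identical(lesion_depth_at(fm, 1)$lesion_voxel_count, 0L)
  expect_gt(depths[length(depths)], 0)
})

test_that("depth is invariant under joint voltage/threshold scaling", {
  fm <- test_field()
  for (cc in c(0.5, 2, 7.3)) {
    expect_equal(lesion_depth_at(fm, 800, ire_threshold(268))$depth_mm,
                 lesion_depth_at(fm, cc * 800, ire_threshold(cc * 268))$depth_mm,
                 tolerance = 1e-12)
  }
})

test_that("sweep by field scaling matches per-voltage re-solves", {
  fm <- test_field(tolerance = 1e-10)
  g <- fm$grid
  cf <- assign_materials(g, material_table(sigma_blood = 0.7,
                                           sigma_myocardium = 0.2))
  for (v in c(500, 1500)) {
    scaled <- lesion_depth_at(fm, v)$depth_mm
    direct <- extract_lesion_depth(
      solve_potential(g, cf, solve_config(v, tolerance = 1e-10)))$depth_mm
    expect_gt(scaled, 0)
    expect_lt(abs(scaled - direct) / direct, 0.005)
  }
})

test_that("voltage sweeps carry the dose grid and respect monotonicity", {
  fm <- test_field()
  tab <- run_voltage_sweep(test_spec(), thr = ire_threshold(), fm_norm = fm)
  expect_identical(nrow(tab), 13L)
  expect_identical(tab$voltage_V, seq(100, 2500, by = 200))
  expect_true(all(tab$elevation_mm == 0))
  expect_true(all(diff(tab$depth_mm) >= 0))
})

test_that("lesion depth decreases as the catheter is lifted off the tissue", {
  d <- vapply(c(0, 2, 4), function(e)
    lesion_depth_at(test_field(elevation = e), 1500)$depth_mm, numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("the minimum-voltage search is consistent with the depth curve", {
  fm <- test_field()
  v <- min_voltage_for_depth(2, fm_norm = fm)
  expect_gte(lesion_depth_at(fm, v)$depth_mm, 2)
  expect_lt(lesion_depth_at(fm, v - 100)$depth_mm, 2)
  # strict search: depth must exceed the target, not merely reach it
  vs <- min_voltage_for_depth(1, strict = TRUE, fm_norm = fm)
  expect_gt(lesion_depth_at(fm, vs)$depth_mm, 1)
  # unreachable target reports why
  out <- min_voltage_for_depth(50, fm_norm = fm)
  expect_true(is.na(out))
  expect_identical(attr(out, "reason"), "not achievable <= cap")
})

test_that("calibration tunes the conductivity ratio to an anchor depth on a coarse grid", {
  # anchor chosen inside the reachable depth range of this coarse grid
  cal <- suppressWarnings(calibrate_conductivity_ratio(
    anchor_voltage = 500, anchor_depth = 2.3, spacing = 0.5,
    extents = c(24, 24, 16), tissue_depth = 8, tolerance = 1e-8))
  expect_s3_class(cal, "calibration")
  expect_gt(cal$ratio, 1); expect_lt(cal$ratio, 10)
  expect_lt(cal$residual_mm, 0.1)
  expect_equal(cal$sigma_blood, cal$ratio * cal$sigma_myocardium,
               tolerance = 1e-12)
  # the returned field really is the calibrated one
  expect_equal(lesion_depth_at(cal$field, 500)$depth_mm, cal$depth_at_anchor,
               tolerance = 1e-12)
  # an impossible anchor is a calibration failure, not a silent answer
  expect_error(suppressWarnings(calibrate_conductivity_ratio(
    anchor_voltage = 500, anchor_depth = 30, spacing = 0.5,
    extents = c(24, 24, 16), tissue_depth = 8, tolerance = 1e-6,
    max_solves = 6)), "calibration failure")
})

test_that("t-based confidence intervals reproduce the printed in-vivo bounds", {
  ci1 <- confidence_interval(2.25, 0.85, 6)
  expect_equal(unname(ci1), c(1.35, 3.14), tolerance = 0.01)
  ci2 <- confidence_interval(6.5, 1.7, 4)
  expect_equal(unname(ci2), c(3.8, 9.2), tolerance = 0.01)
  expect_error(confidence_interval(1, 1, 1), "domain error")
})

test_that("in-vivo validation reports nearest-percent errors and CI membership", {
  val <- validate_against_invivo(data.frame(voltage_V = c(500, 2200),
                                            depth_mm = c(2.28, 6.16)))
  expect_identical(val$percent_error, c(1L, 5L))
  expect_true(all(val$within_ci))
  expect_error(validate_against_invivo(data.frame(voltage_V = 500,
                                                  depth_mm = 2.28)),
               "lookup error")
})

test_that("threshold and lesion inputs are validated", {
  expect_error(ire_threshold(0), "domain error")
  expect_error(ire_threshold(c(1, 2)), "domain error")
  g <- capacitor_grid(16, 0.5) # no tissue anywhere
  cf <- assign_materials(g, material_table(sigma_blood = 0.7,
                                           sigma_myocardium = 0.7))
  fm <- solve_potential(g, cf, solve_config(30, tolerance = 1e-8))
  expect_error(extract_lesion_depth(fm), "precondition error")
})
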