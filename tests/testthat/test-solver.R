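codes <- region_codes()

test_that("parallel-plate field is uniform with |E| = V/g", {
  g <- capacitor_grid(24, 0.5)
  cf <- assign_materials(g, material_table(sigma_blood = 0.7,
                                           sigma_myocardium = 0.7))
  fm <- solve_potential(g, cf, solve_config(30, tolerance = 1e-10))
  e_expect <- 30 / (g$gap_mm / 10) # V/cm
  interior <- fm$Emag[, , 3:22]
  expect_lt(max(abs(interior - e_expect)) / e_expect, 0.01)
  # phi linear in z: second differences vanish
  col <- fm$phi[12, 12, ]
  expect_lt(max(abs(diff(diff(col[2:23])))), 1e-6)
})

test_that("potential respects the discrete maximum principle and electrode Dirichlet values", {
  fm <- test_field()
  V <- fm$voltage
  expect_lte(max(fm$phi, na.rm = TRUE), V / 2 + 1e-9)
  expect_gte(min(fm$phi, na.rm = TRUE), -V / 2 - 1e-9)
  g <- fm$grid
  expect_true(all(fm$phi[g$region == codes[["ELECTRODE_POS"]]] == V / 2))
  expect_true(all(fm$phi[g$region == codes[["ELECTRODE_NEG"]]] == -V / 2))
  expect_true(all(fm$Emag >= 0, na.rm = TRUE))
})

test_that("solution scales linearly with applied voltage", {
  g <- test_grid(spacing = 0.5)
  cf <- assign_materials(g, material_table())
  f1 <- solve_potential(g, cf, solve_config(100, tolerance = 1e-10))
  f2 <- solve_potential(g, cf, solve_config(200, tolerance = 1e-10))
  expect_lt(max(abs(f2$phi - 2 * f1$phi), na.rm = TRUE), 200 * 1e-7)
  rel <- abs(f2$Emag - 2 * f1$Emag) / pmax(2 * f1$Emag, 1e-9)
  expect_lt(max(rel, na.rm = TRUE), 1e-5)
})

test_that("potential is antisymmetric about the midplane and field symmetric about the frontal plane", {
  fm <- test_field()
  d <- fm$grid$dims
  phi <- fm$phi
  mir <- phi[d[1]:1, , ]
  expect_lt(max(abs(phi + mir), na.rm = TRUE), fm$voltage * 1e-5)
  e <- fm$Emag
  expect_lt(max(abs(e - e[, d[2]:1, ]), na.rm = TRUE), max(e, na.rm = TRUE) * 1e-4)
})

test_that("current leaving the anode equals current entering the cathode", {
  cur <- electrode_currents(test_field())
  expect_lt(cur$imbalance, 0.01)
  expect_gt(cur$I_pos, 0)
  expect_lt(cur$I_neg, 0)
})

test_that("centerline field profile decays with depth and scales with voltage", {
  fm <- test_field()
  p <- centerline_profile(fm)
  expect_true(all(p$depth_mm > 0))
  expect_false(is.unsorted(p$depth_mm))
  beyond <- p$E_Vcm[p$depth_mm >= 1]
  expect_true(all(diff(beyond) < 0))
  # linearity: doubling the voltage doubles the profile pointwise
  g <- fm$grid
  cf <- assign_materials(g, material_table())
  f2 <- solve_potential(g, cf, solve_config(2, tolerance = 1e-10))
  p2 <- centerline_profile(f2)
  expect_equal(p2$E_Vcm / p$E_Vcm, rep(2, nrow(p)), tolerance = 1e-4)
})

test_that("grounded and insulated far boundaries give nearly the same mid-depth field", {
  # at the production extents the outer-boundary choice is a few-percent
  # effect on the mid-depth centerline field
  fi <- test_field(extents = c(40, 40, 35), tissue_depth = 15)
  fg <- test_field(extents = c(40, 40, 35), tissue_depth = 15,
                   far_boundary = "grounded")
  e3i <- approx(centerline_profile(fi)$depth_mm, centerline_profile(fi)$E_Vcm, 3)$y
  e3g <- approx(centerline_profile(fg)$depth_mm, centerline_profile(fg)$E_Vcm, 3)$y
  expect_lt(abs(e3i - e3g) / e3i, 0.05)
})

test_that("solver failure modes are reported", {
  g <- test_grid(spacing = 0.5)
  cf <- assign_materials(g, material_table())
  expect_error(solve_potential(g, cf, solve_config(100, max_iterations = 2)),
               "solver error")
  expect_error(solve_config(0), "voltage")
  expect_error(solve_config(100, tolerance = 0.01), "tolerance")
  fm <- solve_potential(g, cf, solve_config(10, tolerance = 1e-6),
                        compute_field = FALSE)
  expect_error(centerline_profile(fm), "state error")
})

test_that("a warm start converges to the same solution in fewer iterations", {
  g <- test_grid(spacing = 0.5)
  cfg <- solve_config(100, tolerance = 1e-10)
  f1 <- solve_potential(g, assign_materials(
    g, material_table(sigma_blood = 0.7, sigma_myocardium = 0.2)), cfg)
  cf2 <- assign_materials(g, material_table(sigma_blood = 0.75,
                                            sigma_myocardium = 0.2))
  cold <- solve_potential(g, cf2, cfg)
  warm <- solve_potential(g, cf2, cfg, x0 = f1$phi)
  expect_lt(warm$iterations, cold$iterations)
  expect_lt(max(abs(warm$phi - cold$phi), na.rm = TRUE), 100 * 1e-7)
})
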