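# compact configuration used by the end-to-end experiment tests
small_cfg <- function(experiment = "voltage_sweep") {
  cfg <- default_config()
  cfg$grid <- list(spacing_mm = 0.5, extents_mm = c(24, 24, 16),
                   tissue_depth_mm = 8)
  cfg$solve$tolerance <- 1e-7
  cfg$lesion$elevations_mm <- c(0, 2)
  cfg$lesion$contact_voltages_V <- 1200
  cfg$lesion$combined_voltages_V <- c(500, 1500, 2500)
  cfg$experiment <- experiment
  cfg
}

test_that("configurations round-trip through YAML with defaults filled in", {
  path <- tempfile(fileext = ".yaml")
  write_config(list(catheter = list(elevation_mm = 3),
                    experiment = "contact_sweep"), path)
  cfg <- read_config(path)
  expect_identical(cfg$catheter$elevation_mm, 3)
  expect_identical(cfg$catheter$electrode_gap_mm, 4) # default preserved
  expect_identical(cfg$experiment, "contact_sweep")
  expect_identical(cfg$lesion$ire_threshold_Vcm, 268)
})

test_that("invalid configurations are rejected with a validation error", {
  cfg <- default_config()
  cfg$experiment <- "banana"
  expect_error(validate_config(cfg), "validation error")
  cfg2 <- default_config()
  cfg2$catheter$elevation_mm <- -1
  expect_error(validate_config(cfg2), "validation error")
  cfg3 <- default_config()
  cfg3$lesion$ire_threshold_Vcm <- 0
  expect_error(validate_config(cfg3), "validation error")
})

test_that("a voltage-sweep run writes the full dose table and a run record", {
  outdir <- tempfile("sweep")
  rec <- suppressWarnings(run_experiment(small_cfg(), outdir))
  csv <- file.path(outdir, "voltage_sweep.csv")
  expect_true(file.exists(csv))
  tab <- read.csv(csv)
  expect_identical(nrow(tab), 13L)
  expect_identical(tab$voltage_V, seq(100L, 2500L, by = 200L))
  expect_true(all(diff(tab$depth_mm) >= 0))
  rr <- jsonlite::read_json(file.path(outdir, "run_record.json"))
  expect_identical(rr$config$experiment, "voltage_sweep")
  expect_true(rr$solves$voltage_sweep$iterations > 0)
})

test_that("identical configurations reproduce byte-identical sweep output", {
  d1 <- tempfile("rep1"); d2 <- tempfile("rep2")
  suppressWarnings(run_experiment(small_cfg(), d1))
  suppressWarnings(run_experiment(small_cfg(), d2))
  f1 <- file.path(d1, "voltage_sweep.csv")
  f2 <- file.path(d2, "voltage_sweep.csv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("a contact-sweep run covers every requested elevation", {
  outdir <- tempfile("contact")
  suppressWarnings(run_experiment(small_cfg("contact_sweep"), outdir))
  tab <- read.csv(file.path(outdir, "contact_sweep_1200V.csv"))
  expect_identical(tab$elevation_mm, c(0L, 2L))
  expect_true(all(tab$voltage_V == 1200))
  expect_true(all(diff(tab$depth_mm) <= 0)) # deeper at contact
})

test_that("a combined run produces the full voltage x elevation grid", {
  outdir <- tempfile("combined")
  suppressWarnings(run_experiment(small_cfg("combined"), outdir))
  tab <- read.csv(file.path(outdir, "combined_grid.csv"))
  expect_identical(nrow(tab), 6L) # 3 voltages x 2 elevations
  expect_identical(sort(unique(tab$voltage_V)), c(500L, 1500L, 2500L))
  expect_identical(sort(unique(tab$elevation_mm)), c(0L, 2L))
})

test_that("the analytic-verification experiment writes a passing comparison", {
  outdir <- tempfile("analytic")
  run_experiment(small_cfg("verify_analytic"), outdir)
  cmp <- read.csv(file.path(outdir, "analytic_verification.csv"))
  band <- cmp$y_mm >= 2 & cmp$y_mm <= 10
  expect_lt(max(cmp$relative_error[band]), 0.05)
})

test_that("VTK exports are legacy ASCII structured points", {
  outdir <- tempfile("vtk")
  suppressWarnings(run_experiment(small_cfg(), outdir, export_vtk = TRUE))
  lines <- readLines(file.path(outdir, "field.vtk"), n = 12)
  expect_match(lines[1], "^# vtk DataFile Version")
  expect_identical(lines[3], "ASCII")
  expect_identical(lines[4], "DATASET STRUCTURED_POINTS")
  expect_match(lines[5], "^DIMENSIONS 48 48 32$")
  expect_true(any(grepl("^SCALARS region int", lines)))
})

test_that("fixture generation writes small analytic cases and rejects misuse", {
  dir <- tempfile("fixtures")
  for (kind in c("capacitor", "point_charges", "linear_profile")) {
    paths <- make_fixture(kind, size = 24, dir = dir)
    expect_true(all(file.exists(paths)))
    expect_true(all(file.size(paths) <= 64 * 1024))
  }
  # capacitor fixture: the solver must reproduce the expected ramp
  exp_tab <- read.csv(file.path(dir, "capacitor_expected.csv"))
  g <- capacitor_grid(24, 0.5)
  cf <- assign_materials(g, material_table(sigma_blood = 0.7,
                                           sigma_myocardium = 0.7))
  fm <- solve_potential(g, cf, solve_config(30, tolerance = 1e-10))
  expect_equal(fm$phi[12, 12, ], exp_tab$phi_V, tolerance = 1e-6)
  expect_error(make_fixture("banana", dir = dir), "usage error")
  expect_error(make_fixture("capacitor", size = 128, dir = dir), "usage error")
})
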