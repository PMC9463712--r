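#' Default experiment configuration
#'
#' Nested configuration covering the catheter, grid, materials, solver and
#' lesion sections, serializable to YAML via [write_config()]. The defaults
#' are the study conditions: 2 mm electrodes with a 4 mm gap on a 2.3 mm
#' shaft, a 40 x 40 x 35 mm domain (15 mm tissue) at 0.25 mm pitch, a
#' 268 V/cm IRE threshold and a 100-2500 V dose range.
#'
#' @return A named list of sections.
#' @export
default_config <- function() {
  list(
    catheter = list(electrode_length_mm = 2, electrode_gap_mm = 4,
                    diameter_mm = 2.3, elevation_mm = 0),
    grid = list(spacing_mm = 0.25, extents_mm = c(40, 40, 35),
                tissue_depth_mm = 15),
    materials = list(sigma_blood_Sm = 0.70, sigma_myocardium_Sm = 0.20,
                     eps_r_blood = 5200, eps_r_myocardium = 9800,
                     temp_coefficient_perC = 0.015,
                     physics_mode = "conduction"),
    solve = list(tolerance = 1e-8, max_iterations = 50000,
                 far_boundary = "insulated"),
    lesion = list(ire_threshold_Vcm = 268, voltage_cap_V = 2500,
                  search_step_V = 100,
                  voltages_V = seq(100, 2500, by = 200),
                  elevations_mm = 0:5,
                  contact_voltages_V = c(700, 1200),
                  combined_voltages_V = c(100, 500, 1000, 1500, 2000, 2500)),
    experiment = "voltage_sweep"
  )
}

#' Read an experiment configuration
#'
#' Reads a YAML configuration and fills unspecified entries from
#' [default_config()].
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- utils::modifyList(default_config(), yaml::read_yaml(path))
  validate_config(cfg)
  cfg
}

#' Write an experiment configuration
#'
#' @param cfg Configuration list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

validate_config <- function(cfg) {
  known <- c("voltage_sweep", "contact_sweep", "combined", "validate",
             "verify_analytic")
  if (!cfg$experiment %in% known)
    stop(sprintf("validation error: unknown experiment '%s' (use one of %s)",
                 cfg$experiment, paste(known, collapse = ", ")))
  ct <- cfg$catheter
  if (ct$electrode_length_mm <= 0 || ct$electrode_gap_mm <= 0 ||
      ct$diameter_mm <= 0 || ct$elevation_mm < 0)
    stop("validation error: invalid [catheter] section")
  if (cfg$grid$spacing_mm <= 0 || length(cfg$grid$extents_mm) != 3)
    stop("validation error: invalid [grid] section")
  if (cfg$materials$sigma_blood_Sm <= 0 || cfg$materials$sigma_myocardium_Sm <= 0)
    stop("validation error: invalid [materials] section")
  if (cfg$lesion$ire_threshold_Vcm <= 0)
    stop("validation error: IRE threshold must be > 0")
  invisible(cfg)
}

cfg_spec <- function(cfg, elevation = cfg$catheter$elevation_mm) {
  catheter_spec(cfg$catheter$electrode_length_mm, cfg$catheter$electrode_gap_mm,
                cfg$catheter$diameter_mm, elevation)
}

cfg_table <- function(cfg) {
  m <- cfg$materials
  material_table(sigma_blood = m$sigma_blood_Sm,
                 sigma_myocardium = m$sigma_myocardium_Sm,
                 eps_r_blood = m$eps_r_blood,
                 eps_r_myocardium = m$eps_r_myocardium,
                 temp_coefficient = m$temp_coefficient_perC,
                 physics_mode = m$physics_mode)
}

cfg_norm_args <- function(cfg) {
  list(table = cfg_table(cfg),
       spacing = cfg$grid$spacing_mm,
       extents = cfg$grid$extents_mm,
       tissue_depth = cfg$grid$tissue_depth_mm,
       tolerance = cfg$solve$tolerance,
       max_iterations = cfg$solve$max_iterations,
       far_boundary = cfg$solve$far_boundary)
}

write_sweep_csv <- function(tab, path) {
  utils::write.csv(
    data.frame(voltage_V = tab$voltage_V,
               elevation_mm = tab$elevation_mm,
               depth_mm = round(tab$depth_mm, 6)),
    path, row.names = FALSE, quote = FALSE)
  path
}

#' Run a configured experiment
#'
#' Dispatches on `cfg$experiment` and writes the experiment's CSV/JSON/VTK
#' outputs into `outdir`. Outputs are deterministic: re-running with an
#' identical configuration reproduces identical CSV bytes.
#'
#' @param cfg Configuration from [default_config()]/[read_config()].
#' @param outdir Output directory (created if needed).
#' @param export_vtk If `TRUE`, also export region/phi/Emag VTK volumes for
#'   the primary solve of the experiment.
#' @return A `run_record` (config snapshot, package version, timestamps,
#'   output manifest, solver diagnostics), also written to
#'   `run_record.json`.
#' @export
run_experiment <- function(cfg, outdir, export_vtk = FALSE) {
  validate_config(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  outputs <- character(0)
  solves <- list()
  na <- cfg_norm_args(cfg)
  thr <- ire_threshold(cfg$lesion$ire_threshold_Vcm)

  note_solve <- function(fm, label)
    solves[[label]] <<- list(iterations = fm$iterations, relres = fm$relres,
                             voltage = fm$voltage)

  if (cfg$experiment == "voltage_sweep") {
    spec <- cfg_spec(cfg)
    fm <- do.call(normalized_field, c(list(spec = spec), na))
    note_solve(fm, "voltage_sweep")
    tab <- run_voltage_sweep(spec, cfg$lesion$voltages_V, thr, fm_norm = fm)
    outputs <- c(outputs, write_sweep_csv(tab, file.path(outdir, "voltage_sweep.csv")))
    if (export_vtk)
      outputs <- c(outputs, write_vtk_structured_points(
        file.path(outdir, "field.vtk"), fm$grid,
        region = fm$grid$region, phi = fm$phi, Emag = fm$Emag))
  } else if (cfg$experiment == "contact_sweep") {
    for (v in cfg$lesion$contact_voltages_V) {
      tab <- do.call(run_contact_sweep,
                     c(list(spec_base = cfg_spec(cfg),
                            elevations = cfg$lesion$elevations_mm,
                            voltage = v, thr = thr), na))
      outputs <- c(outputs, write_sweep_csv(
        tab, file.path(outdir, sprintf("contact_sweep_%dV.csv", v))))
    }
  } else if (cfg$experiment == "combined") {
    rows <- lapply(cfg$lesion$elevations_mm, function(e) {
      fm <- do.call(normalized_field, c(list(spec = cfg_spec(cfg, e)), na))
      note_solve(fm, sprintf("combined_elev%g", e))
      run_voltage_sweep(cfg_spec(cfg, e), cfg$lesion$combined_voltages_V,
                        thr, fm_norm = fm)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$voltage_V, tab$elevation_mm), ]
    outputs <- c(outputs, write_sweep_csv(tab, file.path(outdir, "combined_grid.csv")))
  } else if (cfg$experiment == "validate") {
    cal <- do.call(calibrate_conductivity_ratio,
                   c(list(spec = cfg_spec(cfg), thr = thr,
                          sigma_myocardium = cfg$materials$sigma_myocardium_Sm),
                     na[setdiff(names(na), "table")]))
    note_solve(cal$field, "calibrated")
    ref <- invivo_reference()
    md <- data.frame(
      voltage_V = ref$voltage_V,
      depth_mm = vapply(ref$voltage_V, function(v)
        lesion_depth_at(cal$field, v, thr)$depth_mm, numeric(1)))
    val <- validate_against_invivo(md, ref)
    p <- file.path(outdir, "validation.json")
    jsonlite::write_json(list(calibration = list(ratio = cal$ratio,
                                                 residual_mm = cal$residual_mm),
                              validation = val),
                         p, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, p)
  } else if (cfg$experiment == "verify_analytic") {
    # box much larger than the 5a comparison band: the closed form assumes an
    # unbounded medium and truncation error scales like (y/L)^2
    g <- point_charge_grid(a = 2, spacing = 0.5, extents = c(56, 60, 56))
    cmp <- verify_solver_against_point_charges(g, tolerance = 1e-7)
    p <- file.path(outdir, "analytic_verification.csv")
    utils::write.csv(cmp, p, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, p)
  }

  rec <- structure(list(config = cfg,
                        package_version = as.character(utils::packageVersion("pfasim")),
                        started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                        finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                        outputs = outputs,
                        solves = solves),
                   class = "run_record")
  jsonlite::write_json(unclass(rec), file.path(outdir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(rec)
}

#' Generate analytic test fixtures
#'
#' Writes a labeled grid (legacy ASCII VTK) and its expected closed-form
#' solution (CSV) for one of three analytic cases: a parallel-plate
#' capacitor (linear potential ramp), a two-point-charge dipole (analytic
#' field profile), or a synthetic linear centerline field profile with a
#' known threshold-crossing depth.
#'
#' @param kind One of `"capacitor"`, `"point_charges"`, `"linear_profile"`.
#' @param size Voxels per side (<= 64) for the gridded cases.
#' @param dir Output directory.
#' @return Character vector of file paths written.
#' @export
make_fixture <- function(kind = c("capacitor", "point_charges", "linear_profile"),
                         size = 32, dir = ".") {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop(sprintf("usage error: unknown fixture kind '%s'", kind[1])))
  if (size > 64) stop("usage error: fixture size must be <= 64 voxels per side")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (kind == "capacitor") {
    h <- 0.5
    g <- capacitor_grid(size, h)
    V <- 30
    k <- seq_len(size)
    # linear ramp between the electrode inner faces; electrode layers clamped
    phi <- V * ((k - 1.5) / (size - 2) - 0.5)
    phi[1] <- -V / 2; phi[size] <- V / 2
    grid_path <- file.path(dir, "capacitor_grid.vtk")
    write_vtk_structured_points(grid_path, g, region = g$region)
    csv_path <- file.path(dir, "capacitor_expected.csv")
    utils::write.csv(data.frame(z_mm = g$z, phi_V = phi,
                                E_Vcm = V / (g$gap_mm / 10)),
                     csv_path, row.names = FALSE, quote = FALSE)
    c(grid_path, csv_path)
  } else if (kind == "point_charges") {
    a <- 2
    g <- point_charge_grid(a, spacing = a / 8,
                           extents = c(size, size, size) * a / 8)
    grid_path <- file.path(dir, "point_charges_grid.vtk")
    write_vtk_structured_points(grid_path, g, region = g$region)
    y <- seq(g$a_mm, 5 * g$a_mm, by = g$spacing)
    csv_path <- file.path(dir, "point_charges_expected.csv")
    utils::write.csv(
      data.frame(y_mm = y,
                 E_shape = point_charge_field(q = 1, a = g$a_mm * 1e-3,
                                              y = y * 1e-3)),
      csv_path, row.names = FALSE, quote = FALSE)
    c(grid_path, csv_path)
  } else {
    d <- seq(0.25, 4, by = 0.25)
    csv_path <- file.path(dir, "linear_profile.csv")
    utils::write.csv(data.frame(depth_mm = d, E_Vcm = 536 * (1 - d / 4)),
                     csv_path, row.names = FALSE, quote = FALSE)
    exp_path <- file.path(dir, "linear_profile_expected.csv")
    utils::write.csv(data.frame(threshold_Vcm = 268, depth_mm = 2),
                     exp_path, row.names = FALSE, quote = FALSE)
    c(csv_path, exp_path)
  }
}

#' Regenerate the study's summary tables
#'
#' Runs the full experimental protocol: (a) the 100-2500 V dose-depth table,
#' (b) contact sweeps at 700 V and 1200 V, (c) the combined 6-voltage x
#' 6-elevation grid, and (d) the in-vivo validation report, all with the
#' calibrated conductivity ratio.
#'
#' @param outdir Output directory.
#' @param cfg Base configuration (grid/solver settings are taken from it).
#' @param calibration Optional precomputed [calibrate_conductivity_ratio()]
#'   result; if `NULL` and `skip_calibration = FALSE`, calibration is run
#'   first.
#' @param skip_calibration If `TRUE`, use the configuration's material table
#'   as-is.
#' @return List of `run_record`s, invisibly.
#' @export
regenerate_paper_tables <- function(outdir, cfg = default_config(),
                                    calibration = NULL,
                                    skip_calibration = FALSE) {
  validate_config(cfg)
  if (!skip_calibration) {
    if (is.null(calibration)) {
      na <- cfg_norm_args(cfg)
      calibration <- do.call(
        calibrate_conductivity_ratio,
        c(list(spec = cfg_spec(cfg),
               thr = ire_threshold(cfg$lesion$ire_threshold_Vcm),
               sigma_myocardium = cfg$materials$sigma_myocardium_Sm),
          na[setdiff(names(na), "table")]))
    }
    cfg$materials$sigma_blood_Sm <- calibration$sigma_blood
    cfg$materials$sigma_myocardium_Sm <- calibration$sigma_myocardium
  }
  recs <- list()
  for (ex in c("voltage_sweep", "contact_sweep", "combined", "validate")) {
    cfg$experiment <- ex
    recs[[ex]] <- run_experiment(cfg, outdir)
  }
  invisible(recs)
}
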