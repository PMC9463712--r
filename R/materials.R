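#' Per-region electrical material properties
#'
#' Electrical properties for each region of the computational domain. The
#' electrodes are treated as perfect conductors (equipotential Dirichlet
#' regions) and the shaft as a perfect insulator (zero-flux), so neither
#' needs a finite conductivity. Two physics modes share the same Laplace-type
#' solve: `"conduction"` uses conductivities (steady current at the pulse
#' plateau, the default) and `"electrostatic"` uses relative permittivities
#' as the coefficient field; only the blood:myocardium coefficient ratio
#' affects the field pattern.
#'
#' @param sigma_blood Blood conductivity, S/m. Default 0.70.
#' @param sigma_myocardium Myocardial conductivity, S/m. Default 0.20.
#' @param eps_r_blood Blood relative permittivity (electrostatic mode).
#' @param eps_r_myocardium Myocardial relative permittivity (electrostatic mode).
#' @param temp_coefficient Fractional myocardial conductivity change per degree
#'   Celsius, 1/degC. Default 0.015.
#' @param reference_temperature Temperature at which the table values hold, degC.
#' @param physics_mode `"conduction"` or `"electrostatic"`.
#' @return A `material_table` list.
#' @examples
#' material_table()
#' material_table(sigma_blood = 0.6, sigma_myocardium = 0.25)
#' @export
material_table <- function(sigma_blood = 0.70, sigma_myocardium = 0.20,
                           eps_r_blood = 5200, eps_r_myocardium = 9800,
                           temp_coefficient = 0.015,
                           reference_temperature = 37,
                           physics_mode = c("conduction", "electrostatic")) {
  physics_mode <- match.arg(physics_mode)
  if (temp_coefficient < 0) stop("temp_coefficient must be >= 0")
  structure(list(sigma_blood = sigma_blood,
                 sigma_myocardium = sigma_myocardium,
                 eps_r_blood = eps_r_blood,
                 eps_r_myocardium = eps_r_myocardium,
                 temp_coefficient = temp_coefficient,
                 reference_temperature = reference_temperature,
                 physics_mode = physics_mode),
            class = "material_table")
}

# table entry names required for each region label present in a grid
region_requirements <- function(mode) {
  coef <- if (mode == "conduction")
    c(BLOOD = "sigma_blood", MYOCARDIUM = "sigma_myocardium")
  else
    c(BLOOD = "eps_r_blood", MYOCARDIUM = "eps_r_myocardium")
  # electrodes and shaft need no finite coefficient but must be declared
  # regions the solver knows how to handle; they always are.
  coef
}

#' Assign per-voxel electrical coefficients
#'
#' Maps the material table onto the grid's region labels, producing the
#' coefficient field the solver consumes (conductivity in conduction mode,
#' relative permittivity in electrostatic mode). Conductive regions must have
#' a strictly positive coefficient; the shaft is assigned zero (zero-flux)
#' and electrode voxels are Dirichlet nodes whose coefficient is never read.
#' At region interfaces the solver uses harmonic-mean face coefficients.
#'
#' @param grid A `domain_grid`.
#' @param table A [material_table()].
#' @return A `conductivity_field`: per-voxel coefficient array plus the grid
#'   and table it was derived from.
#' @examples
#' g <- build_domain(catheter_spec(), 0.5, c(24, 24, 16), tissue_depth = 8)
#' cf <- assign_materials(g, material_table())
#' range(cf$values[g$region == region_codes()[["BLOOD"]]])
#' @export
assign_materials <- function(grid, table) {
  stopifnot(inherits(grid, "domain_grid"), inherits(table, "material_table"))
  req <- region_requirements(table$physics_mode)
  present <- names(REGION_CODES)[REGION_CODES %in% unique(as.vector(grid$region))]
  for (rg in intersect(present, names(req))) {
    v <- table[[req[[rg]]]]
    if (is.null(v) || length(v) != 1 || is.na(v))
      stop(sprintf("configuration error: material table has no entry for region %s", rg))
    if (v <= 0)
      stop(sprintf("configuration error: coefficient for region %s must be > 0", rg))
  }
  vals <- array(0, dim = grid$dims)
  cb <- table[[req[["BLOOD"]]]]
  cm <- table[[req[["MYOCARDIUM"]]]]
  vals[grid$region == REGION_CODES[["BLOOD"]]] <- cb
  vals[grid$region == REGION_CODES[["MYOCARDIUM"]]] <- cm
  structure(list(values = vals, grid = grid, table = table,
                 mode = table$physics_mode),
            class = "conductivity_field")
}

#' Temperature correction of myocardial conductivity
#'
#' Applies the linear temperature law sigma(T) = sigma0 * (1 + alpha * dT)
#' on myocardial voxels only; blood, shaft and electrodes are untouched.
#' PFA deposits only a rapid temperature burst of a few degrees, so a single
#' multiplicative correction (rather than a coupled bioheat solve) is used.
#'
#' @param field A `conductivity_field` at the reference temperature.
#' @param deltaT Temperature rise, degC: a scalar or a per-voxel array
#'   matching the grid dimensions. Must be finite.
#' @param alpha Fractional conductivity change per degC (>= 0). Defaults to
#'   the table's `temp_coefficient`.
#' @return A new `conductivity_field` with scaled myocardial values.
#' @examples
#' g <- build_domain(catheter_spec(), 0.5, c(24, 24, 16), tissue_depth = 8)
#' cf <- assign_materials(g, material_table())
#' cf2 <- temperature_update(cf, deltaT = 2)  # sigma_myo scaled by 1.03
#' @export
temperature_update <- function(field, deltaT, alpha = NULL) {
  stopifnot(inherits(field, "conductivity_field"))
  if (is.null(alpha)) alpha <- field$table$temp_coefficient
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0)
    stop("alpha must be a single number >= 0")
  if (!all(is.finite(deltaT))) stop("deltaT must be finite")
  myo <- field$grid$region == REGION_CODES[["MYOCARDIUM"]]
  if (length(deltaT) == 1) {
    fac <- 1 + alpha * deltaT
    if (fac <= 0)
      stop("physical-validity error: alpha * deltaT <= -1 gives non-positive conductivity")
    field$values[myo] <- field$values[myo] * fac
  } else {
    if (!all(dim(deltaT) == field$grid$dims))
      stop("deltaT array must match the grid dimensions")
    fac <- 1 + alpha * deltaT[myo]
    if (any(fac <= 0))
      stop("physical-validity error: alpha * deltaT <= -1 gives non-positive conductivity")
    field$values[myo] <- field$values[myo] * fac
  }
  field
}
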