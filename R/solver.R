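#' Field-solve configuration
#'
#' @param voltage Applied inter-electrode potential difference, V (> 0). The
#'   solve splits it symmetrically: +V/2 on the positive electrode, -V/2 on
#'   the negative (bipolar delivery between the pair).
#' @param far_boundary Outer-boundary condition: `"insulated"` (zero flux,
#'   default) or `"grounded"` (phi = 0 half a cell outside the boundary).
#' @param tolerance Relative residual stopping criterion, in (0, 1e-3].
#'   Default 1e-8.
#' @param max_iterations Conjugate-gradient iteration cap.
#' @return A `solve_config` list.
#' @export
solve_config <- function(voltage, far_boundary = c("insulated", "grounded"),
                         tolerance = 1e-8, max_iterations = 50000L) {
  far_boundary <- match.arg(far_boundary)
  stopifnot(is.numeric(voltage), length(voltage) == 1)
  if (voltage <= 0) stop("voltage must be > 0")
  if (tolerance <= 0 || tolerance > 1e-3)
    stop("tolerance must lie in (0, 1e-3]")
  structure(list(voltage = voltage, far_boundary = far_boundary,
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "solve_config")
}

#' Solve the potential equation on a labeled grid
#'
#' Solves the discrete steady-current equation div(sigma grad phi) = 0 with a
#' finite-volume 7-point stencil (harmonic-mean face coefficients) and
#' Jacobi-preconditioned conjugate gradients. Electrode voxels are Dirichlet
#' nodes at +V/2 / -V/2; shaft voxels and (by default) the outer boundary are
#' zero-flux, so the field is parallel to insulating surfaces.
#'
#' @param grid A `domain_grid`.
#' @param sigma A `conductivity_field` from [assign_materials()].
#' @param cfg A [solve_config()].
#' @param compute_field If `TRUE` (default), also fill the field-magnitude
#'   array via [field_magnitude()].
#' @param x0 Optional initial guess for the potential (an array matching the
#'   grid, e.g. the `phi` of a previous solve on the same grid); cuts
#'   iteration counts when re-solving after a small conductivity change.
#' @return A `field_map`: `phi` (volts, `NA` on shaft voxels), `Emag`
#'   (V/cm, if computed), the grid, the applied voltage, and solver
#'   diagnostics (`iterations`, `relres`).
#' @examples
#' g  <- build_domain(catheter_spec(), 0.5, c(24, 24, 16), tissue_depth = 8)
#' cf <- assign_materials(g, material_table())
#' fm <- solve_potential(g, cf, solve_config(voltage = 500, tolerance = 1e-6))
#' max(fm$Emag[g$region == region_codes()[["MYOCARDIUM"]]])
#' @export
solve_potential <- function(grid, sigma, cfg, compute_field = TRUE, x0 = NULL) {
  stopifnot(inherits(grid, "domain_grid"),
            inherits(sigma, "conductivity_field"),
            inherits(cfg, "solve_config"))
  if (!all(dim(sigma$values) == grid$dims))
    stop("conductivity field does not match the grid")
  res <- fv_solve_cpp(as.integer(grid$region), as.double(sigma$values),
                      as.integer(grid$dims),
                      v_pos = cfg$voltage / 2, v_neg = -cfg$voltage / 2,
                      tol = cfg$tolerance, maxit = cfg$max_iterations,
                      grounded = cfg$far_boundary == "grounded",
                      x0 = if (is.null(x0)) NULL else as.double(x0))
  if (!res$converged)
    stop(sprintf("solver error: no convergence in %d iterations (relative residual %.3g)",
                 res$iterations, res$relres))
  fm <- structure(list(phi = array(res$phi, dim = grid$dims),
                       Emag = NULL, grid = grid, sigma = sigma,
                       voltage = cfg$voltage,
                       far_boundary = cfg$far_boundary,
                       iterations = res$iterations, relres = res$relres),
                  class = "field_map")
  if (compute_field) fm <- field_magnitude(fm) else fm
}

#' Electric-field magnitude from the solved potential
#'
#' Fills `Emag` (V/cm) as the magnitude of the central-difference gradient of
#' `phi`, with one-sided differences at region boundaries and the domain
#' edge. Shaft voxels get `NA`.
#'
#' @param fm A `field_map` with `phi` solved.
#' @return The `field_map` with `Emag` filled.
#' @export
field_magnitude <- function(fm) {
  stopifnot(inherits(fm, "field_map"))
  if (is.null(fm$phi)) stop("state error: potential not solved")
  e <- fv_gradient_cpp(as.double(fm$phi), as.integer(fm$grid$region),
                       as.integer(fm$grid$dims), fm$grid$spacing)
  fm$Emag <- array(e, dim = fm$grid$dims)
  fm
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("field_map: V = %g V, %d x %d x %d voxels, %d CG iterations (relres %.2g)\n",
              x$voltage, x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              x$iterations, x$relres))
  invisible(x)
}

# the 2 x 2 block of grid columns nearest the (x = 0, y = 0) centerline
centerline_columns <- function(grid) {
  nx <- grid$dims[1]; ny <- grid$dims[2]
  list(i = c(nx / 2, nx / 2 + 1), j = c(ny / 2, ny / 2 + 1))
}

#' Field profile down the inter-electrode centerline
#'
#' Samples the field magnitude along the vertical line through the midpoint
#' between the electrodes, from the endocardial surface down into the
#' tissue, at grid spacing. The four voxel columns adjacent to the exact
#' (x = 0, y = 0) centerline are averaged (they are equal up to solver
#' tolerance by symmetry).
#'
#' @param fm A `field_map` with `Emag` computed.
#' @return A data frame with `depth_mm` (> 0, increasing) and `E_Vcm`.
#' @export
centerline_profile <- function(fm) {
  stopifnot(inherits(fm, "field_map"))
  if (is.null(fm$Emag)) stop("state error: field magnitude not computed")
  g <- fm$grid
  cc <- centerline_columns(g)
  kz <- which(g$z < g$surface_z)
  prof <- rowMeans(sapply(cc$i, function(i)
    rowMeans(sapply(cc$j, function(j) fm$Emag[i, j, kz]))))
  d <- g$surface_z - g$z[kz]
  ord <- order(d)
  data.frame(depth_mm = d[ord], E_Vcm = prof[ord])
}

#' Net electrode currents (conduction mode)
#'
#' Total current leaving the positive electrode and entering the negative
#' electrode through their faces, in amperes. In a converged solve the two
#' balance (charge conservation).
#'
#' @param fm A `field_map` solved in conduction mode.
#' @return List with `I_pos`, `I_neg` (A) and `imbalance`, the relative
#'   mismatch |I_pos + I_neg| / |I_pos|.
#' @export
electrode_currents <- function(fm) {
  stopifnot(inherits(fm, "field_map"))
  phi <- fm$phi
  phi[is.na(phi)] <- 0 # shaft voxels carry no current anyway
  res <- fv_electrode_current_cpp(as.double(phi),
                                  as.integer(fm$grid$region),
                                  as.double(fm$sigma$values),
                                  as.integer(fm$grid$dims),
                                  v_pos = fm$voltage / 2,
                                  v_neg = -fm$voltage / 2,
                                  spacing_mm = fm$grid$spacing)
  list(I_pos = res$I_pos, I_neg = res$I_neg,
       imbalance = abs(res$I_pos + res$I_neg) / abs(res$I_pos))
}
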