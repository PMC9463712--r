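#' Closed-form field of two opposite point charges
#'
#' Field magnitude on the perpendicular bisector of a pair of opposite point
#' charges +q and -q separated by 2a:
#' \deqn{E(y) = \frac{2 k q a}{(a^2 + y^2)^{3/2}}}
#' in V/m (equivalently N/C). This is the analytic verification oracle for
#' the numerical solver: a bipolar electrode pair reduces to this dipole
#' limit as the electrodes shrink to points.
#'
#' @param q Charge magnitude, C.
#' @param a Half the charge separation, m (> 0).
#' @param y Distance along the perpendicular bisector, m (vectorized).
#' @param k Coulomb proportionality constant, N m^2 / C^2.
#' @return Field magnitude in V/m. Divide by 100 for V/cm.
#' @examples
#' point_charge_field(q = 1e-9, a = 0.01, y = 0)    # = 2kq/a^2
#' point_charge_field(q = 1e-9, a = 0.01, y = 0.02)
#' @export
point_charge_field <- function(q, a, y, k = 8.9875517873681764e9) {
  if (!is.numeric(a) || length(a) != 1 || a <= 0)
    stop("domain error: a must be a single value > 0")
  if (k <= 0) stop("domain error: k must be > 0")
  2 * k * q * a / (a^2 + y^2)^1.5
}

#' Homogeneous grid with two point-like electrodes
#'
#' Builds an all-blood (single-material) domain with two single-voxel
#' electrodes on the x axis at the voxel centres nearest +/- a, used for the
#' analytic dipole verification. `a` is snapped to the nearest voxel-centre
#' offset; the snapped value is stored in the returned grid as `a_mm`.
#'
#' @param a Half-separation of the point electrodes, mm.
#' @param spacing Voxel pitch, mm.
#' @param extents Domain size `c(Lx, Ly, Lz)`, mm.
#' @return A `domain_grid` with `surface_z = -Inf` (no tissue) and the
#'   electrode voxel indices in `electrode_index`.
#' @export
point_charge_grid <- function(a, spacing, extents) {
  even <- function(L) { n <- as.integer(round(L / spacing)); n + n %% 2L }
  nx <- even(extents[1]); ny <- even(extents[2]); nz <- even(extents[3])
  x <- (seq_len(nx) - 0.5 - nx / 2) * spacing
  y <- (seq_len(ny) - 0.5 - ny / 2) * spacing
  z <- (seq_len(nz) - 0.5 - nz / 2) * spacing
  region <- array(REGION_CODES[["BLOOD"]], dim = c(nx, ny, nz))
  ip <- which.min(abs(x - a)); im <- nx + 1L - ip # mirror image of ip
  jc <- ny / 2; kc <- nz / 2
  region[ip, jc, kc] <- REGION_CODES[["ELECTRODE_POS"]]
  region[im, jc, kc] <- REGION_CODES[["ELECTRODE_NEG"]]
  g <- domain_grid_raw(region, spacing, x, y, z, surface_z = -Inf)
  g$a_mm <- x[ip]
  g$electrode_index <- list(pos = c(ip, jc, kc), neg = c(im, jc, kc))
  g
}

#' Verify the numerical solver against the two-point-charge closed form
#'
#' Solves the potential for two single-voxel electrodes in a homogeneous
#' medium and compares the numerical field magnitude along the perpendicular
#' bisector with the analytic dipole profile. The analytic charge q is fitted
#' at the anchor point y = a (profile-shape comparison, not absolute), so the
#' relative error at the anchor is zero by construction.
#'
#' @param grid A homogeneous grid from [point_charge_grid()].
#' @param V Applied inter-electrode voltage, V.
#' @param sigma Uniform conductivity, S/m (only sets the scale; the shape is
#'   conductivity-independent in a homogeneous medium).
#' @param tolerance,max_iterations Passed to [solve_config()].
#' @param far_boundary Outer-boundary condition; `"grounded"` (default)
#'   mimics an unbounded medium better for this far-field comparison.
#' @return Data frame: `y_mm`, `E_numeric` and `E_analytic` (V/cm),
#'   `relative_error`.
#' @export
verify_solver_against_point_charges <- function(grid, V = 100, sigma = 0.7,
                                                tolerance = 1e-8,
                                                max_iterations = 50000L,
                                                far_boundary = "grounded") {
  stopifnot(inherits(grid, "domain_grid"))
  labs <- unique(as.vector(grid$region))
  if (!setequal(labs, REGION_CODES[c("BLOOD", "ELECTRODE_POS", "ELECTRODE_NEG")]))
    stop("precondition error: grid must be homogeneous with two point electrodes")
  tab <- material_table(sigma_blood = sigma, sigma_myocardium = sigma)
  cf <- assign_materials(grid, tab)
  fm <- solve_potential(grid, cf,
                        solve_config(V, far_boundary = far_boundary,
                                     tolerance = tolerance,
                                     max_iterations = max_iterations))
  a_mm <- grid$a_mm
  jc <- grid$electrode_index$pos[2]
  kc <- grid$electrode_index$pos[3]
  nx <- grid$dims[1]
  icols <- c(nx / 2, nx / 2 + 1) # straddle the bisector at x = +/- h/2
  toff <- grid$y - grid$y[jc]    # distance along the bisector
  jpos <- which(toff > 0)
  e_num <- rowMeans(sapply(icols, function(i) fm$Emag[i, jpos, kc]))
  yy <- toff[jpos]

  anchor <- which.min(abs(yy - a_mm))
  a_m <- a_mm * 1e-3
  y_m <- yy * 1e-3
  shape <- point_charge_field(q = 1, a = a_m, y = y_m) # up to the 2kq factor
  scale <- e_num[anchor] / shape[anchor]
  e_ana <- shape * scale
  data.frame(y_mm = yy, E_numeric = e_num, E_analytic = e_ana,
             relative_error = abs(e_num - e_ana) / e_ana)
}

#' Parallel-plate (capacitor) verification grid
#'
#' Homogeneous block whose first and last z layers are full-cross-section
#' electrodes, so the interior potential is an exact linear ramp and
#' |E| = V / g with g the gap between the electrode inner faces (the
#' conductor fills its voxel, so g = (n - 2) * spacing).
#'
#' @param n Voxels per side.
#' @param spacing Voxel pitch, mm.
#' @return A `domain_grid`; `gap_mm` holds the inner-face gap g.
#' @export
capacitor_grid <- function(n = 32, spacing = 0.5) {
  x <- (seq_len(n) - 0.5 - n / 2) * spacing
  region <- array(REGION_CODES[["BLOOD"]], dim = c(n, n, n))
  region[, , 1] <- REGION_CODES[["ELECTRODE_NEG"]]
  region[, , n] <- REGION_CODES[["ELECTRODE_POS"]]
  g <- domain_grid_raw(region, spacing, x, x, x, surface_z = -Inf)
  g$gap_mm <- (n - 2) * spacing
  g
}
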