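#' Parametric two-electrode catheter description
#'
#' Describes a simplified linear ablation catheter with two cylindrical band
#' electrodes mounted flush on an insulated shaft, lying with its axis
#' parallel to the endocardial plane. `elevation` is the vertical distance
#' from the electrode underside to the endocardial surface; 0 means tangent
#' contact (rigid plane, no tissue indentation).
#'
#' @param electrode_length Axial electrode length, mm (> 0). Default 2.
#' @param electrode_gap Edge-to-edge inter-electrode spacing, mm (> 0). Default 4.
#' @param diameter Catheter (and electrode) outer diameter, mm (> 0).
#'   Default 2.3 mm (7-French).
#' @param elevation Electrode-underside to endocardium distance, mm (>= 0).
#' @return An object of class `catheter_spec`.
#' @examples
#' catheter_spec()                 # contact geometry
#' catheter_spec(elevation = 2)    # catheter lifted 2 mm off the tissue
#' @export
catheter_spec <- function(electrode_length = 2, electrode_gap = 4,
                          diameter = 2.3, elevation = 0) {
  stopifnot(is.numeric(electrode_length), length(electrode_length) == 1,
            is.numeric(electrode_gap), length(electrode_gap) == 1,
            is.numeric(diameter), length(diameter) == 1,
            is.numeric(elevation), length(elevation) == 1)
  if (electrode_length <= 0) stop("electrode_length must be > 0")
  if (electrode_gap <= 0) stop("electrode_gap must be > 0")
  if (diameter <= 0) stop("diameter must be > 0")
  if (elevation < 0)
    stop("geometry error: elevation < 0 would embed electrodes in tissue (unsupported)")
  structure(list(electrode_length = electrode_length,
                 electrode_gap = electrode_gap,
                 diameter = diameter,
                 elevation = elevation),
            class = "catheter_spec")
}

#' @export
print.catheter_spec <- function(x, ...) {
  cat(sprintf(
    "2-electrode catheter: %.2f mm electrodes, %.2f mm gap, %.2f mm diameter, elevation %.2f mm\n",
    x$electrode_length, x$electrode_gap, x$diameter, x$elevation))
  invisible(x)
}

# internal low-level constructor, also used by analytic fixtures
domain_grid_raw <- function(region, spacing, x, y, z, surface_z = 0,
                            spec = NULL, tissue_depth = NA_real_) {
  structure(list(region = region, spacing = spacing,
                 dims = dim(region), x = x, y = y, z = z,
                 surface_z = surface_z, spec = spec,
                 tissue_depth = tissue_depth),
            class = "domain_grid")
}

#' Build the discretized computational domain
#'
#' Voxelizes the catheter-in-blood-pool-over-myocardium geometry on a uniform
#' structured grid. The endocardial plane sits at z = 0; myocardium occupies
#' z < 0 down to `tissue_depth`, blood fills the rest. The catheter axis runs
#' along x at height `elevation + diameter/2`, centred laterally; voxel
#' centres are classified by a point-in-solid test against the analytic
#' cylinder and electrode band extents.
#'
#' @param spec A [catheter_spec()].
#' @param spacing Uniform voxel pitch, mm. Must not exceed
#'   `electrode_length / 4` (at least four voxels across each electrode).
#' @param extents Domain size `c(Lx, Ly, Lz)` in mm. Default
#'   `c(40, 40, 35)` (20 mm blood + 15 mm tissue).
#' @param tissue_depth Myocardial slab thickness, mm (default 15).
#' @return A `domain_grid`: voxel pitch, voxel-centre coordinates, the
#'   integer region array (see [region_codes()]), and the endocardial plane
#'   position `surface_z = 0`.
#' @examples
#' g <- build_domain(catheter_spec(), spacing = 0.5,
#'                   extents = c(40, 40, 35))
#' table(g$region)
#' @export
build_domain <- function(spec, spacing = 0.25, extents = c(40, 40, 35),
                         tissue_depth = 15) {
  stopifnot(inherits(spec, "catheter_spec"), length(extents) == 3,
            all(extents > 0), spacing > 0, tissue_depth > 0,
            tissue_depth < extents[3])
  if (spacing > spec$electrode_length / 4 + 1e-9)
    stop(sprintf(
      "resolution error: spacing %.3g mm too coarse to resolve a %.3g mm electrode (need <= %.3g mm)",
      spacing, spec$electrode_length, spec$electrode_length / 4))
  if (spec$elevation < 0)
    stop("geometry error: electrodes below the endocardial surface are unsupported")

  even <- function(n) n + n %% 2L
  nx <- even(as.integer(round(extents[1] / spacing)))
  ny <- even(as.integer(round(extents[2] / spacing)))
  nzt <- as.integer(round(tissue_depth / spacing))
  nzb <- as.integer(round((extents[3] - tissue_depth) / spacing))
  nz <- nzt + nzb
  x <- (seq_len(nx) - 0.5 - nx / 2) * spacing
  y <- (seq_len(ny) - 0.5 - ny / 2) * spacing
  z <- (seq_len(nz) - 0.5 - nzt) * spacing

  r <- spec$diameter / 2
  z0 <- spec$elevation + r # catheter axis height above the endocardium
  half_gap <- spec$electrode_gap / 2
  x_outer <- half_gap + spec$electrode_length

  if (x_outer > max(x) || z0 + r > max(z) || r > max(y))
    stop("geometry error: catheter not contained in the domain extents")
  if (extents[1] < 10 * spec$electrode_gap || extents[2] < 10 * spec$electrode_gap)
    warning("lateral extents < 10x electrode_gap: far-field boundary may bias the solution")
  if (tissue_depth < 15)
    warning("tissue depth < 15 mm: deep-lesion extraction may hit the slab boundary")

  region <- array(REGION_CODES[["BLOOD"]], dim = c(nx, ny, nz))
  region[, , z < 0] <- REGION_CODES[["MYOCARDIUM"]]

  # catheter cross-section mask in the (y, z) plane
  incyl <- outer(y^2, (z - z0)^2, "+") <= r^2
  if (any(incyl[, z < 0]))
    stop("geometry error: catheter body intersects the myocardium")
  in_pos <- x >= half_gap & x <= x_outer
  in_neg <- x <= -half_gap & x >= -x_outer
  for (i in seq_len(nx)) {
    lab <- if (in_pos[i]) REGION_CODES[["ELECTRODE_POS"]]
           else if (in_neg[i]) REGION_CODES[["ELECTRODE_NEG"]]
           else REGION_CODES[["SHAFT"]]
    sl <- region[i, , ]
    sl[incyl] <- lab
    region[i, , ] <- sl
  }

  n_pos <- sum(region == REGION_CODES[["ELECTRODE_POS"]])
  n_neg <- sum(region == REGION_CODES[["ELECTRODE_NEG"]])
  if (n_pos == 0 || n_neg == 0)
    stop("resolution error: an electrode contains no voxels at this spacing")

  domain_grid_raw(region, spacing, x, y, z, surface_z = 0,
                  spec = spec, tissue_depth = tissue_depth)
}

#' @export
print.domain_grid <- function(x, ...) {
  cat(sprintf("domain_grid: %d x %d x %d voxels at %.3g mm pitch\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing))
  tb <- table(factor(x$region, levels = REGION_CODES,
                     labels = names(REGION_CODES)))
  print(tb)
  invisible(x)
}

#' Symmetry planes of a catheter domain
#'
#' Identifies the frontal plane (the vertical plane y = 0 through both
#' electrode centres) and the midplane (x = 0, equidistant between the
#' electrodes) and verifies the region labels are mirror-symmetric about
#' each: exactly symmetric about the frontal plane, and symmetric with
#' electrode polarity swapped about the midplane.
#'
#' @param grid A `domain_grid` from [build_domain()].
#' @return A `symmetry_info` list with the two plane definitions.
#' @export
symmetry_planes <- function(grid) {
  stopifnot(inherits(grid, "domain_grid"))
  reg <- grid$region
  d <- dim(reg)

  mir_y <- reg[, d[2]:1, , drop = FALSE]
  if (!identical(reg, mir_y)) {
    bad <- which(reg != mir_y, arr.ind = TRUE)[1, ]
    stop(sprintf("symmetry error: frontal-plane mirror mismatch at voxel (%d, %d, %d)",
                 bad[1], bad[2], bad[3]))
  }

  mir_x <- reg[d[1]:1, , , drop = FALSE]
  sw <- mir_x
  sw[mir_x == REGION_CODES[["ELECTRODE_POS"]]] <- REGION_CODES[["ELECTRODE_NEG"]]
  sw[mir_x == REGION_CODES[["ELECTRODE_NEG"]]] <- REGION_CODES[["ELECTRODE_POS"]]
  if (!identical(reg, sw)) {
    bad <- which(reg != sw, arr.ind = TRUE)[1, ]
    stop(sprintf("symmetry error: midplane mirror mismatch at voxel (%d, %d, %d)",
                 bad[1], bad[2], bad[3]))
  }

  structure(list(frontal_plane = list(normal = "y", value = 0),
                 midplane = list(normal = "x", value = 0)),
            class = "symmetry_info")
}

# voxel-centre distances from electrode voxels down to the endocardial plane
electrode_surface_distance <- function(grid) {
  el <- grid$region == REGION_CODES[["ELECTRODE_POS"]] |
        grid$region == REGION_CODES[["ELECTRODE_NEG"]]
  kz <- apply(el, 3, any)
  zmin <- min(grid$z[kz])
  zmin - grid$surface_z
}
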