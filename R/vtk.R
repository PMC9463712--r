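#' Export voxel fields as legacy VTK structured points
#'
#' Writes one or more per-voxel scalar arrays on a uniform grid to a legacy
#' ASCII VTK STRUCTURED_POINTS file (readable by ParaView/VTK). Integer
#' arrays (e.g. region labels) are written as `int`, others as `float`.
#'
#' @param path Output file path.
#' @param grid A `domain_grid` supplying dimensions, spacing and origin.
#' @param ... Named arrays (dimensions matching the grid) to write as
#'   point-data scalars, e.g. `region = grid$region`, `phi = fm$phi`.
#' @return `path`, invisibly.
#' @export
write_vtk_structured_points <- function(path, grid, ...) {
  arrays <- list(...)
  stopifnot(inherits(grid, "domain_grid"), length(arrays) > 0,
            !is.null(names(arrays)), all(nzchar(names(arrays))))
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "pfasim field export",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", grid$x[1], grid$y[1], grid$z[1]),
               sprintf("SPACING %g %g %g", grid$spacing, grid$spacing, grid$spacing),
               sprintf("POINT_DATA %d", prod(d))), con)
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    if (!all(dim(a) == d)) stop(sprintf("array '%s' does not match the grid", nm))
    v <- as.vector(a) # VTK x-fastest ordering matches R arrays
    if (is.integer(v)) {
      writeLines(c(sprintf("SCALARS %s int 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(paste(formatC(v, format = "d"), collapse = "\n"), con)
    } else {
      v[is.na(v)] <- 0
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(paste(formatC(v, format = "g", digits = 7), collapse = "\n"), con)
    }
  }
  invisible(path)
}
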