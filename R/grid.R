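#' Super-resolved reconstruction grid
#'
#' Regular pixel grid for ULM map reconstruction. The default pitch is the
#' acquisition pixel divided by 16: a 110 um lateral x 100 um axial probe
#' pixel gives 6.875 x 6.25 um super-resolved pixels. Pixel `(i, j)` (row i =
#' depth, column j = lateral) spans the half-open interval
#' `[z0 + (i-1)*pitch_z, z0 + i*pitch_z)` (same laterally), so a coordinate
#' exactly on a boundary belongs to the higher-index pixel.
#'
#' @param nz,nx grid dimensions (depth rows, lateral columns).
#' @param pitch_z,pitch_x pixel pitch in micrometres.
#' @param z0,x0 origin (top-left corner) in micrometres.
#' @return An object of class `ulm_grid`.
#' @examples
#' g <- ulm_grid(160, 160)        # 1 mm x 1.1 mm field of view
#' c(g$pitch_z, g$pitch_x)        # 6.25 6.875
#' @export
ulm_grid <- function(nz, nx, pitch_z = 100 / 16, pitch_x = 110 / 16,
                     z0 = 0, x0 = 0) {
  stopifnot(nz >= 1, nx >= 1, pitch_z > 0, pitch_x > 0)
  structure(list(nz = as.integer(nz), nx = as.integer(nx),
                 pitch_z = pitch_z, pitch_x = pitch_x, z0 = z0, x0 = x0),
            class = "ulm_grid")
}

#' @export
print.ulm_grid <- function(x, ...) {
  cat(sprintf("ulm_grid: %d x %d px, pitch %.4g x %.4g um, origin (%g, %g)\n",
              x$nz, x$nx, x$pitch_z, x$pitch_x, x$z0, x$x0))
  invisible(x)
}

#' Super-resolved grid covering a field of view
#'
#' @param fov_z,fov_x field-of-view extent in micrometres.
#' @param coarse_pitch_z,coarse_pitch_x acquisition pixel pitch in um.
#' @param sr_factor super-resolution factor (acquisition pitch / map pitch).
#' @return An [ulm_grid()] whose extent covers the field of view.
#' @export
super_grid <- function(fov_z, fov_x, coarse_pitch_z = 100,
                       coarse_pitch_x = 110, sr_factor = 16) {
  pz <- coarse_pitch_z / sr_factor
  px <- coarse_pitch_x / sr_factor
  ulm_grid(ceiling(fov_z / pz), ceiling(fov_x / px), pz, px)
}

#' Snap continuous positions to grid pixels
#'
#' Nearest-pixel rounding with the half-up tie rule: a position exactly on a
#' pixel boundary is assigned to the higher-index pixel (consistent with the
#' half-open pixel intervals). Positions outside the field of view are
#' flagged.
#'
#' @param z,x positions in micrometres.
#' @param grid an [ulm_grid()].
#' @return list with integer vectors `iz`, `ix` (NA outside the grid) and a
#'   logical `inside`.
#' @export
snap_to_grid <- function(z, x, grid) {
  iz <- floor((z - grid$z0) / grid$pitch_z) + 1L
  ix <- floor((x - grid$x0) / grid$pitch_x) + 1L
  inside <- iz >= 1L & iz <= grid$nz & ix >= 1L & ix <= grid$nx
  iz[!inside] <- NA_integer_
  ix[!inside] <- NA_integer_
  list(iz = as.integer(iz), ix = as.integer(ix), inside = inside)
}

#' Pixel centers of a grid axis
#' @param grid an [ulm_grid()]
#' @param axis `"z"` or `"x"`
#' @return numeric vector of pixel-center coordinates (um).
#' @export
grid_centers <- function(grid, axis = c("z", "x")) {
  axis <- match.arg(axis)
  if (axis == "z") grid$z0 + (seq_len(grid$nz) - 0.5) * grid$pitch_z
  else grid$x0 + (seq_len(grid$nx) - 0.5) * grid$pitch_x
}
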