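#' Build the structured simulation grid
#'
#' Voxelizes the phantom block, embedded channel, actuator disk and the air
#' gap above the surface onto a uniform Cartesian grid. Coordinates are
#' right-handed with x along the flow, z up, and the origin at the actuator
#' centre on the top surface; the solid block occupies z < 0 and the air
#' gap (which hosts the elevated sensing layer) occupies z > 0.
#'
#' @param geometry A `tf_geometry`.
#' @param actuator A `tf_actuator`; the heater is a one-cell-thick disk
#'   sitting on the top surface.
#' @param layout A `tf_layout`; determines how tall the air gap must be so
#'   the elevated thermistors are interior to the domain.
#' @param spacing Uniform cell spacing in mm. Must not exceed a quarter of
#'   the channel diameter, otherwise the channel cannot be resolved.
#' @return An object of class `tf_grid`: cell-centre coordinate vectors,
#'   an integer material array (1 = phantom, 2 = fluid, 3 = actuator,
#'   4 = air, 5 = wall), and bookkeeping fields.
#' @export
build_grid <- function(geometry, actuator, layout, spacing = 0.5) {
  stopifnot(inherits(geometry, "tf_geometry"), inherits(actuator, "tf_actuator"),
            inherits(layout, "tf_layout"))
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  if (geometry$channel_diameter > 0 && spacing > geometry$channel_diameter / 4)
    stop("spacing too coarse to resolve the channel: need spacing <= channel_diameter / 4",
         call. = FALSE)

  h <- spacing
  bx <- geometry$block[1]; by <- geometry$block[2]; bz <- geometry$block[3]
  nx <- max(1L, round(bx / h)); ny <- max(1L, round(by / h))
  nz_solid <- max(1L, round(bz / h))
  # air gap: interlayer spacing plus a 1 mm buffer so the top probes are interior
  air_height <- layout$interlayer_spacing + 1.0
  nz_air <- max(2L, ceiling(air_height / h))
  nz <- nz_solid + nz_air

  xc <- -bx / 2 + (seq_len(nx) - 0.5) * h
  yc <- -by / 2 + (seq_len(ny) - 0.5) * h
  zc <- -nz_solid * h + (seq_len(nz) - 0.5) * h

  mat <- array(1L, dim = c(nx, ny, nz))          # phantom
  mat[, , (nz_solid + 1):nz] <- 4L               # air above the surface

  # channel: cylinder along x, centred in y, top at z = -d.
  # Cells belong to the channel when at least half their cross-section lies
  # inside the true circle (8x8 subsampling); this keeps the voxelized
  # cross-section area close to pi r^2.
  r <- geometry$channel_diameter / 2
  zc_axis <- -(geometry$vessel_depth + r)
  off <- ((1:8) - 4.5) / 8 * h
  sub <- expand.grid(dy = off, dz = off)
  cover <- function(radius) {
    fr <- matrix(0, ny, nz)
    for (iy in seq_len(ny)) {
      dy2 <- (yc[iy] + sub$dy)^2
      for (iz in seq_len(nz)) {
        if ((yc[iy]^2 + (zc[iz] - zc_axis)^2) > (radius + h)^2) next
        fr[iy, iz] <- mean(dy2 + (zc[iz] + sub$dz - zc_axis)^2 <= radius^2)
      }
    }
    fr
  }
  in_fluid <- if (r > 0) cover(r) >= 0.5 else matrix(FALSE, ny, nz)
  wt <- geometry$wall_thickness
  in_wall <- if (wt > 0) cover(r + wt) >= 0.5 & !in_fluid else
    matrix(FALSE, ny, nz)
  for (iy in seq_len(ny)) for (iz in seq_len(nz_solid)) {
    if (in_fluid[iy, iz]) mat[, iy, iz] <- 2L
    else if (in_wall[iy, iz]) mat[, iy, iz] <- 5L
  }

  # actuator: one-cell-thick disk on the surface, centred over the channel axis
  ra <- actuator$diameter / 2
  disk <- outer(xc^2, yc^2, `+`) <= ra^2
  act_layer <- nz_solid + 1L
  mat[, , act_layer][disk] <- 3L
  if (!any(disk))
    stop("spacing too coarse to resolve the actuator disk", call. = FALSE)

  # fluid cross-section sanity (spec invariant: within 10% of the true area)
  n_sect <- sum(in_fluid[, seq_len(nz_solid)])
  true_cells <- pi * r^2 / h^2
  if (r > 0 && abs(n_sect - true_cells) / true_cells > 0.10)
    stop("voxelized channel cross-section deviates more than 10% from the true area; refine the spacing",
         call. = FALSE)

  structure(list(
    nx = nx, ny = ny, nz = nz, nz_solid = nz_solid, spacing = h,
    x = xc, y = yc, z = zc, material = mat,
    labels = c("phantom", "fluid", "actuator", "air", "wall"),
    channel_radius = r, channel_axis_z = zc_axis,
    fluid_section_cells = n_sect
  ), class = "tf_grid")
}

#' @export
print.tf_grid <- function(x, ...) {
  cat(sprintf("<tf_grid> %d x %d x %d cells @ %.3g mm (%d unknowns)\n",
              x$nx, x$ny, x$nz, x$spacing, x$nx * x$ny * x$nz))
  tab <- table(factor(x$labels[x$material], levels = x$labels))
  cat("  cells:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# per-cell velocity (m/s, +x) for fluid cells; zero elsewhere
grid_velocity <- function(grid, flow) {
  u <- array(0, dim = c(grid$nx, grid$ny, grid$nz))
  fl <- grid$material == 2L
  if (flow$speed > 0 && any(fl)) {
    if (flow$profile == "plug") {
      u[fl] <- flow$speed * 1e-3
    } else {
      # developed laminar: u = 2 f (1 - (rho/r)^2), per-cell at the centre
      r <- grid$channel_radius
      d2 <- outer(grid$y^2, (grid$z - grid$channel_axis_z)^2, `+`)  # ny x nz
      prof <- pmax(2 * flow$speed * (1 - d2 / r^2), 0) * 1e-3
      for (iy in seq_len(grid$ny)) for (iz in seq_len(grid$nz))
        if (any(grid$material[, iy, iz] == 2L))
          u[grid$material[, iy, iz] == 2L, iy, iz] <- prof[iy, iz]
    }
  }
  u
}
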