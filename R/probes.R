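#' Interpolate a temperature at a point
#'
#' Trilinear interpolation of the cell-centred temperature field at an
#' arbitrary position inside the domain. Between the outermost cell centre
#' and the physical boundary the nearest-centre value is used.
#'
#' @param field A `thermal_field`.
#' @param position Numeric length-3 (x, y, z) in mm.
#' @return Temperature in degrees C.
#' @export
probe_temperature <- function(field, position) {
  stopifnot(inherits(field, "thermal_field"), length(position) == 3L)
  g <- field$grid
  h <- g$spacing
  lo <- c(g$x[1] - h / 2, g$y[1] - h / 2, g$z[1] - h / 2)
  hi <- c(g$x[g$nx] + h / 2, g$y[g$ny] + h / 2, g$z[g$nz] + h / 2)
  if (any(position < lo - 1e-9) || any(position > hi + 1e-9))
    stop("probe position outside the simulation domain", call. = FALSE)
  coords <- list(g$x, g$y, g$z)
  i0 <- integer(3); w <- numeric(3)
  for (a in 1:3) {
    cs <- coords[[a]]
    n <- length(cs)
    if (position[a] <= cs[1]) { i0[a] <- 1L; w[a] <- 0 }
    else if (position[a] >= cs[n]) { i0[a] <- n - 1L; w[a] <- 1 }
    else {
      i <- findInterval(position[a], cs)
      i0[a] <- i
      w[a] <- (position[a] - cs[i]) / (cs[i + 1L] - cs[i])
    }
    if (n == 1L) { i0[a] <- 1L; w[a] <- 0 }
  }
  Tarr <- field$temperature
  ix <- i0[1]; iy <- i0[2]; iz <- i0[3]
  ix1 <- min(ix + 1L, g$nx); iy1 <- min(iy + 1L, g$ny); iz1 <- min(iz + 1L, g$nz)
  c00 <- Tarr[ix, iy, iz]  * (1 - w[1]) + Tarr[ix1, iy, iz]  * w[1]
  c10 <- Tarr[ix, iy1, iz] * (1 - w[1]) + Tarr[ix1, iy1, iz] * w[1]
  c01 <- Tarr[ix, iy, iz1] * (1 - w[1]) + Tarr[ix1, iy, iz1] * w[1]
  c11 <- Tarr[ix, iy1, iz1] * (1 - w[1]) + Tarr[ix1, iy1, iz1] * w[1]
  c0 <- c00 * (1 - w[2]) + c10 * w[2]
  c1 <- c01 * (1 - w[2]) + c11 * w[2]
  c0 * (1 - w[3]) + c1 * w[3]
}

#' Read the six thermistor channels from a field
#'
#' @param field A `thermal_field`.
#' @param layout A `tf_layout`.
#' @return Named numeric vector of six temperatures (degrees C) in the
#'   fixed order `t_top_up`, `t_top_dn`, `t_top_ref`, `t_bot_up`,
#'   `t_bot_dn`, `t_bot_ref` (see [channel_names()]).
#' @export
sensor_readings <- function(field, layout) {
  pos <- layout_positions(layout)
  out <- apply(pos, 1, function(p) probe_temperature(field, p))
  names(out) <- rownames(pos)
  out
}

#' Minimum-maximum normalized sensor reading
#'
#' @param temperature Temperature(s), degrees C.
#' @param t_min,t_max Normalization range; `t_max` must exceed `t_min`.
#' @return `(temperature - t_min) / (t_max - t_min)`.
#' @export
normalized_reading <- function(temperature, t_min, t_max) {
  if (t_max <= t_min)
    stop("degenerate normalization range: t_max must exceed t_min", call. = FALSE)
  (temperature - t_min) / (t_max - t_min)
}

#' Steady-state energy balance residual
#'
#' Verifies a converged steady solution by numerical surface integration:
#' the actuator input power must equal the conductive flux through the
#' bottom face plus the convective loss through the top face plus the net
#' advected enthalpy through the channel, to within the discretization
#' error.
#'
#' @param field A steady `thermal_field`.
#' @param materials,ambient,flow,actuator_power The configuration used to
#'   produce the field.
#' @return If `actuator_power > 0`, the dimensionless fraction
#'   `|P_in - P_out| / P_in`; if the power is zero, the absolute residual
#'   in mW.
#' @export
energy_balance_residual <- function(field, materials, ambient, flow,
                                    actuator_power) {
  stopifnot(inherits(field, "thermal_field"), isTRUE(field$steady))
  g <- field$grid
  h <- g$spacing * 1e-3
  A_face <- h^2
  Tarr <- field$temperature
  lab <- g$labels[g$material]
  kc <- array(vapply(materials[lab], function(m) m$conductivity, numeric(1)),
              dim = dim(g$material))

  # conductive flux out through the fixed-temperature bottom face (W)
  Tb <- Tarr[, , 1]; kb <- kc[, , 1]
  q_bottom <- sum(2 * kb * h * (Tb - ambient$bottom))

  # convective loss through the top face (W)
  Tt <- Tarr[, , g$nz]; kt <- kc[, , g$nz]
  q_top <- if (ambient$h > 0)
    sum(1 / (1 / ambient$h + (h / 2) / kt) * A_face * (Tt - ambient$ambient))
  else 0

  # net advected enthalpy: outflux at x-max minus influx at T_in (W)
  u <- grid_velocity(g, flow)
  fl <- g$material == 2L
  rc_f <- materials$fluid$density * materials$fluid$specific_heat
  out_mask <- fl[g$nx, , ]
  q_adv <- sum(rc_f * u[g$nx, , ][out_mask] * A_face *
                 (Tarr[g$nx, , ][out_mask] - ambient$inlet))
  # diffusive flux through the Dirichlet inlet face (W)
  in_mask <- fl[1, , ]
  q_in_diff <- sum(2 * kc[1, , ][in_mask] * h *
                     (Tarr[1, , ][in_mask] - ambient$inlet))
  if (flow$speed == 0) {
    out_mask2 <- fl[g$nx, , ]
    q_in_diff <- q_in_diff + sum(2 * kc[g$nx, , ][out_mask2] * h *
                                   (Tarr[g$nx, , ][out_mask2] - ambient$inlet))
  }

  p_out_mW <- (q_bottom + q_top + q_adv + q_in_diff) * 1e3
  if (actuator_power > 0) abs(actuator_power - p_out_mW) / actuator_power
  else abs(p_out_mW)
}
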