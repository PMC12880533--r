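#' Material thermal properties
#'
#' Bundle of the three bulk properties the heat-transport model needs.
#' All quantities are in SI units.
#'
#' @param label Short name for the material (e.g. "phantom", "fluid").
#' @param conductivity Thermal conductivity in W/(m K).
#' @param specific_heat Specific heat capacity in J/(kg K).
#' @param density Density in kg/m^3.
#' @return An object of class `tf_material`.
#' @export
#' @examples
#' material_properties("fluid", 0.6, 4184, 1000)
material_properties <- function(label, conductivity, specific_heat, density) {
  stopifnot(is.character(label), length(label) == 1L)
  vals <- c(conductivity = conductivity, specific_heat = specific_heat,
            density = density)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("material properties must be strictly positive and finite", call. = FALSE)
  structure(list(label = label, conductivity = conductivity,
                 specific_heat = specific_heat, density = density),
            class = "tf_material")
}

#' Default material set for the phantom bench
#'
#' PDMS phantom, water standing in for blood, a copper actuator, and still
#' air for the interlayer gap (modelled as a conducting medium; no
#' convection inside the 1.5 mm gap). Densities for PDMS/water/copper are
#' standard handbook values.
#'
#' @return Named list of `tf_material` objects with entries `phantom`,
#'   `fluid`, `actuator`, `air`, and `wall` (silicone tubing, used only
#'   when a wall thickness is set on the geometry).
#' @export
default_materials <- function() {
  list(
    phantom  = material_properties("phantom",  0.16, 1460, 965),
    fluid    = material_properties("fluid",    0.60, 4184, 1000),
    actuator = material_properties("actuator", 400,  385,  8960),
    air      = material_properties("air",      0.026, 1005, 1.2),
    wall     = material_properties("wall",     0.20, 1300, 1100)
  )
}

#' Phantom geometry
#'
#' A rectangular phantom block with an embedded cylindrical channel running
#' along x, centred in y. The vessel depth `d` is the distance from the top
#' surface to the *top* of the channel.
#'
#' @param block Numeric length-3: block extents (x, y, z) in mm. The block
#'   models a reduced region around the actuator; the full benchtop phantom
#'   is thermally far-field.
#' @param channel_diameter Channel diameter in mm.
#' @param vessel_depth Depth of the top of the channel below the surface, mm.
#' @param wall_thickness Optional tubing wall thickness in mm (0 = none).
#' @param wall_material Optional `tf_material` for the wall; defaults to the
#'   silicone entry of [default_materials()] when a thickness is set.
#' @return An object of class `tf_geometry`.
#' @export
phantom_geometry <- function(block = c(30, 20, 10), channel_diameter = 2.5,
                             vessel_depth = 1.5, wall_thickness = 0,
                             wall_material = NULL) {
  block <- as.numeric(block)
  stopifnot(length(block) == 3L, all(block > 0))
  if (channel_diameter < 0) stop("channel_diameter must be non-negative", call. = FALSE)
  # channel_diameter = 0 means a solid block without a vessel (used for
  # conduction-only verification problems)
  if (vessel_depth <= 0) stop("vessel_depth must be positive", call. = FALSE)
  if (wall_thickness < 0) stop("wall_thickness must be >= 0", call. = FALSE)
  if (vessel_depth + channel_diameter + 2 * wall_thickness > block[3])
    stop("channel does not fit inside the block: vessel_depth + diameter exceeds z extent",
         call. = FALSE)
  structure(list(block = block, channel_diameter = channel_diameter,
                 vessel_depth = vessel_depth, wall_thickness = wall_thickness,
                 wall_material = wall_material),
            class = "tf_geometry")
}

#' Thermal actuator specification
#'
#' A disk heater of diameter `D` centred on the top surface directly over
#' the channel axis, driven at constant power `P` distributed uniformly
#' over the disk.
#'
#' @param diameter Actuator diameter in mm.
#' @param power Heating power in mW.
#' @return An object of class `tf_actuator`.
#' @export
actuator_spec <- function(diameter = 3.5, power = 56.7) {
  if (diameter <= 0) stop("actuator diameter must be positive", call. = FALSE)
  if (power < 0) stop("actuator power must be non-negative", call. = FALSE)
  structure(list(diameter = diameter, power = power), class = "tf_actuator")
}

#' Areal power density of a disk actuator
#'
#' @param power Heating power in mW.
#' @param diameter Disk diameter in mm.
#' @return Power density in mW/mm^2, `power / (pi (diameter/2)^2)`.
#' @export
#' @examples
#' power_density(56.7, 3.5)  # ~5.89 mW/mm^2
power_density <- function(power, diameter) {
  if (diameter <= 0) stop("diameter must be positive", call. = FALSE)
  if (power < 0) stop("power must be non-negative", call. = FALSE)
  power / (pi * (diameter / 2)^2)
}

#' Multilayer thermistor layout
#'
#' Six probe positions: upstream/downstream thermistors at lateral offset
#' `L` along the channel axis from the actuator centre, in a bottom layer
#' flush with the surface and a top layer elevated by the interlayer
#' spacing `H`; plus one reference thermistor per layer at distance `L`
#' perpendicular to the channel axis (outside the flow path).
#'
#' @param lateral_offset Distance L from actuator centre, mm.
#' @param interlayer_spacing Height H of the top layer above the surface, mm.
#' @param actuator_diameter Used only to validate that the thermistors sit
#'   outside the actuator footprint.
#' @return An object of class `tf_layout`.
#' @export
sensor_layout <- function(lateral_offset = 3.5, interlayer_spacing = 1.5,
                          actuator_diameter = 3.5) {
  if (interlayer_spacing <= 0) stop("interlayer_spacing must be positive", call. = FALSE)
  if (lateral_offset <= actuator_diameter / 2)
    stop("lateral_offset must exceed the actuator radius (thermistors outside the footprint)",
         call. = FALSE)
  structure(list(lateral_offset = lateral_offset,
                 interlayer_spacing = interlayer_spacing),
            class = "tf_layout")
}

#' Probe positions of a sensor layout
#'
#' @param layout A `tf_layout`.
#' @return A 6 x 3 matrix of (x, y, z) positions in mm, rows in the fixed
#'   channel order `t_top_up`, `t_top_dn`, `t_top_ref`, `t_bot_up`,
#'   `t_bot_dn`, `t_bot_ref`. Upstream is -x (flow runs towards +x).
#' @export
layout_positions <- function(layout) {
  stopifnot(inherits(layout, "tf_layout"))
  L <- layout$lateral_offset
  H <- layout$interlayer_spacing
  pos <- rbind(
    t_top_up  = c(-L, 0, H),
    t_top_dn  = c( L, 0, H),
    t_top_ref = c( 0, L, H),
    t_bot_up  = c(-L, 0, 0),
    t_bot_dn  = c( L, 0, 0),
    t_bot_ref = c( 0, L, 0)
  )
  colnames(pos) <- c("x", "y", "z")
  pos
}

#' Channel order of the six thermal channels
#' @return Character vector of the six channel names in their fixed order.
#' @export
channel_names <- function() {
  c("t_top_up", "t_top_dn", "t_top_ref", "t_bot_up", "t_bot_dn", "t_bot_ref")
}

#' Ambient and boundary thermal conditions
#'
#' @param ambient Ambient air temperature in degrees C (drives the
#'   convective flux on the exposed top surface).
#' @param h Convective heat-transfer coefficient on exposed top surfaces,
#'   W/(m^2 K).
#' @param bottom Fixed temperature of the bottom surface, degrees C.
#' @param inlet Fluid temperature at the channel entrance, degrees C.
#' @return An object of class `tf_ambient`.
#' @export
ambient_conditions <- function(ambient = 25, h = 15, bottom = 25, inlet = 25) {
  if (h < 0) stop("convective coefficient h must be >= 0", call. = FALSE)
  temps <- c(ambient, bottom, inlet)
  if (any(!is.finite(temps))) stop("temperatures must be finite", call. = FALSE)
  structure(list(ambient = ambient, h = h, bottom = bottom, inlet = inlet),
            class = "tf_ambient")
}

#' Flow condition in the channel
#'
#' @param speed Mean flow speed in mm/s.
#' @param profile Velocity profile across the channel: `"plug"` (uniform,
#'   default) or `"parabolic"` (developed laminar, peak 2x mean).
#' @return An object of class `tf_flow`.
#' @export
flow_condition <- function(speed, profile = c("plug", "parabolic")) {
  profile <- match.arg(profile)
  if (!is.finite(speed) || speed < 0)
    stop("flow speed must be finite and >= 0", call. = FALSE)
  structure(list(speed = speed, profile = profile), class = "tf_flow")
}

#' Full simulation scenario
#'
#' Binds geometry, materials, actuator, layout, ambient conditions, flow
#' and the grid spacing into one configuration object consumed by the
#' forward solver and the dataset generator.
#'
#' @param geometry A `tf_geometry`.
#' @param materials Named list of `tf_material` (see [default_materials()]).
#' @param actuator A `tf_actuator`.
#' @param layout A `tf_layout`.
#' @param ambient A `tf_ambient`.
#' @param flow A `tf_flow`.
#' @param spacing Uniform grid spacing in mm.
#' @return An object of class `tf_scenario`.
#' @export
scenario <- function(geometry = phantom_geometry(),
                     materials = default_materials(),
                     actuator = actuator_spec(),
                     layout = sensor_layout(actuator_diameter = actuator$diameter),
                     ambient = ambient_conditions(),
                     flow = flow_condition(1),
                     spacing = 0.5) {
  stopifnot(inherits(geometry, "tf_geometry"), inherits(actuator, "tf_actuator"),
            inherits(layout, "tf_layout"), inherits(ambient, "tf_ambient"),
            inherits(flow, "tf_flow"))
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  structure(list(geometry = geometry, materials = materials,
                 actuator = actuator, layout = layout, ambient = ambient,
                 flow = flow, spacing = spacing),
            class = "tf_scenario")
}

#' Default benchtop scenario
#'
#' The baseline configuration: 2.5 mm channel in a 30 x 20 x 10 mm PDMS
#' block, 3.5 mm / 56.7 mW actuator, thermistors at L = 3.5 mm with
#' H = 1.5 mm interlayer spacing, 25 C ambient/bottom/inlet with
#' h = 15 W/(m^2 K), plug flow, 0.5 mm grid spacing.
#'
#' @param vessel_depth Vessel depth in mm (default 1.5).
#' @param flow_speed Mean flow speed in mm/s (default 1).
#' @param ... Further arguments forwarded to [scenario()] to override
#'   individual blocks.
#' @return A `tf_scenario`.
#' @export
default_scenario <- function(vessel_depth = 1.5, flow_speed = 1, ...) {
  scenario(geometry = phantom_geometry(vessel_depth = vessel_depth),
           flow = flow_condition(flow_speed), ...)
}

#' Modify a scenario
#'
#' Convenience to derive a new scenario with some blocks replaced.
#'
#' @param sc A `tf_scenario`.
#' @param ... Named blocks or fields to replace. Recognised names:
#'   `geometry`, `materials`, `actuator`, `layout`, `ambient`, `flow`,
#'   `spacing`, plus the shortcuts `vessel_depth`, `flow_speed`,
#'   `ambient_temperature` (which also moves bottom and inlet in lockstep,
#'   mirroring the temperature-controlled chamber and water bath).
#' @return A new `tf_scenario`.
#' @export
update_scenario <- function(sc, ...) {
  stopifnot(inherits(sc, "tf_scenario"))
  mods <- list(...)
  for (nm in names(mods)) {
    v <- mods[[nm]]
    if (nm == "vessel_depth") {
      g <- sc$geometry; g$vessel_depth <- v
      sc$geometry <- phantom_geometry(g$block, g$channel_diameter, v,
                                      g$wall_thickness, g$wall_material)
    } else if (nm == "flow_speed") {
      sc$flow <- flow_condition(v, sc$flow$profile)
    } else if (nm == "ambient_temperature") {
      sc$ambient <- ambient_conditions(ambient = v, h = sc$ambient$h,
                                       bottom = v, inlet = v)
    } else if (nm %in% c("geometry", "materials", "actuator", "layout",
                         "ambient", "flow", "spacing")) {
      sc[[nm]] <- v
    } else stop("unknown scenario field: ", nm, call. = FALSE)
  }
  scenario(sc$geometry, sc$materials, sc$actuator, sc$layout, sc$ambient,
           sc$flow, sc$spacing)
}
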