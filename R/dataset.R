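# Synthetic benchtop protocol: condition grids, labeled datasets,
# condition-grouped folds, design sweeps.

# Steady-solve cache: one forward solve per distinct scenario, keyed by a
# formatted dump of every physical parameter. Replicates re-noise the
# cached readings, mirroring repeated measurements on one bench setup.
.tf_cache <- new.env(parent = emptyenv())

scenario_key <- function(sc) {
  num <- function(x) paste(format(x, digits = 15, scientific = TRUE),
                           collapse = ",")
  mats <- vapply(sc$materials, function(m)
    num(c(m$conductivity, m$specific_heat, m$density)), character(1))
  paste(
    num(sc$geometry$block), num(sc$geometry$channel_diameter),
    num(sc$geometry$vessel_depth), num(sc$geometry$wall_thickness),
    paste(names(mats), mats, collapse = ";"),
    if (!is.null(sc$geometry$wall_material))
      num(c(sc$geometry$wall_material$conductivity,
            sc$geometry$wall_material$specific_heat,
            sc$geometry$wall_material$density)) else "nowall",
    num(c(sc$actuator$diameter, sc$actuator$power)),
    num(c(sc$layout$lateral_offset, sc$layout$interlayer_spacing)),
    num(c(sc$ambient$ambient, sc$ambient$h, sc$ambient$bottom, sc$ambient$inlet)),
    num(sc$flow$speed), sc$flow$profile, num(sc$spacing),
    sep = "|")
}

#' Steady six-channel readings for a scenario (cached)
#'
#' Builds the grid, runs the steady solver and probes the six thermistor
#' positions. Results are memoised on the full physical configuration, so
#' repeated calls (noise replicates, sweeps that leave the thermal problem
#' unchanged) reuse one solve.
#'
#' @param sc A `tf_scenario`.
#' @param cache Use the in-memory cache (default TRUE).
#' @return Named numeric vector of six temperatures in degrees C.
#' @export
steady_readings <- function(sc, cache = TRUE) {
  stopifnot(inherits(sc, "tf_scenario"))
  key <- scenario_key(sc)
  if (cache && !is.null(.tf_cache[[key]])) return(.tf_cache[[key]])
  mats <- sc$materials
  if (!is.null(sc$geometry$wall_material)) mats$wall <- sc$geometry$wall_material
  grid <- build_grid(sc$geometry, sc$actuator, sc$layout, sc$spacing)
  field <- solve_steady(grid, mats, sc$ambient, sc$flow, sc$actuator$power)
  r <- sensor_readings(field, sc$layout)
  if (cache) .tf_cache[[key]] <- r
  r
}

#' Clear the steady-solve cache
#' @return Invisibly, the number of entries removed.
#' @export
clear_solve_cache <- function() {
  n <- length(ls(.tf_cache))
  rm(list = ls(.tf_cache), envir = .tf_cache)
  invisible(n)
}

#' Benchtop condition grid
#'
#' The Cartesian grid of vessel depths and flow rates measured on the
#' bench, with a fixed number of replicate measurements per condition.
#'
#' @param depths Vessel depths in mm (default 1, 1.5, 2).
#' @param flows Flow rates in mm/s (default 1..10).
#' @param replicates Measurements per condition (default 50).
#' @return An object of class `condition_grid` with a `conditions` data
#'   frame (condition_id, depth, flow).
#' @export
condition_grid <- function(depths = c(1, 1.5, 2), flows = 1:10,
                           replicates = 50) {
  if (any(depths <= 0) || any(flows <= 0))
    stop("depths and flows must be positive", call. = FALSE)
  if (replicates < 1) stop("need at least one replicate", call. = FALSE)
  cond <- expand.grid(flow = as.numeric(flows), depth = as.numeric(depths),
                      KEEP.OUT.ATTRS = FALSE)
  cond <- cond[, c("depth", "flow")]
  if (anyDuplicated(cond))
    stop("duplicate (depth, flow) conditions", call. = FALSE)
  cond$condition_id <- sprintf("d%g_f%g", cond$depth, cond$flow)
  structure(list(conditions = cond[, c("condition_id", "depth", "flow")],
                 replicates = as.integer(replicates)),
            class = "condition_grid")
}

#' Measurement noise model
#'
#' Additive i.i.d. Gaussian noise on the probe temperatures at the 20 Hz
#' sampling cadence, before the smoothing filter. The default SD of
#' 0.0075 degrees C is calibrated so that the noise-limited flow-recovery
#' error at the least sensitive end of the measurement range (highest
#' flows) is of the order of the +/- 0.12 mm/s benchtop margin; it is
#' also a plausible post-amplifier noise level for a 10 kOhm NTC bridge
#' sampled at 20 Hz.
#'
#' @param sd Noise standard deviation in degrees C (default 0.0075).
#' @param seed Integer seed making dataset generation reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd = 0.0075, seed = 0L) {
  if (sd < 0) stop("noise sd must be >= 0", call. = FALSE)
  structure(list(sd = sd, seed = as.integer(seed)), class = "noise_model")
}

#' Generate a labeled synthetic dataset
#'
#' One steady forward solve per condition (cached) plus `replicates`
#' re-noised passes through the measurement chain per condition, yielding
#' rows of features with ground-truth (flow, depth) labels.
#'
#' @param grid A `condition_grid`.
#' @param sc Base `tf_scenario`; depth and flow are overridden per
#'   condition.
#' @param noise A `noise_model`.
#' @param mode Feature mode passed to [assemble_features()]
#'   ("temperature", "compensated" or "bridge").
#' @param progress Print one line per condition while solving.
#' @return A `labeled_dataset`: data frame with `condition_id`,
#'   `d_set_mm`, `f_set_mm_s` and one column per feature, plus attributes
#'   `feature_names` and `mode`.
#' @export
generate_dataset <- function(grid, sc = default_scenario(),
                             noise = noise_model(),
                             mode = c("temperature", "compensated", "bridge"),
                             progress = FALSE) {
  stopifnot(inherits(grid, "condition_grid"), inherits(sc, "tf_scenario"))
  mode <- match.arg(mode)
  cond <- grid$conditions
  set.seed(noise$seed)
  rows <- vector("list", nrow(cond))
  for (i in seq_len(nrow(cond))) {
    sci <- update_scenario(sc, vessel_depth = cond$depth[i],
                           flow_speed = cond$flow[i])
    r <- tryCatch(steady_readings(sci),
                  error = function(e)
                    stop(sprintf("forward solve failed at condition %s: %s",
                                 cond$condition_id[i], conditionMessage(e)),
                         call. = FALSE))
    if (progress)
      message(sprintf("solved %s (max reading %.3f C)",
                      cond$condition_id[i], max(r)))
    feats <- t(vapply(seq_len(grid$replicates),
                      function(k) assemble_features(r, noise_sd = noise$sd,
                                                    mode = mode),
                      numeric(if (mode == "temperature") 6L else 4L)))
    df <- data.frame(condition_id = cond$condition_id[i],
                     d_set_mm = cond$depth[i], f_set_mm_s = cond$flow[i])
    rows[[i]] <- cbind(df[rep(1L, grid$replicates), , drop = FALSE], feats)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(!vapply(out[, -(1:3)], function(c) all(is.finite(c)), logical(1))))
    stop("non-finite features generated", call. = FALSE)
  structure(out, feature_names = colnames(out)[-(1:3)], mode = mode,
            class = c("labeled_dataset", "data.frame"))
}

#' Condition-grouped K-fold assignment
#'
#' Partitions the experimental conditions (not rows) into K folds of
#' near-equal size, so replicates of one condition never straddle the
#' train/test boundary.
#'
#' @param grid A `condition_grid` (or a `labeled_dataset`).
#' @param k Number of folds (default 5).
#' @param seed Seed shuffling which conditions share a fold.
#' @return A `fold_assignment`: data frame (condition_id, fold) plus `k`.
#' @export
grouped_kfold <- function(grid, k = 5, seed = 0L) {
  ids <- if (inherits(grid, "condition_grid")) grid$conditions$condition_id
  else unique(grid$condition_id)
  n <- length(ids)
  if (k > n) stop("k exceeds the number of conditions", call. = FALSE)
  set.seed(seed)
  perm <- sample(ids)
  # fold sizes differ by at most one by construction of rep(length.out)
  asg <- data.frame(condition_id = perm, fold = rep(seq_len(k), length.out = n))
  asg <- asg[match(ids, asg$condition_id), ]
  rownames(asg) <- NULL
  structure(list(assignment = asg, k = as.integer(k)),
            class = "fold_assignment")
}

#' Design-parameter grid
#'
#' Cartesian product of actuator diameter, power, thermistor offset and
#' interlayer spacing, each entry a runnable scenario for the RMSE
#' heatmap studies.
#'
#' @param diameters Actuator diameters, mm.
#' @param powers Actuator powers, mW.
#' @param offsets Actuator-thermistor distances L, mm.
#' @param spacings Interlayer spacings H, mm.
#' @param base Base scenario supplying all other blocks.
#' @return List of `tf_scenario`, with attribute `design` (the parameter
#'   data frame).
#' @export
design_grid <- function(diameters = 3.5, powers = 56.7, offsets = 3.5,
                        spacings = 1.5, base = default_scenario()) {
  if (!length(diameters) || !length(powers) || !length(offsets) ||
      !length(spacings))
    stop("parameter sets must be nonempty", call. = FALSE)
  des <- expand.grid(D = diameters, P = powers, L = offsets, H = spacings,
                     KEEP.OUT.ATTRS = FALSE)
  scs <- lapply(seq_len(nrow(des)), function(i)
    update_scenario(base,
                    actuator = actuator_spec(des$D[i], des$P[i]),
                    layout = sensor_layout(des$L[i], des$H[i],
                                           actuator_diameter = des$D[i])))
  attr(scs, "design") <- des
  scs
}

#' Piecewise-constant step flow profile
#'
#' @param levels Flow levels in mm/s, visited in order (default 3, 6, 9).
#' @param dwell Dwell time per level, seconds.
#' @return Function of time (s) returning a `tf_flow`; attributes `levels`,
#'   `dwell` and `duration` are set.
#' @export
step_flow_profile <- function(levels = c(3, 6, 9), dwell = 60) {
  if (dwell <= 0) stop("dwell must be positive", call. = FALSE)
  levels <- as.numeric(levels)
  f <- function(t) {
    i <- pmin(length(levels), floor(t / dwell) + 1L)
    flow_condition(levels[max(1L, i)])
  }
  attr(f, "levels") <- levels
  attr(f, "dwell") <- dwell
  attr(f, "duration") <- dwell * length(levels)
  f
}

#' Sensitivity sweep of the normalized readings
#'
#' Sweeps one physical parameter over a range, re-solves the steady
#' forward model at each point, and reports the maximum change of the
#' minimum-maximum normalized sensor reading across the six channels,
#' relative to the first (baseline) sweep point. Normalization is per
#' channel over the sweep: `S_N = (T - T_min)/(T_max - T_min)` with the
#' min/max taken over all sweep points of that channel (all channels
#' pooled), matching the min-max statistic used for such sweeps.
#'
#' @param parameter One of `"phantom_conductivity"`,
#'   `"fluid_conductivity"`, `"fluid_density"`, `"wall_thickness"`,
#'   `"channel_diameter"`, `"wall_stiffness"`, `"airflow"`.
#' @param range Length-2 numeric range to sweep.
#' @param n Number of sweep points (default 5).
#' @param sc Baseline scenario.
#' @return List with `delta_sn` (max |S_N - S_N(baseline)|), `sn` (matrix
#'   of normalized readings, points x channels), `values` (sweep values),
#'   `readings` (raw temperatures).
#' @export
sensitivity_sweep <- function(parameter, range, n = 5,
                              sc = default_scenario(vessel_depth = 1,
                                                    flow_speed = 1)) {
  supported <- c("phantom_conductivity", "fluid_conductivity",
                 "fluid_density", "wall_thickness", "channel_diameter",
                 "wall_stiffness", "airflow")
  if (!parameter %in% supported)
    stop("unknown parameter '", parameter, "'; supported: ",
         paste(supported, collapse = ", "), call. = FALSE)
  vals <- if (n == 1L) range[1] else seq(range[1], range[2], length.out = n)
  apply_param <- function(sc, v) {
    m <- sc$materials
    g <- sc$geometry
    switch(parameter,
      phantom_conductivity = {
        m$phantom <- material_properties("phantom", v,
                                         m$phantom$specific_heat,
                                         m$phantom$density)
        update_scenario(sc, materials = m)
      },
      fluid_conductivity = {
        m$fluid <- material_properties("fluid", v, m$fluid$specific_heat,
                                       m$fluid$density)
        update_scenario(sc, materials = m)
      },
      fluid_density = {
        m$fluid <- material_properties("fluid", m$fluid$conductivity,
                                       m$fluid$specific_heat, v)
        update_scenario(sc, materials = m)
      },
      wall_thickness = update_scenario(sc, geometry = phantom_geometry(
        g$block, g$channel_diameter, g$vessel_depth, v, sc$materials$wall)),
      channel_diameter = update_scenario(sc, geometry = phantom_geometry(
        g$block, v, g$vessel_depth, g$wall_thickness, g$wall_material)),
      # vessel wall stiffness has no coupling into the heat equations:
      # the scenario is returned unchanged (a pure heat-transfer model)
      wall_stiffness = sc,
      airflow = {
        # external airflow speed (m/s) mapped onto the convective
        # coefficient: h ramps 15 -> 40 W/(m^2 K) across 0.05 -> 0.2 m/s
        hmap <- 15 + (v - 0.05) / (0.2 - 0.05) * 25
        update_scenario(sc, ambient = ambient_conditions(
          sc$ambient$ambient, hmap, sc$ambient$bottom, sc$ambient$inlet))
      })
  }
  readings <- t(vapply(vals, function(v) steady_readings(apply_param(sc, v)),
                       numeric(6)))
  tmin <- min(readings); tmax <- max(readings)
  sn <- if (tmax > tmin) normalized_reading(readings, tmin, tmax)
  else readings * 0
  delta <- max(abs(sweep(sn, 2, sn[1, ], `-`)))
  list(parameter = parameter, values = vals, readings = readings,
       sn = sn, delta_sn = delta)
}
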