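# Forward model: grid construction, steady/transient solver physics,
# probing, and the analytic conduction oracle.

test_that("grid voxelization resolves channel and actuator geometry", {
  geo <- phantom_geometry(block = c(16, 12, 8), channel_diameter = 2.5,
                          vessel_depth = 1)
  act <- actuator_spec(3.5, 56.7)
  lay <- sensor_layout(3.5, 1.5)

  # fine spacing: rasterized disk of radius 5 cells ~ pi * 5^2 cells
  g <- build_grid(geo, act, lay, spacing = 0.25)
  expect_lt(abs(g$fluid_section_cells - pi * 5^2) / (pi * 5^2), 0.10)

  # default spacing still within the 10% cross-section tolerance
  g2 <- build_grid(geo, act, lay, spacing = 0.5)
  true_cells <- pi * 1.25^2 / 0.5^2
  expect_lt(abs(g2$fluid_section_cells - true_cells) / true_cells, 0.10)

  # actuator disk present, centred over the channel axis, one cell thick
  act_idx <- which(g2$material == 3L, arr.ind = TRUE)
  expect_gt(nrow(act_idx), 0)
  expect_length(unique(act_idx[, 3]), 1L)
  expect_equal(unique(act_idx[, 3]), g2$nz_solid + 1L)
  xs <- g2$x[act_idx[, 1]]
  expect_lt(abs(mean(xs)), 0.5)  # centred at x = 0 over the channel

  # vessel depth moves the topmost fluid cell by depth difference / spacing
  top_fluid_z <- function(d) {
    gg <- build_grid(phantom_geometry(block = c(16, 12, 8), vessel_depth = d),
                     act, lay, spacing = 0.5)
    max(which(apply(gg$material == 2L, 3, any)))
  }
  expect_equal(top_fluid_z(1) - top_fluid_z(2), 1 / 0.5)

  # too-coarse spacing is rejected
  expect_error(build_grid(geo, act, lay, spacing = 1.0), "too coarse")
})

test_that("power density matches the bench actuator figure", {
  expect_equal(round(power_density(56.7, 3.5), 2), 5.89)
  expect_equal(power_density(1, 2 / sqrt(pi)), 1.0)
  expect_equal(power_density(10, 4) / power_density(10, 2), 1 / 4)
  expect_error(power_density(10, 0), "positive")
})

test_that("normalized reading is the min-max statistic", {
  expect_equal(normalized_reading(25, 25, 37), 0)
  expect_equal(normalized_reading(37, 25, 37), 1)
  expect_equal(normalized_reading(31, 25, 37), 0.5)
  expect_error(normalized_reading(30, 25, 25), "degenerate")
})

test_that("zero-power homogeneous problem returns the uniform field", {
  f <- small_steady(power = 0)
  expect_true(all(abs(f$temperature - 25) < 1e-6))
  expect_equal(energy_balance_residual(f, small_scenario()$materials,
                                       small_scenario()$ambient,
                                       flow_condition(1), 0),
               0, tolerance = 1e-4)
})

test_that("steady field obeys the maximum principle and peaks under the actuator", {
  sc <- small_scenario(vessel_depth = 1, flow_speed = 1)
  f <- small_steady(sc)
  expect_true(all(f$temperature >= 25 - 1e-6))
  peak <- which(f$temperature == max(f$temperature), arr.ind = TRUE)[1, ]
  g <- f$grid
  # hottest cell lies within the actuator footprint planform
  expect_lte(sqrt(g$x[peak[1]]^2 + g$y[peak[2]]^2),
             sc$actuator$diameter / 2 + g$spacing)
})

test_that("zero flow gives up/downstream mirror symmetry", {
  sc <- small_scenario()
  f <- small_steady(sc, flow = flow_condition(0))
  r <- sensor_readings(f, sc$layout)
  expect_lt(abs(r["t_bot_dn"] - r["t_bot_up"]), 1e-4)
  expect_lt(abs(r["t_top_dn"] - r["t_top_up"]), 1e-4)
})

test_that("advection skews heat downstream, monotonically in flow", {
  sc <- small_scenario(vessel_depth = 1)
  reads <- lapply(c(1, 5, 10), function(fv)
    sensor_readings(small_steady(sc, flow = flow_condition(fv)), sc$layout))
  dnup <- vapply(reads, function(r) unname(r["t_bot_dn"] - r["t_bot_up"]),
                 numeric(1))
  expect_true(all(dnup > 0))          # downstream always warmer
  peaks <- vapply(c(1, 5, 10), function(fv)
    max(small_steady(sc, flow = flow_condition(fv))$temperature), numeric(1))
  expect_true(all(diff(peaks) <= 1e-6))  # peak temperature non-increasing in f
})

test_that("steady energy balance closes by surface integration", {
  sc <- small_scenario(vessel_depth = 1, flow_speed = 2)
  f <- small_steady(sc, flow = flow_condition(2))
  res <- energy_balance_residual(f, sc$materials, sc$ambient,
                                 flow_condition(2), sc$actuator$power)
  expect_lt(res, 0.02)
  # zero-flow variant closes too
  f0 <- small_steady(sc, flow = flow_condition(0))
  expect_lt(energy_balance_residual(f0, sc$materials, sc$ambient,
                                    flow_condition(0), sc$actuator$power),
            0.02)
})

test_that("1D two-layer conduction matches the closed-form slab solution", {
  # homogenise: fluid and actuator take the phantom's properties, no
  # heating -> pure vertical conduction through phantom + air with a
  # Robin top condition; the exact profile is piecewise linear with the
  # flux set by the series resistance
  mats <- default_materials()
  mats$fluid <- material_properties("fluid", mats$phantom$conductivity,
                                    mats$phantom$specific_heat,
                                    mats$phantom$density)
  # the unheated actuator cells take the air properties so the gap layer
  # is uniform and the two-layer closed form applies exactly
  mats$actuator <- mats$air
  amb <- ambient_conditions(ambient = 20, h = 15, bottom = 30, inlet = 30)
  sc <- small_scenario()
  solid <- phantom_geometry(block = c(16, 12, 8), channel_diameter = 0,
                            vessel_depth = 1.5)
  g <- build_grid(solid, sc$actuator, sc$layout, sc$spacing)
  f <- solve_steady(g, mats, amb, flow_condition(0), 0)

  k1 <- mats$phantom$conductivity; k2 <- mats$air$conductivity
  L1 <- g$nz_solid * g$spacing * 1e-3
  L2 <- (g$nz - g$nz_solid) * g$spacing * 1e-3
  q <- (amb$bottom - amb$ambient) / (L1 / k1 + L2 / k2 + 1 / amb$h)
  exact <- function(z_mm) {
    z <- z_mm * 1e-3
    if (z <= 0) amb$bottom - q * (z + L1) / k1
    else amb$bottom - q * L1 / k1 - q * z / k2
  }
  for (z in c(-7, -4, -1, 0.5, 1.5)) {
    got <- probe_temperature(f, c(1.2, -0.8, z))
    want <- exact(z)
    expect_lt(abs(got - want) / abs(want - amb$ambient + 1e-12), 0.005)
  }
})

test_that("probe interpolation is exact at nodes and for linear fields", {
  sc <- small_scenario()
  g <- small_grid(sc)
  a <- 0.7
  lin <- array(rep(25 + a * g$z, each = g$nx * g$ny),
               dim = c(g$nx, g$ny, g$nz))
  f <- structure(list(temperature = lin, grid = g, steady = TRUE,
                      relres = 0, time = NA_real_), class = "thermal_field")
  # node-exact
  expect_equal(probe_temperature(f, c(g$x[3], g$y[4], g$z[5])),
               lin[3, 4, 5])
  # linear reproduction between nodes
  zq <- g$z[5] + 0.3 * sc$spacing
  expect_equal(probe_temperature(f, c(g$x[3], g$y[4], zq)), 25 + a * zq,
               tolerance = 1e-12)
  expect_error(probe_temperature(f, c(100, 0, 0)), "outside")
})

test_that("six-channel readings follow the fixed channel order", {
  sc <- small_scenario()
  f0 <- small_steady(sc, power = 0)
  r0 <- sensor_readings(f0, sc$layout)
  expect_named(r0, channel_names())
  expect_true(all(abs(r0 - 25) < 1e-6))
  # with flow: downstream exceeds upstream in the bottom layer, and
  # bottom-layer channels run hotter than their top-layer counterparts
  f1 <- small_steady(sc, flow = flow_condition(2))
  r1 <- sensor_readings(f1, sc$layout)
  expect_gt(r1["t_bot_dn"], r1["t_bot_up"])
  expect_gt(r1["t_bot_dn"], r1["t_top_dn"])
  expect_gt(r1["t_bot_ref"], r1["t_top_ref"])
})

test_that("transient stepping reaches the steady solution and stays put at zero power", {
  sc <- small_scenario(vessel_depth = 1, flow_speed = 3)
  g <- small_grid(sc)
  tr <- solve_transient(g, sc$materials, sc$ambient, flow_condition(3),
                        sc$actuator$power, duration = 400, dt = 10,
                        keep_every = 40)
  st <- solve_steady(g, sc$materials, sc$ambient, flow_condition(3),
                     sc$actuator$power)
  fin <- tr$fields[[length(tr$fields)]]
  expect_lt(max(abs(fin$temperature - st$temperature)), 0.05)

  tr0 <- solve_transient(g, sc$materials, sc$ambient, flow_condition(3),
                         0, duration = 30, dt = 10)
  for (f in tr0$fields)
    expect_true(all(abs(f$temperature - 25) < 1e-6))
})

test_that("downstream probe settles more slowly over deeper vessels", {
  # step response 3 -> 6 mm/s from the level-1 equilibrium
  settle <- function(depth) {
    sc <- small_scenario(vessel_depth = depth, flow_speed = 3)
    g <- small_grid(sc)
    init <- solve_steady(g, sc$materials, sc$ambient, flow_condition(3),
                         sc$actuator$power)
    tr <- solve_transient(g, sc$materials, sc$ambient, flow_condition(6),
                          sc$actuator$power, duration = 40, dt = 1,
                          initial_temperature = init)
    r <- vapply(tr$fields,
                function(f) sensor_readings(f, sc$layout)[["t_bot_dn"]],
                numeric(1))
    v0 <- sensor_readings(init, sc$layout)[["t_bot_dn"]]
    v1 <- r[length(r)]
    th <- v0 + 0.9 * (v1 - v0)
    tr$times[which(if (v1 > v0) r >= th else r <= th)[1]]
  }
  expect_gt(settle(2), settle(1))
})
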