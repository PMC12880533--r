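# Shared fixtures: a reduced phantom block keeps unit-test solves fast
# while preserving all physics (the full 30 x 20 x 10 mm block is used by
# the acceptance suite only). Steady solves are memoised package-wide, so
# repeated helper calls across test files reuse one solve.

small_scenario <- function(vessel_depth = 1.5, flow_speed = 1, ...) {
  scenario(geometry = phantom_geometry(block = c(16, 12, 8),
                                       vessel_depth = vessel_depth),
           flow = flow_condition(flow_speed), ...)
}

small_grid <- function(sc = small_scenario()) {
  build_grid(sc$geometry, sc$actuator, sc$layout, sc$spacing)
}

small_steady <- function(sc = small_scenario(), power = sc$actuator$power,
                         flow = sc$flow) {
  g <- small_grid(sc)
  solve_steady(g, sc$materials, sc$ambient, flow, power)
}

# compact labeled dataset on the reduced block (12 conditions)
small_dataset <- function(replicates = 15, noise = noise_model(seed = 0),
                          mode = "temperature") {
  cg <- condition_grid(depths = c(1, 1.5, 2), flows = c(1, 4, 7, 10),
                       replicates = replicates)
  list(grid = cg,
       data = generate_dataset(cg, small_scenario(), noise, mode = mode))
}

# quick training configuration for unit tests (accuracy-critical runs use
# the package default)
quick_cfg <- function(epochs = 150, seed = 0L) {
  training_config(epochs = epochs, seed = seed)
}
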