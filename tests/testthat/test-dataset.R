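# Synthetic benchtop protocol: grids, datasets, folds, design sweeps,
# sensitivity sweeps.

test_that("condition grid mirrors the benchtop protocol bookkeeping", {
  cg <- condition_grid()
  expect_equal(nrow(cg$conditions), 30L)
  expect_equal(cg$replicates, 50L)
  expect_false(anyDuplicated(cg$conditions[, c("depth", "flow")]) > 0)
  # expanded protocol
  cg9 <- condition_grid(replicates = 300)
  expect_equal(nrow(cg9$conditions) * cg9$replicates, 9000L)
  expect_error(condition_grid(depths = c(-1, 1)), "positive")
})

test_that("dataset generation has the invariant row count and reproducibility", {
  sd1 <- small_dataset(replicates = 3)
  expect_s3_class(sd1$data, "labeled_dataset")
  expect_equal(nrow(sd1$data), nrow(sd1$grid$conditions) * 3L)
  # labels match their condition
  expect_true(all(sd1$data$condition_id ==
                    sprintf("d%g_f%g", sd1$data$d_set_mm, sd1$data$f_set_mm_s)))
  expect_true(all(is.finite(as.matrix(
    sd1$data[, attr(sd1$data, "feature_names")]))))
  # bit-for-bit reproducible under the same seed
  sd2 <- small_dataset(replicates = 3)
  expect_identical(sd1$data, sd2$data)
  # zero noise duplicates feature rows within a condition
  z <- generate_dataset(condition_grid(depths = 1.5, flows = 2,
                                       replicates = 2),
                        small_scenario(), noise_model(sd = 0, seed = 1))
  expect_equal(unname(as.numeric(z[1, -(1:3)])),
               unname(as.numeric(z[2, -(1:3)])))
})

test_that("bottom differential grows monotonically with flow on the noiseless grid", {
  z <- generate_dataset(condition_grid(depths = 1, flows = c(1, 4, 7, 10),
                                       replicates = 1),
                        small_scenario(), noise_model(sd = 0, seed = 1))
  dnup <- z$t_bot_dn - z$t_bot_up
  expect_true(all(dnup > 0))
  # strictly monotone (decreasing) differential: the flow signal is
  # injective over the benchtop range
  expect_true(all(diff(dnup) < 0) || all(diff(dnup) > 0))
})

test_that("grouped k-fold partitions conditions evenly and reproducibly", {
  cg <- condition_grid()
  folds <- grouped_kfold(cg, 5, seed = 0)
  asg <- folds$assignment
  expect_setequal(asg$condition_id, cg$conditions$condition_id)
  expect_equal(sort(unique(asg$fold)), 1:5)
  sizes <- table(asg$fold)
  expect_true(max(sizes) - min(sizes) <= 1)
  expect_true(all(sizes == 6))          # 30 conditions in 5 groups of 6
  # held-out rows per fold with 50 replicates = 6 x 50 = 300
  expect_equal(unname(sizes[1] * cg$replicates), 300)
  # reproducible; different seed reshuffles
  expect_identical(asg, grouped_kfold(cg, 5, seed = 0)$assignment)
  expect_false(identical(asg, grouped_kfold(cg, 5, seed = 1)$assignment))
  expect_error(grouped_kfold(cg, 31), "exceeds")
})

test_that("design grids enumerate the bench parameter studies", {
  dp <- design_grid(diameters = c(2, 3.5, 5.6), powers = c(37.8, 56.7, 75.6))
  expect_length(dp, 9L)
  des <- attr(dp, "design")
  # sweeping (D, P) leaves the geometry at its defaults
  expect_true(all(des$L == 3.5) && all(des$H == 1.5))
  lh <- design_grid(offsets = c(2, 3.5, 5.6), spacings = c(1, 1.5, 2))
  expect_length(lh, 9L)
  # sweeping (L, H) fixes D = 3.5 mm and P = 56.7 mW
  expect_true(all(attr(lh, "design")$D == 3.5))
  expect_true(all(attr(lh, "design")$P == 56.7))
  expect_error(design_grid(diameters = numeric(0)), "nonempty")
})

test_that("step flow profiles are piecewise constant over the dwell blocks", {
  p1 <- step_flow_profile(levels = 5, dwell = 60)
  expect_equal(p1(10)$speed, 5)
  expect_equal(p1(59.9)$speed, 5)
  p3 <- step_flow_profile(levels = c(3, 6, 9), dwell = 60)
  expect_equal(attr(p3, "duration"), 180)
  expect_equal(p3(60 + 1e-6)$speed, 6)   # level 2 right after the first dwell
  expect_equal(p3(179)$speed, 9)
  expect_error(step_flow_profile(dwell = 0), "dwell")
})

test_that("sensitivity sweeps honour coupling and degenerate cases", {
  sc <- small_scenario(vessel_depth = 1, flow_speed = 1)
  # single sweep point: Delta S_N = 0 by construction
  s1 <- sensitivity_sweep("fluid_conductivity", c(0.6, 0.6), n = 1, sc = sc)
  expect_equal(s1$delta_sn, 0)
  # wall stiffness has no thermal coupling: all sweep points identical
  sw <- sensitivity_sweep("wall_stiffness", c(130, 180), n = 3, sc = sc)
  expect_equal(sw$delta_sn, 0)
  # fluid conductivity does couple
  sk <- sensitivity_sweep("fluid_conductivity", c(0.5, 0.6), n = 3, sc = sc)
  expect_gt(sk$delta_sn, 0)
  expect_error(sensitivity_sweep("viscosity", c(1, 2)), "supported")
})
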