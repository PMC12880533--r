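# Inversion network and the grouped-CV evaluation protocol.

test_that("rmse is the root mean squared deviation", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(5, 2), 3)
  expect_error(rmse(1:3, 1:2), "length mismatch")
})

test_that("regressor fits, predicts and honours its contracts", {
  set.seed(1)
  n <- 400
  X <- matrix(runif(n * 6), n, 6)
  colnames(X) <- channel_names()
  Y <- cbind(flow = 2 + 5 * X[, 1] - X[, 2], depth = 1 + X[, 3])
  m <- fit_regressor(list(X = X, Y = Y), regressor_spec(), quick_cfg())
  # training loss decreases
  expect_lt(tail(m$losses, 1), m$losses[1])
  p <- predict(m, X)
  expect_true(all(is.finite(p)))
  expect_lt(rmse(Y[, 1], p[, "flow"]), 0.2)
  # determinism: same seed, same predictions
  m2 <- fit_regressor(list(X = X, Y = Y), regressor_spec(), quick_cfg())
  expect_identical(predict(m2, X), p)
  # batch and single-row prediction agree
  expect_equal(unname(predict(m, X[7, ])), unname(p[7, , drop = FALSE]),
               tolerance = 1e-10)
  # width contract
  expect_error(predict(m, X[, 1:4]), "width mismatch")
  # constant-target fit collapses to the label
  Xc <- X[1:40, ]; Yc <- cbind(flow = rep(3, 40), depth = rep(1.5, 40))
  mc <- fit_regressor(list(X = Xc, Y = Yc), regressor_spec(),
                      quick_cfg(500))
  pc <- predict(mc, Xc)
  expect_lt(max(abs(pc[, "flow"] - 3)), 0.1)
  expect_lt(max(abs(pc[, "depth"] - 1.5)), 0.1)
})

test_that("grouped CV tests every row exactly once and guards leakage", {
  sd <- small_dataset(replicates = 6)
  folds <- grouped_kfold(sd$grid, 3, seed = 0)
  rep <- crossval_evaluate(sd$data, folds, regressor_spec(),
                           quick_cfg(100))
  expect_equal(nrow(rep$predictions), nrow(sd$data))
  # each condition tested in exactly one fold
  by_cond <- tapply(rep$predictions$fold, rep$predictions$condition_id,
                    function(f) length(unique(f)))
  expect_true(all(by_cond == 1))
  expect_gte(rep$q95_f, 0)
  expect_gte(rep$q95_d, median(abs(rep$predictions$d_meas -
                                     rep$predictions$d_set)))
  # incomplete fold coverage is rejected
  bad <- folds
  bad$assignment <- bad$assignment[-1, ]
  expect_error(crossval_evaluate(sd$data, bad, regressor_spec(),
                                 quick_cfg(10)), "cover")
})

test_that("pooled CV metrics are invariant to fold enumeration order", {
  sd <- small_dataset(replicates = 4)
  folds <- grouped_kfold(sd$grid, 3, seed = 2)
  r1 <- crossval_evaluate(sd$data, folds, regressor_spec(), quick_cfg(60))
  # relabel folds 1,2,3 -> 3,1,2: same membership, different enumeration
  folds2 <- folds
  folds2$assignment$fold <- c(3L, 1L, 2L)[folds2$assignment$fold]
  r2 <- crossval_evaluate(sd$data, folds2, regressor_spec(), quick_cfg(60))
  expect_equal(r1$rmse_f, r2$rmse_f, tolerance = 1e-12)
  expect_equal(r1$rmse_d, r2$rmse_d, tolerance = 1e-12)
  expect_equal(r1$q95_f, r2$q95_f, tolerance = 1e-12)
})

test_that("a perfect oracle predictor yields zero pooled RMSE", {
  # injects truth as predictions through the report arithmetic
  expect_equal(rmse(c(1, 5, 9), c(1, 5, 9)), 0)
  sd <- small_dataset(replicates = 2, noise = noise_model(sd = 0, seed = 0))
  # with zero noise and a model trained until interpolation on all data,
  # training rows are recovered nearly exactly
  m <- fit_regressor(sd$data, regressor_spec(), training_config(epochs = 800))
  p <- predict(m, sd$data)
  expect_lt(rmse(sd$data$f_set_mm_s, p[, "flow"]), 0.12)
  expect_lt(rmse(sd$data$d_set_mm, p[, "depth"]), 0.05)
})

test_that("dual-layer features recover depth strictly better than bottom-only", {
  sd <- small_dataset(replicates = 15)
  folds <- grouped_kfold(sd$grid, 3, seed = 0)
  ab <- layer_ablation(sd$data, folds, regressor_spec(), quick_cfg(200))
  expect_lt(ab$full$rmse_d, ab$bottom_only$rmse_d)
  # flow recovery comparable within the fold confidence intervals
  expect_lt(ab$full$fold_mean_f - ab$bottom_only$fold_mean_f,
            ab$full$fold_ci_f + ab$bottom_only$fold_ci_f + 1e-9)
})

test_that("recovery error shrinks as sensor noise vanishes", {
  cg <- condition_grid(depths = c(1, 2), flows = c(1, 4, 7, 10),
                       replicates = 8)
  folds <- grouped_kfold(cg, 2, seed = 0)
  r_hi <- crossval_evaluate(
    generate_dataset(cg, small_scenario(), noise_model(sd = 0.05, seed = 3)),
    folds, regressor_spec(), quick_cfg(120))
  r_lo <- crossval_evaluate(
    generate_dataset(cg, small_scenario(), noise_model(sd = 0.002, seed = 3)),
    folds, regressor_spec(), quick_cfg(120))
  expect_lt(r_lo$rmse_f, r_hi$rmse_f + r_hi$fold_ci_f + 1e-9)
})

test_that("dynamic tracking follows step flow changes after settling", {
  # model trained at the step levels on the reduced block; the shallow
  # vessel settles within a few seconds so a 40 s dwell is ample
  cg <- condition_grid(depths = c(1, 1.5, 2), flows = c(1, 3, 6, 9),
                       replicates = 12)
  ds <- generate_dataset(cg, small_scenario(), noise_model(seed = 0))
  m <- fit_regressor(ds, regressor_spec(), quick_cfg(400))
  dt <- dynamic_tracking_eval(m, small_scenario(vessel_depth = 1),
                              profile = step_flow_profile(levels = c(3, 6),
                                                          dwell = 40),
                              dt = 2)
  expect_equal(nrow(dt$per_step), 2L)
  expect_true(all(abs(dt$per_step$post_settling_err) < 0.3))
})
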