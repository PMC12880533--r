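# Cardio generator, Bland-Altman agreement and the flow+PPG fusion model.

test_that("cardio records satisfy the generator invariants", {
  cfg <- cardio_config(valsalva_onset = 120, seed = 4)
  recs <- generate_cardio_dataset(cfg, n_records = 2, duration = 400)
  expect_length(recs, 2L)
  r <- recs[[1]]
  expect_true(all(r$sp > r$dp))                       # SP > DP everywhere
  expect_equal(length(r$ppg), 128 * length(r$flow))   # 128 Hz vs 1 Hz
  expect_equal(length(r$sp), length(r$time))
  # determinism under the seed; a different seed differs
  recs2 <- generate_cardio_dataset(cfg, n_records = 2, duration = 400)
  expect_identical(recs[[1]]$sp, recs2[[1]]$sp)
  recs3 <- generate_cardio_dataset(cardio_config(valsalva_onset = 120,
                                                 seed = 5), 2, 400)
  expect_false(identical(recs[[1]]$sp, recs3[[1]]$sp))
  # timing validation
  expect_error(generate_cardio_dataset(cardio_config(valsalva_onset = 500),
                                       1, 600), "exceeds")
})

test_that("the maneuver window shows the configured four-phase structure", {
  amp <- c(15, -20, -15, 10)
  t <- seq(0, 599)
  off <- thermoflow:::valsalva_offset(t, 200, 140, amp)
  # quiescent outside the maneuver and its recovery tail
  expect_true(all(abs(off[t < 195]) < 1e-9))
  # each phase window carries the configured sign
  p <- 200 + 140 * c(0, 0.10, 0.60, 0.75, 0.90)
  mid <- function(a, b) mean(off[t > a + 2 & t < b - 2])
  expect_gt(mid(p[1] + 4, p[2]), 0)   # (i) elevation
  expect_lt(mid(p[2] + 2, p[3] - 4), 0)   # (ii) compensatory decrease
  expect_lt(mid(p[3] + 2, p[4] - 4), 0)   # (iii) release drop
  expect_gt(mid(p[4] + 2, p[5] - 2), 0)   # (iv) overshoot
  # zero amplitudes keep the pressure at baseline
  cfg0 <- cardio_config(phase_offsets = c(0, 0, 0, 0),
                        pressure_noise_sd = 0, valsalva_onset = 120)
  r0 <- generate_cardio_dataset(cfg0, 1, 400)[[1]]
  # only the slow drift remains; remove it via the paired difference
  expect_lt(max(r0$sp - r0$dp) - min(r0$sp - r0$dp), 1.5)
})

test_that("bland_altman reproduces the closed-form cases", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0); expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)

  ba5 <- bland_altman(c(10, 20, 30), c(15, 25, 35))
  expect_equal(ba5$bias, 5)
  expect_equal(ba5$loa_low, 5); expect_equal(ba5$loa_high, 5)

  ref <- c(0, 0, 0); mea <- c(-2, 0, 2)
  ba <- bland_altman(ref, mea)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 2)
  expect_equal(ba$loa_low, -3.92)
  expect_equal(ba$loa_high, 3.92)
  # LoA bracket the bias by construction
  expect_lte(ba$loa_low, ba$bias); expect_gte(ba$loa_high, ba$bias)

  # translation equivariance
  bac <- bland_altman(ref, mea + 7)
  expect_equal(bac$bias, ba$bias + 7)
  expect_equal(bac$loa_low, ba$loa_low + 7)
  expect_equal(bac$loa_high, ba$loa_high + 7)
  expect_error(bland_altman(1, 1), "at least two")
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("error_reduction handles equal, halved and degenerate errors", {
  expect_equal(error_reduction(4, 4), 0)
  expect_equal(error_reduction(4, 2), 50)
  expect_true(is.na(error_reduction(0, 1)))
  expect_equal(error_reduction(c(sp = 10, dp = 5), c(sp = 5, dp = 4)),
               c(sp = 50, dp = 20))
})

test_that("constant-pressure records are fitted by both modes", {
  cfg <- cardio_config(phase_offsets = c(0, 0, 0, 0), pressure_noise_sd = 0,
                       flow_noise_sd = 0.01, ppg_noise_sd = 0.005,
                       valsalva_onset = 60, valsalva_duration = 10, seed = 2)
  recs <- generate_cardio_dataset(cfg, 3, 200)
  # strip the drift to make the pressure truly constant
  recs <- lapply(recs, function(r) {
    r$sp <- rep(120, length(r$sp)); r$dp <- rep(80, length(r$dp)); r
  })
  for (mode in c("ppg_only", "fused")) {
    m <- fit_bp_model(recs[1:2], mode)
    p <- predict(m, recs[[3]])
    expect_lt(rmse(p$sp_ref, p$sp_pred), 0.5)
    expect_lt(rmse(p$dp_ref, p$dp_pred), 0.5)
  }
})

test_that("ppg_only ignores the flow channel by construction", {
  recs <- generate_cardio_dataset(cardio_config(valsalva_onset = 100, seed = 3),
                                  3, 300)
  m <- fit_bp_model(recs[1:2], "ppg_only")
  test_rec <- recs[[3]]
  p1 <- predict(m, test_rec)
  test_rec$flow <- rev(test_rec$flow)   # scramble the flow channel
  p2 <- predict(m, test_rec)
  expect_identical(p1$sp_pred, p2$sp_pred)
  # whereas the fused model does use it
  mf <- fit_bp_model(recs[1:2], "fused")
  q1 <- predict(mf, recs[[3]])
  tr2 <- recs[[3]]; tr2$flow <- rev(tr2$flow)
  q2 <- predict(mf, tr2)
  expect_false(identical(q1$sp_pred, q2$sp_pred))
})

test_that("flow fusion helps when flow is informative and not otherwise", {
  # majority over 5 generator seeds: fused beats PPG-only on held-out
  # records when the flow-pressure coupling is active
  wins <- 0L
  for (s in 1:5) {
    demo <- run_bp_demo(cardio_config(valsalva_onset = 120, seed = s),
                        n_records = 5, n_test = 2, duration = 400, seed = s)
    if (demo$rmse["fused", "sp"] < demo$rmse["ppg_only", "sp"] &&
        demo$rmse["fused", "dp"] < demo$rmse["ppg_only", "dp"])
      wins <- wins + 1L
  }
  expect_gte(wins, 3L)

  # with the coupling switched off the two modes agree closely
  d0 <- run_bp_demo(cardio_config(coupling_gain = 0, valsalva_onset = 120,
                                  seed = 1),
                    n_records = 5, n_test = 2, duration = 400, seed = 1)
  rel <- abs(d0$rmse["fused", ] - d0$rmse["ppg_only", ]) /
    d0$rmse["ppg_only", ]
  expect_true(all(rel < 0.15))
})

test_that("fusion narrows the Bland-Altman limits over the maneuver window", {
  demo <- run_bp_demo(cardio_config(valsalva_onset = 120, seed = 0),
                      n_records = 5, n_test = 2, duration = 400, seed = 0)
  width <- function(a) a$loa_high - a$loa_low
  expect_lt(width(demo$agreement$sp_fused), width(demo$agreement$sp_ppg))
  expect_lt(width(demo$agreement$dp_fused), width(demo$agreement$dp_ppg))
})
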