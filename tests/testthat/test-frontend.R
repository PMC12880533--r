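# Signal chain: NTC model, Wheatstone bridge, smoothing, decimation and
# feature assembly.

test_that("thermistor follows the beta model", {
  expect_equal(thermistor_resistance(25), 10000)
  # independently evaluated closed form at 50 C
  m <- thermistor_model(r0 = 10e3, t0 = 298.15, beta = 3380)
  want <- 10e3 * exp(3380 * (1 / 323.15 - 1 / 298.15))
  expect_equal(thermistor_resistance(50, m), want)
  expect_equal(round(want), 4160, tolerance = 1e-3)  # ~4.16 kOhm
  # NTC: strictly decreasing in temperature
  ts <- seq(0, 80, by = 5)
  expect_true(all(diff(thermistor_resistance(ts, m)) < 0))
  expect_error(thermistor_resistance(-300), "absolute zero")
})

test_that("bridge differential is balanced, antisymmetric and rejects common mode", {
  m <- thermistor_model(); cfg <- bridge_config()
  expect_equal(bridge_differential(25, 25, m, cfg), 0)
  # hand-evaluated divider expression at gain 1, Vs 3.3, R = R0
  cfg1 <- bridge_config(supply = 3.3, r_fixed = 10e3, gain = 1)
  rs <- thermistor_resistance(30, m)
  want <- 3.3 * (rs / (rs + 10e3) - 0.5)
  expect_equal(bridge_differential(30, 25, m, cfg1), want)
  # antisymmetry
  expect_equal(bridge_differential(30, 25, m, cfg),
               -bridge_differential(25, 30, m, cfg))
  # equal Delta-T at shifted common temperature differs only through the
  # thermistor nonlinearity (bounded), and a common-mode shift moves the
  # output far less than shifting one arm alone
  v1 <- bridge_differential(30, 25, m, cfg1)
  v2 <- bridge_differential(35, 30, m, cfg1)
  expect_lt(abs(v2 - v1), 0.25 * abs(v1))
  dm_common <- abs(bridge_differential(30 + 5, 25 + 5, m, cfg1) - v1)
  dm_single <- abs(bridge_differential(30 + 5, 25, m, cfg1) - v1)
  expect_lt(dm_common, 0.3 * dm_single)
})

test_that("EMA filter has unit DC gain and the stated recursion", {
  x <- c(0, 1, 1, 1, 1)
  y <- ema_filter(x, alpha = 0.05)
  expect_equal(y[1], 0)
  expect_equal(y[2], 0.05)
  expect_equal(y[3], 0.0975)
  # constant input is a fixed point
  expect_equal(ema_filter(rep(3.7, 50), 0.05), rep(3.7, 50))
  # alpha = 1 is the identity
  z <- rnorm(20)
  expect_equal(ema_filter(z, 1), z)
  expect_error(ema_filter(z, 0), "alpha")
  # linearity per channel
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(ema_filter(2 * a + 3 * b, 0.05),
               2 * ema_filter(a, 0.05) + 3 * ema_filter(b, 0.05))
})

test_that("decimation takes non-overlapping 1 s block means", {
  st <- sensor_stream(matrix(rep(4.2, 20 * 6), 20, 6), rate = 20)
  out <- decimate_to_1hz(st)
  expect_equal(nrow(out$data), 1L)
  expect_true(all(out$data == 4.2))

  st2 <- sensor_stream(matrix(rep(1:20, 6), 20, 6), rate = 20)
  expect_equal(unname(decimate_to_1hz(st2)$data[1, 1]), 10.5)

  # trailing partial block dropped: 39 samples -> exactly one output
  st3 <- sensor_stream(matrix(rnorm(39 * 6), 39, 6), rate = 20)
  out3 <- decimate_to_1hz(st3)
  expect_equal(nrow(out3$data), 1L)
  # block-mean conservation over consumed samples
  expect_equal(unname(out3$data[1, ]), unname(colMeans(st3$data[1:20, ])))

  expect_warning(decimate_to_1hz(sensor_stream(matrix(rnorm(6 * 6), 6, 6),
                                               rate = 20)),
                 "fewer than 20")
  expect_error(decimate_to_1hz(sensor_stream(matrix(1, 10, 6), rate = 10)),
               "20 Hz")
})

test_that("feature assembly is deterministic, ordered and mode-aware", {
  r <- setNames(c(28.6, 29.7, 29.5, 27.6, 29.9, 29.8), channel_names())
  # zero noise: features equal the steady readings (temperature mode)
  f0 <- assemble_features(r, noise_sd = 0)
  expect_equal(as.numeric(f0), as.numeric(r), tolerance = 1e-12)
  # determinism under a fixed seed; variation within a few noise SDs
  set.seed(7); f1 <- assemble_features(r, noise_sd = 0.01)
  set.seed(7); f2 <- assemble_features(r, noise_sd = 0.01)
  set.seed(8); f3 <- assemble_features(r, noise_sd = 0.01)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  expect_true(all(abs(f3 - r) < 3 * 0.01))
  # channel-order contract
  bad <- r; names(bad)[1:2] <- names(bad)[2:1]
  expect_error(assemble_features(bad), "fixed channel order")
  # widths per mode
  expect_length(assemble_features(r, noise_sd = 0, mode = "compensated"), 4L)
  expect_length(assemble_features(r, noise_sd = 0, mode = "bridge"), 4L)
  # compensated mode cancels a uniform ambient shift exactly
  fc <- assemble_features(r, noise_sd = 0, mode = "compensated")
  fc5 <- assemble_features(r + 5, noise_sd = 0, mode = "compensated")
  expect_equal(fc, fc5, tolerance = 1e-12)
  # bridge mode shifts differential features by well under 10% of a
  # +5 C common-mode shift
  fb <- assemble_features(r, noise_sd = 0, mode = "bridge")
  fb5 <- assemble_features(r + 5, noise_sd = 0, mode = "bridge")
  expect_true(all(abs(fb5 - fb) < 0.1 * 5))
})
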