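# Evaluation protocol: grouped cross-validation, RMSE and 95% error
# quantiles, ambient robustness, dynamic tracking, single- vs dual-layer
# ablation.

#' Root mean squared error
#'
#' @param truth,estimate Numeric vectors of equal length (n >= 1).
#' @return `sqrt(mean((truth - estimate)^2))`, in the units of the inputs.
#' @export
rmse <- function(truth, estimate) {
  if (length(truth) != length(estimate))
    stop("length mismatch between truth and estimate", call. = FALSE)
  if (length(truth) < 1L) stop("need at least one value", call. = FALSE)
  sqrt(mean((truth - estimate)^2))
}

#' Grouped cross-validated evaluation
#'
#' Trains the regressor on K-1 condition groups and tests on the held-out
#' group, rotating so every condition (hence every row) is tested exactly
#' once; pools all test predictions for the headline metrics and also
#' reports fold-level dispersion.
#'
#' @param data A `labeled_dataset`.
#' @param folds A `fold_assignment` covering the dataset's conditions.
#' @param spec,cfg Regressor architecture and training configuration.
#' @return An `evaluation_report`: pooled `rmse_f` (mm/s), `rmse_d` (mm),
#'   95% absolute-error quantiles `q95_f`, `q95_d`, per-condition and
#'   per-flow breakdowns, fold-level RMSEs with mean +/- half-width of the
#'   95% confidence interval, and the pooled `predictions` data frame.
#' @export
crossval_evaluate <- function(data, folds, spec = regressor_spec(),
                              cfg = training_config()) {
  stopifnot(inherits(data, "labeled_dataset"), inherits(folds, "fold_assignment"))
  asg <- folds$assignment
  if (!all(data$condition_id %in% asg$condition_id))
    stop("fold assignment does not cover all conditions", call. = FALSE)
  fold_of <- asg$fold[match(data$condition_id, asg$condition_id)]
  preds <- vector("list", folds$k)
  fold_rmse_f <- numeric(folds$k)
  fold_rmse_d <- numeric(folds$k)
  for (kk in seq_len(folds$k)) {
    te <- fold_of == kk
    tr <- !te
    # leakage guard: a condition must never appear on both sides
    if (length(intersect(unique(data$condition_id[tr]),
                         unique(data$condition_id[te]))))
      stop("leakage: a condition appears in both train and test of a fold",
           call. = FALSE)
    train <- data[tr, , drop = FALSE]
    test <- data[te, , drop = FALSE]
    attributes(train)[c("feature_names", "mode", "class")] <-
      attributes(data)[c("feature_names", "mode", "class")]
    attributes(test)[c("feature_names", "mode", "class")] <-
      attributes(data)[c("feature_names", "mode", "class")]
    model <- fit_regressor(train, spec, cfg)
    ph <- predict(model, test)
    preds[[kk]] <- data.frame(condition_id = test$condition_id,
                              fold = kk,
                              f_set = test$f_set_mm_s, d_set = test$d_set_mm,
                              f_meas = ph[, "flow"], d_meas = ph[, "depth"])
    fold_rmse_f[kk] <- rmse(test$f_set_mm_s, ph[, "flow"])
    fold_rmse_d[kk] <- rmse(test$d_set_mm, ph[, "depth"])
  }
  pl <- do.call(rbind, preds)
  err_f <- pl$f_meas - pl$f_set
  err_d <- pl$d_meas - pl$d_set
  per_cond <- aggregate(cbind(abs_err_f = abs(err_f), abs_err_d = abs(err_d)),
                        by = list(condition_id = pl$condition_id), FUN = mean)
  per_flow <- do.call(rbind, lapply(split(pl, pl$f_set), function(g)
    data.frame(f_set = g$f_set[1],
               rmse_f = rmse(g$f_set, g$f_meas),
               rmse_d = rmse(g$d_set, g$d_meas))))
  ci_half <- function(v) {
    if (length(v) < 2) return(NA_real_)
    qt(0.975, length(v) - 1) * sd(v) / sqrt(length(v))
  }
  structure(list(
    rmse_f = rmse(pl$f_set, pl$f_meas),
    rmse_d = rmse(pl$d_set, pl$d_meas),
    q95_f = unname(quantile(abs(err_f), 0.95)),
    q95_d = unname(quantile(abs(err_d), 0.95)),
    err_correlation = if (sd(err_f) > 0 && sd(err_d) > 0)
      cor(err_f, err_d) else NA_real_,
    fold_rmse_f = fold_rmse_f, fold_rmse_d = fold_rmse_d,
    fold_mean_f = mean(fold_rmse_f), fold_ci_f = ci_half(fold_rmse_f),
    fold_mean_d = mean(fold_rmse_d), fold_ci_d = ci_half(fold_rmse_d),
    per_condition = per_cond, per_flow = per_flow,
    predictions = pl, n = nrow(pl)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d pooled test predictions\n", x$n))
  cat(sprintf("  RMSE_f = %.4f mm/s (folds %.4f +/- %.4f)\n",
              x$rmse_f, x$fold_mean_f, x$fold_ci_f))
  cat(sprintf("  RMSE_d = %.4f mm   (folds %.4f +/- %.4f)\n",
              x$rmse_d, x$fold_mean_d, x$fold_ci_d))
  cat(sprintf("  95%% |err|: flow %.4f mm/s, depth %.4f mm\n",
              x$q95_f, x$q95_d))
  cat(sprintf("  max per-flow RMSE_d = %.4f mm; err corr = %.3f\n",
              max(x$per_flow$rmse_d), x$err_correlation))
  invisible(x)
}

#' Ambient-temperature robustness evaluation
#'
#' Trains the regressor on the 25 C-ambient synthetic grid using
#' reference-compensated differential features, then tests on simulations
#' at elevated ambient temperatures where chamber, water bath and bottom
#' plate move together. Reports the worst-case absolute flow error across
#' all temperature x flow combinations.
#'
#' @param sc Base scenario (trained at its ambient settings).
#' @param train_grid Condition grid for training (default: the full
#'   30-condition benchtop grid).
#' @param test_temperatures Ambient temperatures for testing, degrees C.
#' @param test_flows Flow rates for testing, mm/s.
#' @param test_depth Vessel depth used for the test sets, mm.
#' @param replicates Noise replicates per test combination.
#' @param noise,spec,cfg Noise model, architecture, training config.
#' @param feature_mode `"compensated"` (default: digital per-layer
#'   reference subtraction, which cancels a uniform ambient shift) or
#'   `"bridge"` (analog voltage differentials, which retain the
#'   thermistor-nonlinearity gain change with ambient).
#' @param seed Seed for the test-set noise draws.
#' @return List with `worst_abs_err_f` (mm/s), the per-combination error
#'   table `errors`, and the trained `model`.
#' @export
ambient_robustness_eval <- function(sc = default_scenario(),
                                    train_grid = condition_grid(),
                                    test_temperatures = c(30, 32.5, 35),
                                    test_flows = c(1, 3, 5, 7, 9),
                                    test_depth = 1.5,
                                    replicates = 10,
                                    noise = noise_model(),
                                    spec = regressor_spec(input = 4),
                                    cfg = training_config(),
                                    feature_mode = c("compensated", "bridge"),
                                    seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  train <- generate_dataset(train_grid, sc, noise, mode = feature_mode)
  model <- fit_regressor(train, spec, cfg)
  set.seed(seed)
  rows <- list()
  for (ta in test_temperatures) for (fv in test_flows) {
    sci <- update_scenario(sc, vessel_depth = test_depth, flow_speed = fv,
                           ambient_temperature = ta)
    r <- steady_readings(sci)
    feats <- t(vapply(seq_len(replicates),
                      function(k) assemble_features(r, noise_sd = noise$sd,
                                                    mode = feature_mode),
                      numeric(4)))
    ph <- predict(model, feats)
    rows[[length(rows) + 1L]] <-
      data.frame(ambient = ta, f_set = fv,
                 max_abs_err_f = max(abs(ph[, "flow"] - fv)),
                 mean_err_f = mean(ph[, "flow"] - fv))
  }
  errors <- do.call(rbind, rows)
  list(worst_abs_err_f = max(errors$max_abs_err_f), errors = errors,
       model = model)
}

#' Dynamic flow-tracking evaluation
#'
#' Runs the transient solver under a piecewise-constant step flow profile,
#' feeds the probe temperatures through the measurement chain at 20 Hz
#' (linearly interpolated between solver steps), predicts flow at 1 Hz
#' with a trained model, and reports per-step 10-90% settling times and
#' post-settling tracking errors.
#'
#' @param model A trained `tsm_mlp` (temperature mode, 6 features).
#' @param sc Scenario (depth taken from its geometry).
#' @param profile A [step_flow_profile()].
#' @param dt Solver time step, s.
#' @param noise_sd Sensor noise SD, degrees C.
#' @param settle_frac Fraction of each dwell treated as post-settling
#'   (default last 40%).
#' @return List with `predictions` (1 Hz data frame: time, f_set, f_meas),
#'   `per_step` (level, settling_time_s, post_settling_mean,
#'   post_settling_err).
#' @export
dynamic_tracking_eval <- function(model, sc = default_scenario(),
                                  profile = step_flow_profile(dwell = 30),
                                  dt = 1, noise_sd = 0.0075,
                                  settle_frac = 0.4) {
  duration <- attr(profile, "duration")
  grid <- build_grid(sc$geometry, sc$actuator, sc$layout, sc$spacing)
  # start from equilibrium at the first flow level: on the bench the
  # device has been running long before the first step change
  init <- solve_steady(grid, sc$materials, sc$ambient, profile(0),
                       sc$actuator$power)
  tr <- solve_transient(grid, sc$materials, sc$ambient, profile,
                        sc$actuator$power, duration = duration, dt = dt,
                        initial_temperature = init)
  # probe the six channels at every solver step
  temps <- t(vapply(tr$fields, function(f) sensor_readings(f, sc$layout),
                    numeric(6)))
  # 20 Hz cadence via linear interpolation between solver steps
  t20 <- seq(dt, duration, by = 1 / 20)
  temps20 <- vapply(seq_len(6), function(j)
    approx(tr$times, temps[, j], xout = t20, rule = 2)$y,
    numeric(length(t20)))
  colnames(temps20) <- channel_names()
  noisy <- temps20 + matrix(rnorm(length(temps20), sd = noise_sd),
                            nrow(temps20))
  st <- ema_filter(sensor_stream(noisy, rate = 20, start = dt))
  one <- decimate_to_1hz(st)
  ph <- predict(model, one$data)
  tsec <- one$time + 0.5  # centre of each 1 s block
  f_set <- vapply(tsec, function(t) profile(t)$speed, numeric(1))
  preds <- data.frame(time = tsec, f_set = f_set, f_meas = ph[, "flow"])

  dwell <- attr(profile, "dwell")
  levels <- attr(profile, "levels")
  per_step <- do.call(rbind, lapply(seq_along(levels), function(i) {
    t0 <- (i - 1) * dwell; t1 <- i * dwell
    w <- preds$time > t0 & preds$time <= t1
    seg <- preds[w, ]
    lo <- if (i == 1) 0 else levels[i - 1]
    hi <- levels[i]
    thresh <- lo + 0.9 * (hi - lo)
    crossed <- which(seg$f_meas >= thresh)
    settle <- if (length(crossed)) seg$time[crossed[1]] - t0 else NA_real_
    post <- seg[seg$time > t1 - settle_frac * dwell, ]
    data.frame(level = hi, settling_time_s = settle,
               post_settling_mean = mean(post$f_meas),
               post_settling_err = mean(post$f_meas) - hi)
  }))
  list(predictions = preds, per_step = per_step)
}

#' Single- vs dual-layer ablation
#'
#' Compares the full six-feature regressor against one restricted to the
#' three bottom-layer channels, using identical folds, data and training
#' configuration. A single sensing layer cannot separate flow rate from
#' vessel depth; the dual-layer model must recover depth strictly better.
#'
#' @param data A six-feature `labeled_dataset` (temperature mode).
#' @param folds A `fold_assignment`.
#' @param spec,cfg Architecture (input width adjusted per arm) and
#'   training configuration.
#' @return List with `full` and `bottom_only` evaluation reports.
#' @export
layer_ablation <- function(data, folds, spec = regressor_spec(),
                           cfg = training_config()) {
  stopifnot(inherits(data, "labeled_dataset"))
  bottom_cols <- c("t_bot_up", "t_bot_dn", "t_bot_ref")
  if (!all(bottom_cols %in% attr(data, "feature_names")))
    stop("ablation requires the six temperature-mode features", call. = FALSE)
  full <- crossval_evaluate(data, folds, spec, cfg)
  sub <- data[, c("condition_id", "d_set_mm", "f_set_mm_s", bottom_cols)]
  attr(sub, "feature_names") <- bottom_cols
  attr(sub, "mode") <- attr(data, "mode")
  class(sub) <- c("labeled_dataset", "data.frame")
  bottom <- crossval_evaluate(sub, folds,
                              regressor_spec(input = 3, hidden = spec$hidden,
                                             output = spec$output,
                                             dropout = spec$dropout,
                                             batchnorm = spec$batchnorm,
                                             dropout_layers = spec$dropout_layers),
                              cfg)
  list(full = full, bottom_only = bottom)
}
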