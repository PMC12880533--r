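# Electrical/digital signal chain: NTC thermistors, Wheatstone bridges
# against a reference thermistor, exponential smoothing at 20 Hz, and
# decimation to the 1 Hz cadence consumed by the inversion network.

#' NTC thermistor model
#'
#' Standard beta-parameter model of a negative-temperature-coefficient
#' thermistor: `R(T) = R0 exp(B (1/T_K - 1/T0))`.
#'
#' @param r0 Nominal resistance at the reference temperature, ohms.
#' @param t0 Reference temperature in kelvin (default 298.15 K = 25 C).
#' @param beta Beta coefficient in kelvin.
#' @return An object of class `tf_thermistor`.
#' @export
thermistor_model <- function(r0 = 10e3, t0 = 298.15, beta = 3380) {
  if (r0 <= 0 || beta <= 0 || t0 <= 0)
    stop("r0, t0 and beta must be positive", call. = FALSE)
  structure(list(r0 = r0, t0 = t0, beta = beta), class = "tf_thermistor")
}

#' Thermistor resistance at a temperature
#'
#' @param temperature Temperature(s) in degrees C (must exceed absolute zero).
#' @param model A `tf_thermistor`.
#' @return Resistance(s) in ohms.
#' @export
#' @examples
#' thermistor_resistance(25)   # 10 kOhm at the nominal point
thermistor_resistance <- function(temperature, model = thermistor_model()) {
  if (any(temperature <= -273.15))
    stop("temperature at or below absolute zero", call. = FALSE)
  tk <- temperature + 273.15
  model$r0 * exp(model$beta * (1 / tk - 1 / model$t0))
}

#' Bridge and amplifier configuration
#'
#' @param supply Bridge supply voltage, V.
#' @param r_fixed Fixed bridge resistance, ohms.
#' @param gain Differential amplifier gain.
#' @param adc_fullscale ADC full-scale voltage, V.
#' @param adc_bits ADC resolution in bits.
#' @return An object of class `tf_bridge`.
#' @export
bridge_config <- function(supply = 3.3, r_fixed = 10e3, gain = 100,
                          adc_fullscale = 3.3, adc_bits = 12) {
  vals <- c(supply, r_fixed, gain, adc_fullscale, adc_bits)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("bridge configuration values must be positive and finite", call. = FALSE)
  structure(list(supply = supply, r_fixed = r_fixed, gain = gain,
                 adc_fullscale = adc_fullscale, adc_bits = adc_bits),
            class = "tf_bridge")
}

#' Wheatstone-bridge differential output
#'
#' Amplified difference of the two half-bridge node voltages formed by the
#' sensing and reference thermistors against fixed resistors:
#' `V = gain * Vs * (R(T_sense)/(R(T_sense)+R) - R(T_ref)/(R(T_ref)+R))`.
#' Balanced (zero) when the two temperatures are equal; a common shift of
#' both temperatures is largely rejected.
#'
#' @param t_sense,t_ref Sensing and reference temperatures, degrees C.
#' @param model A `tf_thermistor`.
#' @param cfg A `tf_bridge`.
#' @return Amplified differential voltage, V (vectorized).
#' @export
bridge_differential <- function(t_sense, t_ref, model = thermistor_model(),
                                cfg = bridge_config()) {
  rs <- thermistor_resistance(t_sense, model)
  rr <- thermistor_resistance(t_ref, model)
  cfg$gain * cfg$supply *
    (rs / (rs + cfg$r_fixed) - rr / (rr + cfg$r_fixed))
}

#' Sensor stream container
#'
#' Timestamped multi-channel samples at a fixed rate.
#'
#' @param data Numeric matrix, one column per channel (default six channels
#'   in the [channel_names()] order).
#' @param rate Sample rate in Hz.
#' @param start Time of the first sample, seconds.
#' @param units Unit flag for the samples ("degC" or "V").
#' @return An object of class `sensor_stream` with fields `time`, `data`,
#'   `rate`, `units`.
#' @export
sensor_stream <- function(data, rate = 20, start = 0, units = "degC") {
  data <- as.matrix(data)
  if (is.null(colnames(data)) && ncol(data) == 6L)
    colnames(data) <- channel_names()
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  structure(list(time = start + (seq_len(nrow(data)) - 1L) / rate,
                 data = data, rate = rate, units = units),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %d samples x %d channels @ %g Hz [%s]\n",
              nrow(x$data), ncol(x$data), x$rate, x$units))
  invisible(x)
}

#' Exponential moving-average filter
#'
#' First-order recursive smoother `y_t = alpha x_t + (1 - alpha) y_{t-1}`
#' with `y_1 = x_1`, applied per channel. Unit DC gain.
#'
#' @param stream A `sensor_stream` (or plain numeric matrix/vector).
#' @param alpha Smoothing coefficient in (0, 1].
#' @return Filtered object of the same type.
#' @export
ema_filter <- function(stream, alpha = 0.05) {
  if (alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]", call. = FALSE)
  smooth1 <- function(x) {
    if (length(x) == 0L) return(x)
    # y_t = alpha x_t + (1-alpha) y_{t-1}  ==  stats::filter recursive form
    y <- stats::filter(alpha * x, 1 - alpha, method = "recursive",
                       init = x[1])
    y[1] <- x[1]
    # note: init sets y_0 = x_1 so y_1 = alpha x_1 + (1-alpha) x_1 = x_1
    as.numeric(y)
  }
  smooth_mat <- function(m) {
    if (nrow(m) == 0L) return(m)
    out <- vapply(seq_len(ncol(m)), function(j) smooth1(m[, j]),
                  numeric(nrow(m)))
    matrix(out, nrow = nrow(m), dimnames = dimnames(m))
  }
  if (inherits(stream, "sensor_stream")) {
    stream$data <- smooth_mat(stream$data)
    stream
  } else if (is.matrix(stream)) {
    smooth_mat(stream)
  } else smooth1(stream)
}

#' Decimate a 20 Hz stream to 1 Hz block means
#'
#' Averages non-overlapping 20-sample (1 s) blocks per channel; a trailing
#' partial block is dropped.
#'
#' @param stream A `sensor_stream` sampled at 20 Hz.
#' @return A `sensor_stream` at 1 Hz.
#' @export
decimate_to_1hz <- function(stream) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (stream$rate != 20)
    stop("decimate_to_1hz expects a 20 Hz stream", call. = FALSE)
  n <- nrow(stream$data)
  nb <- n %/% 20L
  if (nb == 0L) {
    warning("fewer than 20 samples: empty 1 Hz output")
    return(sensor_stream(stream$data[0, , drop = FALSE], rate = 1,
                         units = stream$units))
  }
  blk <- rep(seq_len(nb), each = 20L)
  kept <- seq_len(nb * 20L)
  means <- apply(stream$data[kept, , drop = FALSE], 2,
                 function(col) tapply(col, blk, mean))
  means <- matrix(means, nrow = nb,
                  dimnames = list(NULL, colnames(stream$data)))
  sensor_stream(means, rate = 1, start = stream$time[1], units = stream$units)
}

#' Assemble inversion features from probe temperatures
#'
#' Full measurement chain for one observation window: take the six steady
#' (or instantaneous) probe temperatures, add i.i.d. Gaussian sensor noise
#' at the 20 Hz sampling cadence, optionally convert to Wheatstone-bridge
#' differential voltages (reference-compensated mode), smooth with the
#' exponential moving average, decimate to 1 Hz, and return the final
#' 1 Hz feature vector.
#'
#' In `"temperature"` mode the six features are the filtered temperatures
#' in the [channel_names()] order. In `"compensated"` mode the features
#' are the four per-layer reference-compensated differential temperatures
#' `(dt_top_up, dt_top_dn, dt_bot_up, dt_bot_dn)`, i.e. each linearized
#' thermistor reading minus its same-layer reference, which cancels
#' common-mode ambient shifts in the digital domain. In `"bridge"` mode
#' the features are instead the four amplified analog bridge differential
#' voltages `(v_top_up, v_top_dn, v_bot_up, v_bot_dn)`; these reject a
#' common-mode offset but retain the thermistor-nonlinearity gain
#' variation with ambient temperature.
#'
#' @param readings Named numeric vector of six probe temperatures
#'   (degrees C) in the [channel_names()] order.
#' @param noise_sd Gaussian noise SD on each probe temperature, degrees C.
#' @param mode `"temperature"` (default), `"compensated"`, or `"bridge"`.
#' @param seconds Length of the simulated 20 Hz window, s; the last 1 Hz
#'   sample is returned so the smoother has warmed up.
#' @param alpha Smoothing coefficient of the filter.
#' @param model,cfg Thermistor and bridge models (bridge mode only).
#' @return Named feature vector (length 6 in temperature mode, 4 in
#'   bridge mode), with attribute `units`.
#' @export
assemble_features <- function(readings, noise_sd = 0.0075,
                              mode = c("temperature", "compensated", "bridge"),
                              seconds = 2, alpha = 0.05,
                              model = thermistor_model(),
                              cfg = bridge_config()) {
  mode <- match.arg(mode)
  if (is.null(names(readings))) names(readings) <- channel_names()
  if (!identical(names(readings), channel_names()))
    stop("readings must be in the fixed channel order: ",
         paste(channel_names(), collapse = ", "), call. = FALSE)
  n <- round(seconds * 20)
  noisy <- matrix(rep(readings, each = n), nrow = n) +
    matrix(rnorm(n * 6, sd = noise_sd), nrow = n)
  colnames(noisy) <- channel_names()
  if (mode == "compensated") {
    sig <- cbind(
      dt_top_up = noisy[, "t_top_up"] - noisy[, "t_top_ref"],
      dt_top_dn = noisy[, "t_top_dn"] - noisy[, "t_top_ref"],
      dt_bot_up = noisy[, "t_bot_up"] - noisy[, "t_bot_ref"],
      dt_bot_dn = noisy[, "t_bot_dn"] - noisy[, "t_bot_ref"]
    )
    units <- "degC"
  } else if (mode == "bridge") {
    sig <- cbind(
      v_top_up = bridge_differential(noisy[, "t_top_up"], noisy[, "t_top_ref"], model, cfg),
      v_top_dn = bridge_differential(noisy[, "t_top_dn"], noisy[, "t_top_ref"], model, cfg),
      v_bot_up = bridge_differential(noisy[, "t_bot_up"], noisy[, "t_bot_ref"], model, cfg),
      v_bot_dn = bridge_differential(noisy[, "t_bot_dn"], noisy[, "t_bot_ref"], model, cfg)
    )
    units <- "V"
  } else {
    sig <- noisy
    units <- "degC"
  }
  st <- sensor_stream(sig, rate = 20, units = units)
  st <- ema_filter(st, alpha = alpha)
  one <- decimate_to_1hz(st)
  out <- one$data[nrow(one$data), ]
  attr(out, "units") <- units
  out
}
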