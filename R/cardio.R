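# Synthetic multimodal cardio records: 1 Hz blood-flow sequence, 128 Hz
# PPG waveform and reference systolic/diastolic pressure with a
# Valsalva-maneuver four-phase excursion.

#' Synthetic cardio generator configuration
#'
#' @param baseline_sp,baseline_dp Baseline systolic/diastolic pressure,
#'   mmHg (SP must exceed DP).
#' @param heart_rate Heart rate in Hz (default 1.2 = 72 bpm).
#' @param valsalva_onset Maneuver onset, seconds into the record.
#' @param valsalva_duration Maneuver duration, s (default 140).
#' @param phase_offsets Pressure offsets (mmHg) of the four Valsalva
#'   phases: (i) initial elevation, (ii) compensatory decrease,
#'   (iii) release drop, (iv) overshoot.
#' @param coupling_gain Flow-pressure coupling, mm/s per mmHg of mean
#'   arterial pressure deviation (default 0.05). Zero decouples the flow
#'   channel from pressure entirely.
#' @param baseline_flow Baseline flow rate, mm/s.
#' @param ppg_pulse_width Width (s) of the systolic PPG peak.
#' @param ppg_dicrotic Relative amplitude of the dicrotic hump.
#' @param pressure_noise_sd,flow_noise_sd,ppg_noise_sd Additive noise SDs.
#' @param seed Generator seed.
#' @return An object of class `cardio_config`.
#' @export
cardio_config <- function(baseline_sp = 120, baseline_dp = 80,
                          heart_rate = 1.2,
                          valsalva_onset = 200, valsalva_duration = 140,
                          phase_offsets = c(15, -20, -15, 10),
                          coupling_gain = 0.05, baseline_flow = 3,
                          ppg_pulse_width = 0.12, ppg_dicrotic = 0.4,
                          pressure_noise_sd = 1.5, flow_noise_sd = 0.08,
                          ppg_noise_sd = 0.02, seed = 0L) {
  if (baseline_sp <= baseline_dp)
    stop("baseline SP must exceed baseline DP", call. = FALSE)
  if (valsalva_duration <= 0) stop("maneuver duration must be positive", call. = FALSE)
  if (length(phase_offsets) != 4L)
    stop("phase_offsets must give the four Valsalva phases in order", call. = FALSE)
  structure(list(baseline_sp = baseline_sp, baseline_dp = baseline_dp,
                 heart_rate = heart_rate, valsalva_onset = valsalva_onset,
                 valsalva_duration = valsalva_duration,
                 phase_offsets = phase_offsets,
                 coupling_gain = coupling_gain, baseline_flow = baseline_flow,
                 ppg_pulse_width = ppg_pulse_width,
                 ppg_dicrotic = ppg_dicrotic,
                 pressure_noise_sd = pressure_noise_sd,
                 flow_noise_sd = flow_noise_sd, ppg_noise_sd = ppg_noise_sd,
                 seed = as.integer(seed)),
            class = "cardio_config")
}

# smooth indicator ramp: 0 before a, 1 after b (raised cosine in between)
.ramp <- function(t, a, b) {
  w <- (t - a) / max(b - a, 1e-9)
  w <- pmin(pmax(w, 0), 1)
  0.5 - 0.5 * cos(pi * w)
}

# four-phase Valsalva pressure offset trace (mmHg) at times t (s)
valsalva_offset <- function(t, onset, duration, amp) {
  # phase boundaries as fractions of the maneuver: strain onset spike,
  # compensatory decline, release drop, overshoot and recovery
  p <- onset + duration * c(0, 0.10, 0.60, 0.75, 0.90, 1)
  off <- numeric(length(t))
  off <- off + amp[1] * (.ramp(t, p[1], p[1] + 4) - .ramp(t, p[2] - 4, p[2]))
  off <- off + amp[2] * (.ramp(t, p[2] - 4, p[2]) - .ramp(t, p[3] - 4, p[3]))
  off <- off + amp[3] * (.ramp(t, p[3] - 4, p[3]) - .ramp(t, p[4] - 4, p[4]))
  off <- off + amp[4] * (.ramp(t, p[4] - 4, p[4]) - .ramp(t, p[5] - 6, p[6]))
  off
}

#' Generate synthetic multimodal cardio records
#'
#' Each record carries an aligned 1 Hz flow-rate sequence, a 128 Hz PPG
#' waveform and 1 Hz reference SP/DP series. Pressures follow a baseline
#' with slow drift plus the four-phase Valsalva excursion; flow couples to
#' mean arterial pressure through `coupling_gain` (declining during the
#' maneuver); the PPG pulse amplitude is modulated by pulse pressure.
#'
#' @param cfg A [cardio_config()].
#' @param n_records Number of records.
#' @param duration Record length, s.
#' @return List of `multimodal_record` objects, each with `time` (1 Hz),
#'   `flow`, `sp`, `dp`, `ppg_time` (128 Hz), `ppg`.
#' @export
generate_cardio_dataset <- function(cfg = cardio_config(), n_records = 6,
                                    duration = 600) {
  stopifnot(inherits(cfg, "cardio_config"))
  if (cfg$valsalva_onset + cfg$valsalva_duration > duration)
    stop("maneuver does not fit in the record: onset + duration exceeds length",
         call. = FALSE)
  set.seed(cfg$seed)
  fs <- 128
  lapply(seq_len(n_records), function(rec) {
    t1 <- seq(0, duration - 1)                 # 1 Hz grid
    # slow autonomic drift, shared by SP and DP (visible in flow, not in
    # the PPG amplitude which tracks pulse pressure only)
    drift <- 6 * sin(2 * pi * t1 / 300 + runif(1, 0, 2 * pi)) +
      cumsum(rnorm(length(t1), sd = 0.15))
    vo_sp <- valsalva_offset(t1, cfg$valsalva_onset, cfg$valsalva_duration,
                             cfg$phase_offsets)
    vo_dp <- valsalva_offset(t1, cfg$valsalva_onset, cfg$valsalva_duration,
                             0.7 * cfg$phase_offsets)
    sp <- cfg$baseline_sp + drift + vo_sp +
      rnorm(length(t1), sd = cfg$pressure_noise_sd)
    dp <- cfg$baseline_dp + drift + vo_dp +
      rnorm(length(t1), sd = cfg$pressure_noise_sd)
    bad <- sp <= dp
    sp[bad] <- dp[bad] + 1  # generator invariant: SP > DP everywhere
    map <- dp + (sp - dp) / 3
    map0 <- cfg$baseline_dp + (cfg$baseline_sp - cfg$baseline_dp) / 3
    flow <- cfg$baseline_flow + cfg$coupling_gain * (map - map0) +
      rnorm(length(t1), sd = cfg$flow_noise_sd)

    # PPG: two-Gaussian pulse per beat, amplitude modulated by pulse
    # pressure relative to baseline
    tp <- seq(0, duration - 1 / fs, by = 1 / fs)
    period <- 1 / cfg$heart_rate
    beat_t <- seq(0, duration + period, by = period)
    pp <- sp - dp
    pp0 <- cfg$baseline_sp - cfg$baseline_dp
    ppg <- numeric(length(tp))
    for (bt in beat_t) {
      idx1 <- max(1L, min(length(t1), floor(bt) + 1L))
      amp <- pp[idx1] / pp0
      w <- which(tp >= bt - 0.5 & tp <= bt + period)
      if (!length(w)) next
      dtb <- tp[w] - bt
      ppg[w] <- ppg[w] + amp * (
        exp(-(dtb - 0.15)^2 / (2 * cfg$ppg_pulse_width^2)) +
          cfg$ppg_dicrotic *
            exp(-(dtb - 0.15 - 0.25)^2 / (2 * (1.6 * cfg$ppg_pulse_width)^2)))
    }
    ppg <- ppg + rnorm(length(ppg), sd = cfg$ppg_noise_sd)
    structure(list(time = t1, flow = flow, sp = sp, dp = dp,
                   ppg_time = tp, ppg = ppg, record_id = rec),
              class = "multimodal_record")
  })
}

#' @export
print.multimodal_record <- function(x, ...) {
  cat(sprintf("<multimodal_record #%d> %d s; SP %.0f-%.0f, DP %.0f-%.0f mmHg; flow %.2f-%.2f mm/s; %d PPG samples\n",
              x$record_id, length(x$time), min(x$sp), max(x$sp),
              min(x$dp), max(x$dp), min(x$flow), max(x$flow), length(x$ppg)))
  invisible(x)
}
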