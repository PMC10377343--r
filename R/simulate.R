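# Synthetic wearable-session simulator.
#
# Generates multirate recordings (PPG 20 Hz, accel/gyro 10 Hz, skin
# temperature 0.1 Hz, reference ECG 250 Hz, reference accel 100 Hz) with the
# statistical structure the reconstruction pipeline assumes: a Beer-Lambert
# reflected-intensity model whose exponent carries the cardiac pulse, slow
# "DC" drift, a mechanical artifact coupled to wrist acceleration (Mmec) and
# a vascular artifact driven by finger-movement bursts that the wrist IMU
# cannot see (Mvascular).

ACTIVITIES <- c("A_rest", "B_read", "C_write", "D_walk_slow", "E_walk_fast")
ACTIVITY_GROUP <- c(A_rest = 1L, B_read = 2L, C_write = 2L,
                    D_walk_slow = 3L, E_walk_fast = 3L)

#' Build an activity protocol schedule
#'
#' With no argument, returns the default ~30-minute protocol of nine
#' segments: rest 5, read 3, rest 2, walk-slow 5, rest 2, write 3, rest 2,
#' walk-fast 5, rest 2 minutes. Each activity maps to a movement group:
#' 1 = rest, 2 = finger/arm micro-movement (read, write), 3 = displacement
#' (walking).
#'
#' @param spec optional data.frame or list of `(activity, minutes)` pairs;
#'   activities must be among `A_rest`, `B_read`, `C_write`, `D_walk_slow`,
#'   `E_walk_fast`.
#' @return a `ppg_schedule` data.frame with columns `activity`, `duration_s`,
#'   `group`, `start_s`, `end_s`.
#' @examples
#' sch <- make_schedule()
#' sum(sch$duration_s) / 60 # 29 minutes
#' @export
make_schedule <- function(spec = NULL) {
  if (is.null(spec)) {
    spec <- data.frame(
      activity = c("A_rest", "B_read", "A_rest", "D_walk_slow", "A_rest",
                   "C_write", "A_rest", "E_walk_fast", "A_rest"),
      minutes = c(5, 3, 2, 5, 2, 3, 2, 5, 2)
    )
  } else if (is.list(spec) && !is.data.frame(spec)) {
    if (length(spec) == 0) stop("empty protocol: at least one segment required")
    spec <- data.frame(
      activity = vapply(spec, function(s) as.character(s[[1]]), ""),
      minutes = vapply(spec, function(s) as.numeric(s[[2]]), 0)
    )
  }
  if (nrow(spec) == 0) stop("empty protocol: at least one segment required")
  bad <- setdiff(spec$activity, ACTIVITIES)
  if (length(bad))
    stop("unknown activity id(s): ", paste(bad, collapse = ", "))
  if (any(spec$minutes <= 0)) stop("segment durations must be positive")
  out <- data.frame(
    activity = spec$activity,
    duration_s = spec$minutes * 60,
    group = unname(ACTIVITY_GROUP[spec$activity])
  )
  out$end_s <- cumsum(out$duration_s)
  out$start_s <- out$end_s - out$duration_s
  class(out) <- c("ppg_schedule", "data.frame")
  out
}

#' Draw default user physiology
#'
#' Resting heart rate is truncated-normal (mean 65, sd 8, range 45-85 bpm);
#' activity HR elevations are 0/+4/+6/+15/+30 bpm for rest, read, write,
#' walk-slow and walk-fast; HR relaxes towards its target with a 35-s time
#' constant; inter-beat jitter sd is 30 ms; baseline skin temperature is
#' uniform on 33-35 degC and couples to lagged HR at 0.02 degC per bpm with a
#' 60-s lag.
#'
#' @param seed integer seed controlling the random draws and all downstream
#'   simulation randomness for this user.
#' @return a `ppg_physiology` list.
#' @export
default_physiology <- function(seed = 1L) {
  with_seed(seed, {
    rhr <- 65 + 8 * rnorm(1)
    while (rhr < 45 || rhr > 85) rhr <- 65 + 8 * rnorm(1)
    base_temp <- runif(1, 33, 35)
    phys <- list(
      resting_hr = rhr,
      hr_delta = c(A_rest = 0, B_read = 4, C_write = 6,
                   D_walk_slow = 15, E_walk_fast = 30),
      hr_time_constant = 35,
      ibi_jitter_sd = 0.030,
      hr_wander_sd = 4,
      hr_wander_tau = 100,
      base_temperature = base_temp,
      temp_coupling_gain = 0.02,
      temp_lag = 60,
      ppg_ac_amplitude = 1,
      random_seed = as.integer(seed)
    )
    class(phys) <- "ppg_physiology"
    phys
  })
}

validate_physiology <- function(phys) {
  stopifnot(
    phys$resting_hr >= 40, phys$resting_hr <= 100,
    all(phys$hr_delta >= 0),
    phys$temp_lag >= 0,
    phys$hr_time_constant > 0
  )
  d <- phys$hr_delta
  ord <- c(d[["A_rest"]], min(d[["B_read"]], d[["C_write"]]),
           max(d[["B_read"]], d[["C_write"]]), d[["D_walk_slow"]],
           d[["E_walk_fast"]])
  if (is.unsorted(ord))
    stop("hr_delta must be non-decreasing over rest <= read/write <= walk")
  invisible(phys)
}

#' Default Beer-Lambert artifact model
#'
#' Parameters of the reflected-intensity model
#' `Io = Ii * exp(-sum_j eps_j c_j(t) d_j(t))`. The summed exponent is
#' represented as a baseline absorbance plus a pulsatile term, slow drift,
#' a mechanical term proportional to wrist acceleration (`mmec_gain`, the
#' path-length route) and a vascular term driven by finger-movement bursts
#' active only during group-2 activities (`mvascular_gain`, the tissue
#' concentration route). Setting both gains to zero leaves a clean
#' quasi-periodic PPG.
#'
#' @param mmec_gain absorbance units per m/s^2 of wrist acceleration.
#' @param mvascular_gain dimensionless scale of the finger-burst artifact.
#' @return a `ppg_artifact` list; sensor-noise SDs and burst/gait parameters
#'   can be overridden by editing the returned list.
#' @export
default_artifact <- function(mmec_gain = 0.02, mvascular_gain = 1) {
  art <- list(
    input_intensity = 1,
    base_absorbance = 1.5,
    ac_absorbance = 0.03,      # cardiac pulse amplitude in the exponent
    resp_absorbance = 0.015,   # respiration-band DC ripple
    drift_absorbance = 0.01,   # thermoregulation drift over a session
    mmec_gain = mmec_gain,
    mvascular_gain = mvascular_gain,
    vasc_burst_rate = 0.5, vasc_burst_amp = 0.05, vasc_burst_decay = 0.8,
    arm_burst_rate = 0.12, arm_burst_amp = 0.12, arm_burst_decay = 0.4,
    gyro_burst_rate = 0.50, gyro_burst_amp = 6, gyro_burst_decay = 0.4,
    step_freq = c(D_walk_slow = 1.6, E_walk_fast = 2.0),
    gait_accel_amp = c(D_walk_slow = 2.0, E_walk_fast = 3.0),
    gait_gyro_amp = c(D_walk_slow = 40, E_walk_fast = 60),
    ppg_noise_sd = 2e-4,
    accel_noise_sd = 0.05,
    gyro_noise_sd = 0.5,
    temp_noise_sd = 0.005,
    ecg_noise_sd = 0.03,
    ref_accel_noise_sd = 0.05
  )
  class(art) <- "ppg_artifact"
  validate_artifact(art)
}

validate_artifact <- function(art) {
  if (art$mmec_gain < 0 || art$mvascular_gain < 0)
    stop("artifact gains must be non-negative")
  stopifnot(art$input_intensity > 0, art$base_absorbance >= 0)
  invisible(art)
}

#' Simulate a heart-rate trace and R-peak train
#'
#' Instantaneous HR follows first-order relaxation towards
#' `resting_hr + hr_delta[activity]` with time constant `hr_time_constant`
#' (exact discrete exponential update on a 10-Hz grid), plus a slow
#' Ornstein-Uhlenbeck wander (`hr_wander_sd` bpm, correlation time
#' `hr_wander_tau` s) standing in for autonomic variability. R-peaks are
#' produced by integrate-and-fire on the instantaneous rate with Gaussian
#' inter-beat jitter.
#'
#' @param schedule a `ppg_schedule`.
#' @param phys a `ppg_physiology`.
#' @return list with `time` (s, 10 Hz), `hr` (bpm) and `r_peaks` (s).
#' @export
simulate_hr_trace <- function(schedule, phys) {
  validate_physiology(phys)
  dur <- sum(schedule$duration_s)
  dt <- 0.1
  tt <- seq(0, dur, by = dt)
  target <- hr_target_at(schedule, phys, tt)
  hr <- numeric(length(tt))
  hr[1] <- target[1]
  decay <- exp(-dt / phys$hr_time_constant)
  for (k in seq_len(length(tt) - 1))
    hr[k + 1] <- target[k + 1] + (hr[k] - target[k + 1]) * decay
  wsd <- phys$hr_wander_sd %||% 0
  if (wsd > 0) {
    wtau <- phys$hr_wander_tau %||% 100
    rho <- exp(-dt / wtau)
    innov_sd <- wsd * sqrt(1 - rho^2)
    wander <- with_seed(phys$random_seed + 3L, {
      w <- numeric(length(tt))
      w[1] <- rnorm(1, 0, wsd)
      eps <- rnorm(length(tt) - 1, 0, innov_sd)
      for (k in seq_len(length(tt) - 1)) w[k + 1] <- w[k] * rho + eps[k]
      w
    })
    hr <- pmax(hr + wander, 35)
  }
  hr_fun <- stats::approxfun(tt, hr, rule = 2)
  r_peaks <- with_seed(phys$random_seed + 1L, {
    peaks <- numeric(0)
    t <- 0
    while (t <= dur) {
      peaks <- c(peaks, t)
      ibi <- 60 / hr_fun(t)
      if (phys$ibi_jitter_sd > 0)
        ibi <- ibi + rnorm(1, 0, phys$ibi_jitter_sd)
      t <- t + max(ibi, 0.25)
    }
    peaks
  })
  list(time = tt, hr = hr, r_peaks = r_peaks)
}

hr_target_at <- function(schedule, phys, tt) {
  idx <- findInterval(tt, schedule$start_s, rightmost.closed = FALSE)
  idx[idx < 1] <- 1L
  idx[idx > nrow(schedule)] <- nrow(schedule)
  phys$resting_hr + unname(phys$hr_delta[schedule$activity[idx]])
}

activity_at <- function(schedule, tt) {
  idx <- findInterval(tt, schedule$start_s)
  idx[idx < 1] <- 1L
  idx[idx > nrow(schedule)] <- nrow(schedule)
  schedule$activity[idx]
}

# --- internal motion models ----------------------------------------------

# Damped-oscillation burst events; each row: t0, amp, freq, decay, and a unit
# direction over the three axes. Evaluated lazily at arbitrary times.
draw_bursts <- function(schedule, groups, rate, amp, decay,
                        freq_range = c(0.8, 2.5)) {
  ev <- list()
  for (s in seq_len(nrow(schedule))) {
    if (!(schedule$group[s] %in% groups)) next
    n <- stats::rpois(1, rate * schedule$duration_s[s])
    if (n == 0) next
    t0 <- sort(runif(n, schedule$start_s[s], schedule$end_s[s]))
    dir <- matrix(rnorm(3 * n), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    ev[[length(ev) + 1]] <- data.frame(
      t0 = t0,
      amp = amp * runif(n, 0.5, 1.5),
      freq = runif(n, freq_range[1], freq_range[2]),
      decay = decay,
      dx = dir[, 1], dy = dir[, 2], dz = dir[, 3]
    )
  }
  if (length(ev)) do.call(rbind, ev) else NULL
}

eval_bursts <- function(events, tt, axes = TRUE) {
  n <- length(tt)
  out <- if (axes) matrix(0, n, 3) else numeric(n)
  if (is.null(events)) return(out)
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    i0 <- findInterval(e$t0, tt) + 1L
    i1 <- findInterval(e$t0 + 6 * e$decay, tt)
    if (i1 < i0) next
    u <- tt[i0:i1] - e$t0
    wave <- e$amp * exp(-u / e$decay) * sin(2 * pi * e$freq * u)
    if (axes) {
      out[i0:i1, 1] <- out[i0:i1, 1] + wave * e$dx
      out[i0:i1, 2] <- out[i0:i1, 2] + wave * e$dy
      out[i0:i1, 3] <- out[i0:i1, 3] + wave * e$dz
    } else out[i0:i1] <- out[i0:i1] + wave
  }
  out
}

# Gait + burst wrist-motion model (noise-free "true" motion, m/s^2 or deg/s).
build_motion <- function(schedule, art, kind = c("accel", "gyro")) {
  kind <- match.arg(kind)
  gait <- list()
  for (s in seq_len(nrow(schedule))) {
    if (schedule$group[s] != 3) next
    act <- schedule$activity[s]
    amp <- if (kind == "accel") art$gait_accel_amp[[act]] else art$gait_gyro_amp[[act]]
    gait[[length(gait) + 1]] <- list(
      start = schedule$start_s[s], end = schedule$end_s[s],
      freq = art$step_freq[[act]], amp = amp,
      phase = runif(3, 0, 2 * pi)
    )
  }
  events <- if (kind == "accel")
    draw_bursts(schedule, 2L, art$arm_burst_rate, art$arm_burst_amp,
                art$arm_burst_decay)
  else
    draw_bursts(schedule, 2L, art$gyro_burst_rate, art$gyro_burst_amp,
                art$gyro_burst_decay)
  list(gait = gait, events = events)
}

eval_motion <- function(model, tt) {
  out <- eval_bursts(model$events, tt, axes = TRUE)
  for (g in model$gait) {
    m <- tt >= g$start & tt < g$end
    if (!any(m)) next
    u <- tt[m]
    out[m, 1] <- out[m, 1] + g$amp * sin(2 * pi * g$freq * u + g$phase[1])
    out[m, 2] <- out[m, 2] + 0.6 * g$amp * sin(2 * pi * g$freq * u + g$phase[2])
    out[m, 3] <- out[m, 3] + 0.5 * g$amp * sin(4 * pi * g$freq * u + g$phase[3])
  }
  out
}

# Two-Gaussian (systolic + dicrotic) pulse waveform, one template per beat.
pulse_wave <- function(tt, r_peaks) {
  out <- numeric(length(tt))
  if (length(r_peaks) < 2) return(out)
  ibis <- diff(r_peaks)
  ibis <- c(ibis, ibis[length(ibis)])
  for (k in seq_along(r_peaks)) {
    t0 <- r_peaks[k]; ibi <- ibis[k]
    i0 <- findInterval(t0, tt) + 1L
    i1 <- findInterval(t0 + ibi, tt)
    if (i1 < i0) next
    u <- tt[i0:i1] - t0
    out[i0:i1] <- out[i0:i1] +
      exp(-(u - 0.28 * ibi)^2 / (2 * (0.09 * ibi)^2)) +
      0.35 * exp(-(u - 0.60 * ibi)^2 / (2 * (0.12 * ibi)^2))
  }
  out
}

# Sum-of-Gaussians QRS + T template placed at each R-peak.
ecg_wave <- function(tt, r_peaks) {
  out <- numeric(length(tt))
  comp <- data.frame(
    mu = c(-0.035, 0, 0.035, 0.30),
    sd = c(0.010, 0.012, 0.012, 0.070),
    amp = c(-0.15, 1.00, -0.25, 0.30)
  )
  for (t0 in r_peaks) {
    i0 <- findInterval(t0 - 0.1, tt) + 1L
    i1 <- findInterval(t0 + 0.55, tt)
    if (i1 < i0) next
    u <- tt[i0:i1] - t0
    w <- numeric(length(u))
    for (j in seq_len(nrow(comp)))
      w <- w + comp$amp[j] * exp(-(u - comp$mu[j])^2 / (2 * comp$sd[j]^2))
    out[i0:i1] <- out[i0:i1] + w
  }
  out
}

#' Simulate a complete wearable session
#'
#' Produces one multirate recording: wrist PPG (20 Hz) through the
#' Beer-Lambert artifact model, wrist accelerometer and gyroscope (10 Hz),
#' skin temperature (0.1 Hz) coupled to lagged heart rate, and (optionally)
#' a chest-strap reference: ECG (250 Hz) with a QRS template at each R-peak
#' and a reference accelerometer (100 Hz) recording the same wrist motion
#' time-shifted by a device clock offset.
#'
#' @param schedule a `ppg_schedule` (default: the standard 29-min protocol).
#' @param phys a `ppg_physiology`.
#' @param artifact a `ppg_artifact`.
#' @param include_reference simulate the reference device channels.
#' @param clock_offset reference-device clock offset in seconds; `NULL`
#'   (default) draws uniformly from -5..+5 s.
#' @return a `raw_session` list of channel data.frames plus metadata.
#' @export
simulate_session <- function(schedule = make_schedule(),
                             phys = default_physiology(),
                             artifact = default_artifact(),
                             include_reference = TRUE,
                             clock_offset = NULL) {
  validate_physiology(phys)
  validate_artifact(artifact)
  dur <- sum(schedule$duration_s)
  trace <- simulate_hr_trace(schedule, phys)

  with_seed(phys$random_seed + 2L, {
    if (is.null(clock_offset)) clock_offset <- runif(1, -5, 5)

    t_ppg <- seq(0, dur - 1 / 20, by = 1 / 20)
    t_imu <- seq(0, dur - 1 / 10, by = 1 / 10)
    t_tmp <- seq(0, dur - 10, by = 10)

    accel_model <- build_motion(schedule, artifact, "accel")
    gyro_model <- build_motion(schedule, artifact, "gyro")
    # finger-movement oscillations are slow (page turns, pen strokes)
    vasc_events <- if (artifact$mvascular_gain > 0)
      draw_bursts(schedule, 2L,
                  artifact$vasc_burst_rate,
                  artifact$vasc_burst_amp * artifact$mvascular_gain,
                  artifact$vasc_burst_decay,
                  freq_range = c(0.8, 1.5))
    else NULL

    # --- PPG via Beer-Lambert exponent -----------------------------------
    pulse <- pulse_wave(t_ppg, trace$r_peaks)
    f_resp <- runif(1, 0.2, 0.3)
    dc <- artifact$resp_absorbance * sin(2 * pi * f_resp * t_ppg + runif(1, 0, 2 * pi)) +
      artifact$drift_absorbance * t_ppg / dur
    mmec <- if (artifact$mmec_gain > 0) {
      m20 <- eval_motion(accel_model, t_ppg)
      artifact$mmec_gain * rowSums(m20) / sqrt(3)
    } else 0
    mvasc <- eval_bursts(vasc_events, t_ppg, axes = FALSE)
    expo <- artifact$base_absorbance +
      artifact$ac_absorbance * phys$ppg_ac_amplitude * pulse +
      dc + mmec + mvasc
    expo <- pmax(expo, 0)
    ppg <- artifact$input_intensity * exp(-expo) +
      rnorm(length(t_ppg), 0, artifact$ppg_noise_sd)

    # --- wrist IMU -------------------------------------------------------
    acc <- eval_motion(accel_model, t_imu)
    acc[, 3] <- acc[, 3] + 9.81 # gravity; removed downstream by detrending
    acc <- acc + matrix(rnorm(length(t_imu) * 3, 0, artifact$accel_noise_sd),
                        ncol = 3)
    gyr <- eval_motion(gyro_model, t_imu) +
      matrix(rnorm(length(t_imu) * 3, 0, artifact$gyro_noise_sd), ncol = 3)

    # --- temperature: lagged HR coupling ---------------------------------
    hr_fun <- stats::approxfun(trace$time, trace$hr, rule = 2)
    hr_lag <- hr_fun(pmax(t_tmp - phys$temp_lag, 0))
    temp <- phys$base_temperature +
      phys$temp_coupling_gain * (hr_lag - phys$resting_hr) +
      0.05 * sin(2 * pi * t_tmp / 900 + runif(1, 0, 2 * pi)) +
      rnorm(length(t_tmp), 0, artifact$temp_noise_sd)

    # --- reference device (shifted clock) --------------------------------
    ecg_df <- NULL; racc_df <- NULL
    if (include_reference) {
      t_ecg <- seq(0, dur - 1 / 250, by = 1 / 250)
      ecg <- ecg_wave(t_ecg, trace$r_peaks + clock_offset) +
        0.15 * sin(2 * pi * 0.3 * t_ecg + runif(1, 0, 2 * pi)) +
        rnorm(length(t_ecg), 0, artifact$ecg_noise_sd)
      ecg_df <- data.frame(time_s = t_ecg, value = ecg)
      t_ra <- seq(0, dur - 1 / 100, by = 1 / 100)
      ra <- eval_motion(accel_model, t_ra - clock_offset) +
        matrix(rnorm(length(t_ra) * 3, 0, artifact$ref_accel_noise_sd), ncol = 3)
      racc_df <- data.frame(time_s = t_ra, ax = ra[, 1], ay = ra[, 2], az = ra[, 3])
    }

    t_task <- seq(0, dur - 1, by = 1)
    act <- activity_at(schedule, t_task)
    session <- list(
      ppg = data.frame(time_s = t_ppg, value = ppg),
      accel = data.frame(time_s = t_imu, ax = acc[, 1], ay = acc[, 2], az = acc[, 3]),
      gyro = data.frame(time_s = t_imu, gx = gyr[, 1], gy = gyr[, 2], gz = gyr[, 3]),
      temperature = data.frame(time_s = t_tmp, value = temp),
      ecg = ecg_df,
      ref_accel = racc_df,
      task = data.frame(time_s = t_task, activity = act,
                        group = unname(ACTIVITY_GROUP[act])),
      hr_true = data.frame(time_s = trace$time, hr = trace$hr),
      r_peaks_true = trace$r_peaks,
      clock_offset = clock_offset,
      rates = list(ppg = 20, accel = 10, gyro = 10, temperature = 0.1,
                   ecg = 250, ref_accel = 100),
      schedule = schedule,
      phys = phys,
      seed = phys$random_seed
    )
    class(session) <- "raw_session"
    session
  })
}

#' Simulate a cohort of users
#'
#' @param n_users number of users.
#' @param seed master seed; user `u` is simulated with physiology seed
#'   `seed * 1000 + u`.
#' @param schedule shared protocol schedule.
#' @param artifact shared artifact model.
#' @return list of `raw_session`.
#' @export
simulate_cohort <- function(n_users, seed = 1L, schedule = make_schedule(),
                            artifact = default_artifact()) {
  lapply(seq_len(n_users), function(u) {
    phys <- default_physiology(seed * 1000L + u)
    simulate_session(schedule, phys, artifact)
  })
}

#' @export
print.raw_session <- function(x, ...) {
  dur <- max(x$ppg$time_s)
  cat(sprintf("raw_session: %.1f min, PPG %d samples @20 Hz, %s reference\n",
              dur / 60, nrow(x$ppg),
              if (is.null(x$ecg)) "no" else "ECG+accel"))
  invisible(x)
}
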