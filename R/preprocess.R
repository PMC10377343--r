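# Raw-channel conditioning: baseline removal, IMU vector norms, PPG
# band-pass + low-pass smoothing, temperature resampling and 6-s windowing.

#' Remove slow baseline with a centred moving average
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param window moving-average span in seconds (default 2).
#' @return `x` minus its centred moving average (edges use the available
#'   samples only).
#' @export
remove_baseline <- function(x, fs, window = 2) {
  n <- length(x)
  w <- max(1L, round(window * fs))
  if (n < w) stop("series shorter than the baseline window")
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  x - (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Euclidean vector norm of a tri-axial signal
#'
#' @param x,y,z axis series of equal length.
#' @return elementwise `sqrt(x^2 + y^2 + z^2)`.
#' @export
vector_norm <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z))
    stop("axis series must have equal lengths")
  sqrt(x^2 + y^2 + z^2)
}

#' Band-pass and smooth the PPG signal
#'
#' Zero-phase 4th-order Butterworth band-pass over the heart-rate fundamental
#' band (default 0.6-3 Hz) followed by a zero-phase Hamming-design FIR
#' low-pass (cutoff 4 Hz, order 41).
#'
#' @param ppg raw PPG series at `fs` Hz.
#' @param cfg a [pipeline_config()].
#' @param fs sampling rate in Hz (default 20).
#' @return filtered series, same length.
#' @export
filter_ppg <- function(ppg, cfg = pipeline_config(), fs = 20) {
  if (length(ppg) < 10 * fs)
    stop("PPG signal too short to filter (need >= 10 s)")
  bp <- butter_bandpass(4, cfg$bandpass[1], cfg$bandpass[2], fs)
  y <- filtfilt_ba(bp$b, bp$a, ppg, pad = round(3 * fs / cfg$bandpass[1]))
  lp <- fir_lowpass(cfg$lowpass_order, cfg$lowpass_cutoff_hz, fs)
  filtfilt_ba(lp, 1, y, pad = length(lp))
}

#' Condition a raw session
#'
#' Applies per-axis baseline removal and the Euclidean norm to the IMU
#' channels, band-pass + low-pass filtering to the PPG, sample-and-hold
#' resampling of the 0.1-Hz temperature to 1 Hz, and attaches the aligned
#' ground-truth HR stream when a reference ECG is present (Pan-Tompkins
#' peaks, tachogram HR, accelerometer synchronisation) or the simulator
#' truth otherwise.
#'
#' @param session a `raw_session`.
#' @param cfg a [pipeline_config()].
#' @param label_source `"reference"` (ECG-derived, requires the reference
#'   channels), `"simulator"` (simulator truth track), or `"auto"`.
#' @return a `processed_session` list.
#' @export
process_session <- function(session, cfg = pipeline_config(),
                            label_source = c("auto", "reference", "simulator")) {
  label_source <- match.arg(label_source)
  fs_imu <- session$rates$accel
  fs_ppg <- session$rates$ppg

  ax <- remove_baseline(session$accel$ax, fs_imu)
  ay <- remove_baseline(session$accel$ay, fs_imu)
  az <- remove_baseline(session$accel$az, fs_imu)
  gx <- remove_baseline(session$gyro$gx, fs_imu)
  gy <- remove_baseline(session$gyro$gy, fs_imu)
  gz <- remove_baseline(session$gyro$gz, fs_imu)

  accel_norm <- vector_norm(ax, ay, az)
  gyro_norm <- vector_norm(gx, gy, gz)
  ppg_f <- filter_ppg(session$ppg$value, cfg, fs_ppg)

  dur <- round(max(session$ppg$time_s) + 1 / session$rates$ppg)
  t1 <- seq(0, dur - 1, by = 1)
  temp1 <- sample_hold(session$temperature$time_s, session$temperature$value, t1)

  if (label_source == "auto")
    label_source <- if (!is.null(session$ecg)) "reference" else "simulator"

  hr_track <- NULL
  lag <- 0
  if (label_source == "reference") {
    if (is.null(session$ecg)) stop("session has no reference ECG channel")
    peaks <- pan_tompkins(session$ecg$value, session$rates$ecg)
    lag <- tryCatch(
      synchronize(accel_norm, fs_imu,
                  session$ref_accel[, c("ax", "ay", "az")],
                  session$rates$ref_accel),
      error = function(e) 0)
    tac <- tachogram(peaks - lag)
    hr <- hr_from_tachogram(tac)
    hr_track <- data.frame(time_s = hr$time_s, hr = hr$hr)
  } else if (!is.null(session$hr_true)) {
    hr_track <- data.frame(time_s = session$hr_true$time_s,
                           hr = session$hr_true$hr)
  }

  out <- list(
    ppg_filtered = data.frame(time_s = session$ppg$time_s, value = ppg_f),
    accel_norm = data.frame(time_s = session$accel$time_s, value = accel_norm),
    gyro_norm = data.frame(time_s = session$gyro$time_s, value = gyro_norm),
    temperature = data.frame(time_s = t1, value = temp1),
    task = session$task,
    hr_track = hr_track,
    sync_lag = lag,
    rates = list(ppg = fs_ppg, imu = fs_imu, temperature = 1)
  )
  class(out) <- "processed_session"
  out
}

sample_hold <- function(t_src, x_src, t_out) {
  idx <- findInterval(t_out, t_src)
  idx[idx < 1] <- 1L
  x_src[idx]
}

#' Cut a processed session into labelled 6-s windows
#'
#' Windows of `cfg$window_length` seconds advance by `cfg$window_hop`.
#' Each window's task class is the majority activity group inside it (ties
#' go to the earlier segment); its HR label is the mean of the aligned
#' ground-truth HR stream within the window. A trailing partial window is
#' dropped.
#'
#' @param proc a `processed_session`.
#' @param cfg a [pipeline_config()].
#' @return a `windowed_session`: per-channel sample matrices (one row per
#'   window) plus a `meta` data.frame with `start_s`, `label_task`,
#'   `label_hr`.
#' @export
window_session <- function(proc, cfg = pipeline_config()) {
  wl <- cfg$window_length
  hop <- cfg$window_hop
  dur <- floor(max(proc$ppg_filtered$time_s) + 1 / proc$rates$ppg)
  if (dur < wl) stop("session shorter than one window")
  starts <- seq(0, dur - wl, by = hop)
  n <- length(starts)

  fs_ppg <- proc$rates$ppg
  fs_imu <- proc$rates$imu
  np <- wl * fs_ppg; ni <- wl * fs_imu; nt <- wl * 1

  ppg_m <- matrix(NA_real_, n, np)
  acc_m <- matrix(NA_real_, n, ni)
  gyr_m <- matrix(NA_real_, n, ni)
  tmp_m <- matrix(NA_real_, n, nt)
  lab_task <- integer(n)
  lab_hr <- numeric(n)

  hr_fun <- if (!is.null(proc$hr_track))
    stats::approxfun(proc$hr_track$time_s, proc$hr_track$hr, rule = 2)
  else NULL

  task_t <- proc$task$time_s
  task_g <- proc$task$group

  for (i in seq_len(n)) {
    t0 <- starts[i]
    i_p <- round(t0 * fs_ppg)
    i_i <- round(t0 * fs_imu)
    i_t <- round(t0)
    ppg_m[i, ] <- proc$ppg_filtered$value[(i_p + 1):(i_p + np)]
    acc_m[i, ] <- proc$accel_norm$value[(i_i + 1):(i_i + ni)]
    gyr_m[i, ] <- proc$gyro_norm$value[(i_i + 1):(i_i + ni)]
    tmp_m[i, ] <- proc$temperature$value[(i_t + 1):(i_t + nt)]
    sel <- task_t >= t0 & task_t < t0 + wl
    g <- task_g[sel]
    cnt <- table(g)
    best <- max(cnt)
    tied <- as.integer(names(cnt)[cnt == best])
    # ties broken toward the earlier segment: first group reaching the max
    lab_task[i] <- if (length(tied) == 1) tied else g[g %in% tied][1]
    lab_hr[i] <- if (!is.null(hr_fun))
      mean(hr_fun(seq(t0, t0 + wl, by = 0.5))) else NA_real_
  }

  out <- list(ppg = ppg_m, accel = acc_m, gyro = gyr_m, temp = tmp_m,
              meta = data.frame(start_s = starts, label_task = lab_task,
                                label_hr = lab_hr),
              rates = list(ppg = fs_ppg, imu = fs_imu, temperature = 1),
              window_length = wl)
  class(out) <- "windowed_session"
  out
}
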