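# Reference HR labelling: Pan-Tompkins QRS detection, tachogram,
# instantaneous HR, and cross-device synchronisation via the accelerometers.

#' Pan-Tompkins QRS detection
#'
#' Classic stage sequence: 5-15 Hz band-pass, five-point derivative,
#' squaring, 150-ms moving-window integration, then adaptive dual-threshold
#' peak search with a 200-ms refractory period and a search-back pass at
#' half threshold when an expected beat is missed. Peak times are refined to
#' the maximum of the band-passed signal in the 150 ms preceding each
#' integrated-signal peak.
#'
#' @param ecg ECG series.
#' @param fs sampling rate in Hz (default 250).
#' @return ascending R-peak times in seconds (empty for flat input).
#' @export
pan_tompkins <- function(ecg, fs = 250) {
  if (length(ecg) < 5 * fs) stop("need at least 5 s of ECG")
  if (stats::sd(ecg) < 1e-12) return(numeric(0))

  bp <- butter_bandpass(2, 5, 15, fs)
  f <- filtfilt_ba(bp$b, bp$a, ecg, pad = fs)
  # five-point derivative (1/8)(2x[n] + x[n-1] - x[n-3] - 2x[n-4]) * fs
  n <- length(f)
  d <- numeric(n)
  idx <- 5:n
  d[idx] <- (2 * f[idx] + f[idx - 1] - f[idx - 3] - 2 * f[idx - 4]) * fs / 8
  sq <- d^2
  wlen <- round(0.150 * fs)
  mwi <- as.numeric(stats::filter(sq, rep(1 / wlen, wlen), sides = 1))
  mwi[is.na(mwi)] <- 0

  refr <- round(0.200 * fs)
  # candidate peaks: local maxima of the integrated signal
  is_pk <- c(FALSE, diff(sign(diff(mwi))) < 0, FALSE)
  cand <- which(is_pk)
  if (!length(cand)) return(numeric(0))

  spki <- max(mwi[seq_len(min(2 * fs, n))]) * 0.5
  npki <- mean(mwi[seq_len(min(2 * fs, n))]) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  rr_avg <- NA_real_
  last <- -Inf
  for (p in cand) {
    if (p - last < refr) next
    if (mwi[p] > thr1) {
      peaks <- c(peaks, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
      if (length(peaks) >= 2) {
        rr <- diff(tail(peaks, 9)) / fs
        rr_avg <- mean(rr)
      }
      last <- p
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
      # search-back: accept at half threshold if a beat is overdue
      if (!is.na(rr_avg) && (p - last) / fs > 1.66 * rr_avg &&
          mwi[p] > 0.5 * thr1) {
        peaks <- c(peaks, p)
        spki <- 0.25 * mwi[p] + 0.75 * spki
        last <- p
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  if (!length(peaks)) return(numeric(0))

  # refine to the band-passed maximum in the preceding 150 ms
  w <- round(0.150 * fs)
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, p - w)
    lo + which.max(f[lo:p]) - 1
  }, 0)
  (sort(unique(refined)) - 1) / fs
}

#' Build a tachogram from R-peak times
#'
#' @param r_peaks ascending R-peak times in seconds.
#' @return a `tachogram` list with `r_peak_times` and the inter-beat
#'   intervals `ibi` (seconds), `ibi[i]` spanning peaks `i` and `i + 1`.
#' @export
tachogram <- function(r_peaks) {
  if (length(r_peaks) < 2) stop("need at least 2 R-peaks")
  if (is.unsorted(r_peaks, strictly = TRUE)) stop("R-peak times must be ascending")
  out <- list(r_peak_times = r_peaks, ibi = diff(r_peaks))
  if (any(out$ibi <= 0)) stop("inter-beat intervals must be positive")
  class(out) <- "tachogram"
  out
}

#' Instantaneous heart rate from a tachogram
#'
#' `HR(i) = 60 / IBI(i)` in bpm, timestamped at the later peak of each
#' interval.
#'
#' @param t a [tachogram()].
#' @return data.frame with `time_s` and `hr`.
#' @examples
#' hr_from_tachogram(tachogram(c(0, 1)))$hr # 60 bpm
#' @export
hr_from_tachogram <- function(t) {
  stopifnot(inherits(t, "tachogram"))
  data.frame(time_s = t$r_peak_times[-1], hr = 60 / t$ibi)
}

#' Synchronise wristband and reference device clocks
#'
#' Down-samples the reference accelerometer norm to the wrist rate, removes
#' the baseline from both norms, and returns the lag (in seconds) by which
#' the reference stream trails the wrist stream, located as the argmax of
#' their normalised cross-correlation over +/- `max_lag` seconds with
#' parabolic sub-sample interpolation.
#'
#' @param wrist_accel_norm wrist accelerometer norm series.
#' @param fs_wrist its sampling rate (Hz).
#' @param ref_accel reference accelerometer: data.frame/matrix with three
#'   axis columns, or an already-computed norm vector.
#' @param fs_ref reference sampling rate (Hz).
#' @param max_lag search range in seconds (default 30).
#' @return lag in seconds; apply `-lag` to reference timestamps to align.
#' @export
synchronize <- function(wrist_accel_norm, fs_wrist, ref_accel, fs_ref,
                        max_lag = 30) {
  if (is.data.frame(ref_accel) || is.matrix(ref_accel)) {
    ref_accel <- as.matrix(ref_accel)
    rn <- vector_norm(remove_baseline(ref_accel[, 1], fs_ref),
                      remove_baseline(ref_accel[, 2], fs_ref),
                      remove_baseline(ref_accel[, 3], fs_ref))
  } else rn <- ref_accel
  dec <- round(fs_ref / fs_wrist)
  ref10 <- rn[seq(1, length(rn), by = dec)]
  w <- remove_baseline(wrist_accel_norm, fs_wrist)
  r <- remove_baseline(ref10, fs_wrist)
  nn <- min(length(w), length(r))
  if (nn < 60 * fs_wrist) stop("need at least 60 s of overlap")
  w <- w[seq_len(nn)]; r <- r[seq_len(nn)]
  if (stats::sd(w) < 1e-9 || stats::sd(r) < 1e-9)
    stop("cannot synchronize: both accelerometer streams are motionless")
  w <- (w - mean(w)) / stats::sd(w)
  r <- (r - mean(r)) / stats::sd(r)
  lmax <- round(max_lag * fs_wrist)
  lags <- -lmax:lmax
  cc <- vapply(lags, function(L) {
    if (L >= 0) sum(w[seq_len(nn - L)] * r[(1 + L):nn])
    else sum(w[(1 - L):nn] * r[seq_len(nn + L)])
  }, 0)
  k <- which.max(cc)
  lag <- lags[k]
  # parabolic interpolation around the discrete maximum
  if (k > 1 && k < length(lags)) {
    y1 <- cc[k - 1]; y2 <- cc[k]; y3 <- cc[k + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-12) lag <- lag + 0.5 * (y1 - y3) / den
  }
  lag / fs_wrist
}
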