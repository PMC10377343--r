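# Digital filter design and zero-phase application.
#
# Only the two designs the pipeline needs are implemented: a Butterworth
# band-pass (analog prototype + band transformation + bilinear transform)
# and a Hamming-windowed-sinc FIR low-pass. Both are applied forward and
# backward (filtfilt) so the pass-band is phase-neutral.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

polyval_z <- function(coef, z) {
  # coef in decreasing powers
  acc <- 0 + 0i
  for (cf in coef) acc <- acc * z + cf
  acc
}

#' Design a Butterworth band-pass filter
#'
#' Returns transfer-function coefficients for a digital band-pass filter of
#' analog prototype order `order` (so `2 * order` poles), obtained by the
#' band transformation and the bilinear transform with frequency pre-warping.
#'
#' @param order analog low-pass prototype order (4 gives the pipeline default).
#' @param low,high band edges in Hz.
#' @param fs sampling rate in Hz.
#' @return list with numerator `b` and denominator `a`.
#' @keywords internal
butter_bandpass <- function(order, low, high, fs) {
  stopifnot(low > 0, high > low, high < fs / 2)
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  poles <- c()
  for (p in proto) {
    disc <- sqrt((bw * p / 2)^2 - w0^2)
    poles <- c(poles, bw * p / 2 + disc, bw * p / 2 - disc)
  }
  # bilinear transform: z = (2 fs + s) / (2 fs - s)
  zp <- (2 * fs + poles) / (2 * fs - poles)
  zz <- c(rep(1 + 0i, order), rep(-1 + 0i, order)) # zeros at s = 0 and s = Inf
  b <- Re(poly_from_roots(zz))
  a <- Re(poly_from_roots(zp))
  # unit gain at the (digital) centre frequency
  wc <- 2 * pi * sqrt(low * high) / fs
  g <- Mod(polyval_z(b, exp(1i * wc)) / polyval_z(a, exp(1i * wc)))
  list(b = b / g, a = a)
}

#' Design a Hamming-window FIR low-pass filter
#'
#' @param order filter order (number of taps minus one).
#' @param cutoff cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @return numeric vector of `order + 1` taps, normalised to unit DC gain.
#' @keywords internal
fir_lowpass <- function(order, cutoff, fs) {
  n <- 0:order
  m <- n - order / 2
  fc <- cutoff / fs
  h <- ifelse(m == 0, 2 * fc, sin(2 * pi * fc * m) / (pi * m))
  w <- 0.54 - 0.46 * cos(2 * pi * n / order)
  h <- h * w
  h / sum(h)
}

#' Zero-phase filtering
#'
#' Applies `filter(b, a, .)` forward and backward over an odd-reflection
#' padded copy of the signal, cancelling the filter's phase response.
#'
#' @param b,a transfer-function coefficients.
#' @param x signal.
#' @param pad padding length in samples (default 3 x coefficient length,
#'   capped at `length(x) - 1`).
#' @return filtered signal, same length as `x`.
#' @keywords internal
filtfilt_ba <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- 3L * max(length(a), length(b))
  pad <- min(pad, n - 1L)
  if (pad > 0) {
    pre <- 2 * x[1] - x[(pad + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - pad)]
    xe <- c(pre, x, post)
  } else xe <- x
  y <- .iir_filter(b, a, xe)
  y <- rev(.iir_filter(b, a, rev(y)))
  if (pad > 0) y <- y[(pad + 1):(pad + n)]
  y
}
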