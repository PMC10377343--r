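# Per-window feature battery (63 columns) and z-normalisation.
#
# The PPG contributes 18 features: 14 statistics, mean first and second time
# derivatives, the fundamental frequency in the HR band, and the accumulated
# spectral energy sum(FFT * conj(FFT)). Accelerometer norm, gyroscope norm
# and temperature contribute the 14 statistics plus accumulated energy each:
# 18 + 3 * 15 = 63.

STAT_NAMES <- c("mean", "median", "sd", "mad", "p25", "p75", "iqr",
                "skewness", "kurtosis", "mode", "trimmed_mean", "geom_mean",
                "harm_mean", "variance")

#' Feature column catalogue
#'
#' @return data.frame mapping column index to source signal and feature name.
#' @export
feature_catalogue <- function() {
  ppg <- c(STAT_NAMES, "d1_mean", "d2_mean", "fund_freq", "energy")
  oth <- c(STAT_NAMES, "energy")
  src <- c(rep("ppg", length(ppg)), rep("accel", length(oth)),
           rep("gyro", length(oth)), rep("temp", length(oth)))
  feat <- c(ppg, oth, oth, oth)
  data.frame(index = seq_along(src), source = src, feature = feat,
             name = paste(src, feat, sep = "_"))
}

# 14 summary statistics of one window.
stat_battery <- function(x) {
  n <- length(x)
  mu <- mean(x)
  v <- stats::var(x)
  s <- sqrt(v)
  m2 <- mean((x - mu)^2)
  skw <- if (m2 > 1e-24) mean((x - mu)^3) / m2^1.5 else 0
  krt <- if (m2 > 1e-24) mean((x - mu)^4) / m2^2 else 0
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  rng <- range(x)
  md <- if (diff(rng) < 1e-12) x[1] else {
    breaks <- seq(rng[1], rng[2], length.out = 11)
    bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), 10L)
    cnt <- tabulate(bin, 10L)
    k <- which.max(cnt)
    (breaks[k] + breaks[k + 1]) / 2
  }
  ax <- abs(x) + 1e-9
  c(mean = mu, median = stats::median(x), sd = s,
    mad = mean(abs(x - mu)), p25 = q[1], p75 = q[2], iqr = q[2] - q[1],
    skewness = skw, kurtosis = krt, mode = md,
    trimmed_mean = mean(x, trim = 0.1),
    geom_mean = exp(mean(log(ax))),
    harm_mean = n / sum(1 / ax),
    variance = v)
}

# Accumulated spectral energy: Re(sum(FFT(x) * conj(FFT(x)))).
spectral_energy <- function(x) {
  f <- stats::fft(x)
  Re(sum(f * Conj(f)))
}

# Location (Hz) of the largest magnitude-spectrum peak in [band]. `nfft`
# controls zero-padding: the feature battery uses the window's natural
# resolution (nfft = n, 1/6 Hz for a 6-s window) while the FFT routing path
# pads to >= 2048 points (~0.01 Hz). NA when the band carries no energy.
fundamental_frequency <- function(x, fs, band = c(0.6, 3), nfft = NULL) {
  n <- length(x)
  nfft <- max(nfft %||% n, n)
  mag <- Mod(stats::fft(c(x - mean(x), rep(0, nfft - n))))
  freq <- (seq_len(nfft) - 1) * fs / nfft
  sel <- which(freq >= band[1] & freq <= band[2])
  if (!length(sel) || max(mag[sel]) < 1e-12) return(NA_real_)
  freq[sel[which.max(mag[sel])]]
}

#' Compute the 63-feature battery for one window
#'
#' @param ppg filtered PPG samples of the window (default 120 at 20 Hz).
#' @param accel,gyro accelerometer/gyroscope norm samples (default 60 at 10 Hz).
#' @param temp temperature samples (default 6 at 1 Hz).
#' @param cfg a [pipeline_config()] (supplies the HR band for the
#'   fundamental-frequency feature).
#' @param fs_ppg PPG sampling rate.
#' @return named numeric vector of length 63, ordered as in
#'   [feature_catalogue()].
#' @export
feature_battery <- function(ppg, accel, gyro, temp, cfg = pipeline_config(),
                            fs_ppg = 20) {
  ff <- fundamental_frequency(ppg, fs_ppg, cfg$bandpass)
  ppg_feats <- c(stat_battery(ppg),
                 d1_mean = mean(diff(ppg)) * fs_ppg,
                 d2_mean = mean(diff(diff(ppg))) * fs_ppg^2,
                 fund_freq = if (is.na(ff)) 0 else ff,
                 energy = spectral_energy(ppg))
  out <- c(ppg_feats,
           c(stat_battery(accel), energy = spectral_energy(accel)),
           c(stat_battery(gyro), energy = spectral_energy(gyro)),
           c(stat_battery(temp), energy = spectral_energy(temp)))
  names(out) <- feature_catalogue()$name
  out
}

#' Featurize a windowed session into a window table
#'
#' @param win a `windowed_session` from [window_session()], or a list of them
#'   (e.g. one per user; rows are concatenated).
#' @param cfg a [pipeline_config()].
#' @return a `window_table` data.frame: 63 feature columns, `label_hr`,
#'   `label_task`; the column catalogue is attached as attribute
#'   `"catalogue"`.
#' @export
featurize <- function(win, cfg = pipeline_config()) {
  if (inherits(win, "windowed_session")) win <- list(win)
  cat_df <- feature_catalogue()
  tabs <- lapply(win, function(w) {
    n <- nrow(w$meta)
    m <- matrix(NA_real_, n, nrow(cat_df))
    for (i in seq_len(n))
      m[i, ] <- feature_battery(w$ppg[i, ], w$accel[i, ], w$gyro[i, ],
                                w$temp[i, ], cfg, w$rates$ppg)
    df <- as.data.frame(m)
    names(df) <- cat_df$name
    df$label_hr <- w$meta$label_hr
    df$label_task <- w$meta$label_task
    df
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  attr(out, "catalogue") <- cat_df
  class(out) <- c("window_table", "data.frame")
  validate_window_table(out)
  out
}

validate_window_table <- function(tab) {
  cat_df <- feature_catalogue()
  feats <- setdiff(names(tab), c("label_hr", "label_task"))
  if (!identical(feats, cat_df$name))
    stop("window table must have exactly the 63 catalogue feature columns")
  if (any(!is.finite(as.matrix(tab[feats]))))
    stop("window table contains missing/non-finite feature values")
  if (nrow(tab) && !all(tab$label_task %in% 1:3))
    stop("label_task values must be in {1, 2, 3}")
  invisible(tab)
}

feature_matrix <- function(tab) {
  as.matrix(tab[setdiff(names(tab), c("label_hr", "label_task"))])
}

#' Fit z-normalisation statistics on a training table
#'
#' @param train a `window_table`.
#' @return a `norm_stats` list with per-feature `mean` and `sd`; features
#'   with zero variance are recorded in `dropped` (with a warning) and
#'   removed when the stats are applied.
#' @export
fit_norm <- function(train) {
  if (nrow(train) == 0) stop("training table is empty")
  X <- feature_matrix(train)
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  dropped <- names(which(sdev <= 1e-12 | !is.finite(sdev)))
  if (length(dropped))
    warning("dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
  out <- list(mean = mu, sd = sdev, dropped = dropped,
              features = colnames(X))
  class(out) <- "norm_stats"
  out
}

#' Apply z-normalisation
#'
#' @param tab a `window_table`.
#' @param stats a `norm_stats` fitted on the training split.
#' @return the table with each retained feature transformed to
#'   `(x - mean) / sd` using the training statistics.
#' @export
apply_norm <- function(tab, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  feats <- setdiff(names(tab), c("label_hr", "label_task"))
  if (!identical(feats, stats$features))
    stop("column catalogue mismatch between table and normalisation stats")
  keep <- setdiff(feats, stats$dropped)
  for (f in keep) tab[[f]] <- (tab[[f]] - stats$mean[[f]]) / stats$sd[[f]]
  if (length(stats$dropped)) tab <- tab[setdiff(names(tab), stats$dropped)]
  tab
}
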