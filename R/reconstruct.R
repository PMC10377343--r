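# Window routing and evaluation: class 1 -> FFT of the filtered PPG,
# class 2 -> Gaussian-process regressor (B1), class 3 -> bagged trees (B2).

#' Heart rate from the FFT of a filtered PPG window
#'
#' Magnitude spectrum of the zero-padded window (>= 2048 points); HR is 60
#' times the frequency of the largest peak inside the HR band.
#'
#' @param ppg_window filtered PPG samples (one window).
#' @param cfg a [pipeline_config()].
#' @param fs sampling rate (Hz).
#' @return HR in bpm, or `NA` when the band carries no energy.
#' @export
hr_from_fft <- function(ppg_window, cfg = pipeline_config(), fs = 20) {
  f <- fundamental_frequency(ppg_window, fs, cfg$bandpass, nfft = 2048)
  if (is.na(f)) NA_real_ else 60 * f
}

#' Reconstruct the HR series of a session
#'
#' Processes, windows and featurizes a raw session, normalises the features
#' with the bundle's training statistics, classifies every window and routes
#' it to the FFT path (class 1), the GPR regressor B1 (class 2) or the
#' bagged-trees regressor B2 (class 3). Windows whose FFT path finds no
#' in-band peak fall back to B1.
#'
#' @param session a `raw_session` (or an already-windowed session from
#'   [window_session()], passed via `windows`).
#' @param bundle a `trained_bundle`.
#' @param cfg a [pipeline_config()].
#' @param windows optional pre-computed `windowed_session`.
#' @param label_source forwarded to [process_session()].
#' @return a `reconstruction_result` data.frame with one row per window:
#'   `time_s`, `predicted_class`, `route`, `hr_pred`, `hr_fft` (the
#'   FFT-only estimate for every window), `label_task`, `label_hr`.
#' @export
reconstruct <- function(session, bundle, cfg = bundle$cfg, windows = NULL,
                        label_source = "auto") {
  if (is.null(windows)) {
    proc <- process_session(session, cfg, label_source)
    windows <- window_session(proc, cfg)
  }
  tab <- featurize(windows, cfg)
  ntab <- apply_norm(tab, bundle$norm)

  cls_feats <- bundle$selection_classifier
  Xc <- as.matrix(ntab[names(cls_feats$weights)[cls_feats$selected]])
  pred_class <- predict(bundle$classifier, Xc)

  reg_feats <- bundle$selection_regressor
  Xr <- as.matrix(ntab[names(reg_feats$weights)[reg_feats$selected]])

  n <- nrow(ntab)
  hr_fft <- vapply(seq_len(n),
                   function(i) hr_from_fft(windows$ppg[i, ], cfg,
                                           windows$rates$ppg),
                   0)
  hr_b1 <- predict(bundle$regressor_b1, Xr)
  hr_b2 <- predict(bundle$regressor_b2, Xr)

  route <- c("fft", "b1", "b2")[pred_class]
  hr_pred <- ifelse(pred_class == 1, hr_fft,
                    ifelse(pred_class == 2, hr_b1, hr_b2))
  fallback <- pred_class == 1 & is.na(hr_fft)
  if (any(fallback)) {
    route[fallback] <- "b1"
    hr_pred[fallback] <- hr_b1[fallback]
    message(sum(fallback), " window(s) had no in-band FFT peak; routed to B1")
  }

  out <- data.frame(time_s = windows$meta$start_s,
                    predicted_class = pred_class, route = route,
                    hr_pred = hr_pred, hr_fft = hr_fft,
                    label_task = windows$meta$label_task,
                    label_hr = windows$meta$label_hr)
  class(out) <- c("reconstruction_result", "data.frame")
  out
}

rmse <- function(pred, truth) {
  ok <- is.finite(pred) & is.finite(truth)
  if (!any(ok)) return(NA_real_)
  sqrt(mean((pred[ok] - truth[ok])^2))
}

#' Evaluate a reconstruction against its labels
#'
#' Classification accuracy and one-vs-rest precision/recall/F1 per class;
#' HR RMSE overall and per true task group; and the "no-algorithm" baseline
#' RMSE in which every window uses the FFT estimate regardless of class.
#'
#' @param result a `reconstruction_result` (rows may be pooled across
#'   sessions) with labels present.
#' @return a `reconstruction_metrics` list: `accuracy`, `per_class`
#'   (data.frame with precision/recall/f1), `rmse_total`, `rmse_per_task`,
#'   `baseline_rmse_total`, `baseline_rmse_per_task`, `confusion`.
#' @export
evaluate_reconstruction <- function(result) {
  if (nrow(result) == 0 || all(!is.finite(result$label_hr)))
    stop("no labelled windows to evaluate")
  classes <- 1:3
  conf <- table(factor(result$label_task, classes),
                factor(result$predicted_class, classes))
  acc <- sum(diag(conf)) / sum(conf)
  per_class <- data.frame(
    class = classes,
    precision = vapply(classes, function(k) {
      d <- sum(conf[, as.character(k)])
      if (d == 0) NA_real_ else conf[as.character(k), as.character(k)] / d
    }, 0),
    recall = vapply(classes, function(k) {
      d <- sum(conf[as.character(k), ])
      if (d == 0) NA_real_ else conf[as.character(k), as.character(k)] / d
    }, 0)
  )
  per_class$f1 <- with(per_class,
                       2 * precision * recall / (precision + recall))
  by_task <- split(result, factor(result$label_task, classes))
  out <- list(
    accuracy = acc,
    per_class = per_class,
    confusion = conf,
    rmse_total = rmse(result$hr_pred, result$label_hr),
    rmse_per_task = vapply(by_task, function(d) rmse(d$hr_pred, d$label_hr), 0),
    baseline_rmse_total = rmse(result$hr_fft, result$label_hr),
    baseline_rmse_per_task = vapply(by_task,
                                    function(d) rmse(d$hr_fft, d$label_hr), 0)
  )
  class(out) <- "reconstruction_metrics"
  out
}

#' @export
print.reconstruction_metrics <- function(x, ...) {
  cat(sprintf("accuracy: %.1f%%\n", 100 * x$accuracy))
  print(round(x$per_class, 3))
  cat(sprintf("RMSE total: %.2f bpm (FFT-only baseline: %.2f bpm)\n",
              x$rmse_total, x$baseline_rmse_total))
  cat("RMSE per task:",
      paste(sprintf("%d: %.2f", 1:3, x$rmse_per_task), collapse = ", "), "\n")
  invisible(x)
}
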