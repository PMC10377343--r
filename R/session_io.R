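# Session and table persistence, pipeline configuration, CLI entry points.
#
# A session is a directory of one CSV per channel plus meta.json; window
# tables are CSVs with a JSON column catalogue alongside. All numeric IO
# round-trips at full double precision (data.table's shortest-exact
# representation).

#' Pipeline configuration
#'
#' @param window_length analysis window in seconds.
#' @param window_hop hop between consecutive windows in seconds.
#' @param bandpass PPG band-pass edges (Hz); the HR fundamental band.
#' @param lowpass_cutoff_hz FIR smoothing low-pass cutoff (Hz).
#' @param lowpass_order FIR smoothing filter order.
#' @param n_classifier_features features kept for the activity classifier.
#' @param n_regressor_features features kept for the HR regressors.
#' @param split_fraction training fraction of the shuffled dataset.
#' @param cv_folds folds for cross-validated training scores.
#' @param n_learners,learning_rate,max_splits AdaBoost classifier
#'   hyper-parameters (ensemble size, shrinkage, per-tree split cap).
#' @param bag_learners,bag_min_leaf bagged-trees regressor hyper-parameters.
#' @param gpr_kernel_scale,gpr_signal_sd,gpr_noise_sd initial Gaussian-process
#'   hyper-parameters (isotropic exponential kernel), refit by marginal
#'   likelihood.
#' @param gpr_max_n,nca_max_n,relieff_max_n observation caps (seeded
#'   subsampling) for the O(n^2)-or-worse learners.
#' @param seed master seed; all pipeline randomness flows from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(window_length = 6, window_hop = 1,
                            bandpass = c(0.6, 3.0),
                            lowpass_cutoff_hz = 4, lowpass_order = 41,
                            n_classifier_features = 9,
                            n_regressor_features = 15,
                            split_fraction = 0.70, cv_folds = 5,
                            n_learners = 492, learning_rate = 0.34449,
                            max_splits = 204,
                            bag_learners = 14, bag_min_leaf = 3,
                            gpr_kernel_scale = 0.55637,
                            gpr_signal_sd = 14.331,
                            gpr_noise_sd = 69.2202,
                            gpr_max_n = 800, nca_max_n = 500,
                            relieff_max_n = 1500,
                            seed = 1L) {
  stopifnot(bandpass[1] > 0, bandpass[1] < bandpass[2], bandpass[2] < 10,
            window_hop > 0, window_hop <= window_length,
            split_fraction > 0, split_fraction < 1)
  out <- as.list(environment())
  class(out) <- "pipeline_config"
  out
}

#' Write a raw session to a directory
#'
#' One CSV per channel (`ppg.csv`, `accel.csv`, `gyro.csv`,
#' `temperature.csv`, optional `ecg.csv` / `ref_accel.csv`, simulator-only
#' `hr_true.csv`) plus `meta.json` with rates, schedule, physiology and seed.
#'
#' @param session a `raw_session`.
#' @param path directory to create.
#' @export
save_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, file)
    data.table::fwrite(df, file.path(path, file))
  wr(session$ppg, "ppg.csv")
  wr(session$accel, "accel.csv")
  wr(session$gyro, "gyro.csv")
  wr(session$temperature, "temperature.csv")
  wr(session$task, "task.csv")
  if (!is.null(session$ecg)) wr(session$ecg, "ecg.csv")
  if (!is.null(session$ref_accel)) wr(session$ref_accel, "ref_accel.csv")
  if (!is.null(session$hr_true)) wr(session$hr_true, "hr_true.csv")
  meta <- list(rates = session$rates, seed = session$seed,
               clock_offset = session$clock_offset,
               schedule = as.data.frame(unclass(session$schedule)),
               physiology = unclass(session$phys),
               r_peaks_true = session$r_peaks_true)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

read_channel <- function(path, file, rate, n_value_cols, mandatory = TRUE) {
  fp <- file.path(path, file)
  if (!file.exists(fp)) {
    if (mandatory) stop("missing mandatory channel file: ", file)
    return(NULL)
  }
  df <- as.data.frame(data.table::fread(fp))
  if (ncol(df) != n_value_cols + 1)
    stop("channel ", file, ": expected ", n_value_cols + 1, " columns")
  t <- df$time_s
  if (is.unsorted(t, strictly = TRUE))
    stop("channel ", file, ": non-monotone timestamps")
  if (length(t) > 1) {
    observed <- 1 / stats::median(diff(t))
    if (abs(observed - rate) / rate > 0.01)
      stop("channel ", file, ": sample rate ", signif(observed, 4),
           " Hz does not match declared ", rate, " Hz")
  }
  df
}

#' Load a session directory
#'
#' Validates each channel against the rates declared in `meta.json`; missing
#' optional reference channels yield a reference-free session.
#'
#' @param path session directory written by [save_session()].
#' @return a `raw_session`.
#' @export
load_session <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("missing meta.json in ", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  r <- meta$rates
  session <- list(
    ppg = read_channel(path, "ppg.csv", r$ppg, 1),
    accel = read_channel(path, "accel.csv", r$accel, 3),
    gyro = read_channel(path, "gyro.csv", r$gyro, 3),
    temperature = read_channel(path, "temperature.csv", r$temperature, 1),
    ecg = read_channel(path, "ecg.csv", r$ecg, 1, mandatory = FALSE),
    ref_accel = read_channel(path, "ref_accel.csv", r$ref_accel, 3,
                             mandatory = FALSE),
    task = as.data.frame(data.table::fread(file.path(path, "task.csv"))),
    hr_true = if (file.exists(file.path(path, "hr_true.csv")))
      as.data.frame(data.table::fread(file.path(path, "hr_true.csv"))) else NULL,
    r_peaks_true = meta$r_peaks_true,
    clock_offset = meta$clock_offset,
    rates = as.list(r),
    schedule = {
      sc <- meta$schedule
      class(sc) <- c("ppg_schedule", "data.frame")
      sc
    },
    phys = {
      ph <- meta$physiology
      ph$hr_delta <- unlist(ph$hr_delta)
      class(ph) <- "ppg_physiology"
      ph
    },
    seed = meta$seed
  )
  session$reference_free <- is.null(session$ecg)
  class(session) <- "raw_session"
  session
}

#' Save / load a window table
#'
#' The CSV holds the 63 feature columns plus `label_hr` and `label_task`
#' (65 value columns); the column catalogue is written alongside as
#' `<path>.catalogue.json`.
#'
#' @param tab a `window_table`.
#' @param path CSV file path.
#' @export
save_window_table <- function(tab, path) {
  validate_window_table(tab)
  data.table::fwrite(as.data.frame(tab), path)
  jsonlite::write_json(attr(tab, "catalogue"),
                       paste0(path, ".catalogue.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_window_table
#' @export
load_window_table <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  expected <- c(feature_catalogue()$name, "label_hr", "label_task")
  if (!identical(names(df), expected))
    stop("window table column mismatch: expected ", length(expected),
         " columns in catalogue order")
  attr(df, "catalogue") <- feature_catalogue()
  class(df) <- c("window_table", "data.frame")
  validate_window_table(df)
  df
}
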