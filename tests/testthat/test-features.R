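make_window <- function(seed = 1) {
  set.seed(seed)
  list(ppg = rnorm(120), accel = abs(rnorm(60)), gyro = abs(rnorm(60)),
       temp = 33 + cumsum(rnorm(6, 0, 0.01)))
}

test_that("catalogue has 63 bijective columns with the stated allocation", {
  cat_df <- feature_catalogue()
  expect_equal(nrow(cat_df), 63)
  expect_equal(anyDuplicated(cat_df$name), 0)
  expect_equal(sum(cat_df$source == "ppg"), 18)
  for (s in c("accel", "gyro", "temp"))
    expect_equal(sum(cat_df$source == s), 15)
})

test_that("constant windows follow the stated conventions", {
  f <- feature_battery(rep(2, 120), rep(2, 60), rep(2, 60), rep(2, 6))
  expect_equal(unname(f["ppg_mean"]), 2)
  expect_equal(unname(f["ppg_median"]), 2)
  expect_equal(unname(f["ppg_mode"]), 2)
  expect_equal(unname(f["ppg_sd"]), 0)
  expect_equal(unname(f["ppg_variance"]), 0)
  expect_equal(unname(f["ppg_skewness"]), 0)
  expect_equal(unname(f["ppg_kurtosis"]), 0)
  expect_equal(unname(f["ppg_d1_mean"]), 0)
  expect_equal(unname(f["ppg_d2_mean"]), 0)
})

test_that("accumulated energy matches the 4-point FFT worked example and Parseval", {
  expect_equal(ppghr:::spectral_energy(c(1, 0, 0, 0)), 4)
  set.seed(2)
  for (n in c(7, 60, 120)) {
    x <- rnorm(n)
    expect_equal(ppghr:::spectral_energy(x), n * sum(x^2), tolerance = 1e-12)
  }
})

test_that("fundamental frequency locates a pure tone within one FFT bin", {
  t <- seq(0, 6 - 1 / 20, by = 1 / 20)
  x <- sin(2 * pi * 1.5 * t)
  expect_equal(ppghr:::fundamental_frequency(x, 20), 1.5,
               tolerance = 1 / 6 + 1e-9)
  expect_equal(ppghr:::fundamental_frequency(x, 20, nfft = 4096), 1.5,
               tolerance = 0.01)
  expect_true(is.na(ppghr:::fundamental_frequency(rep(0, 120), 20)))
})

test_that("statistics agree with direct-formula oracles to 1e-9 relative", {
  for (seed in 1:5) {
    w <- make_window(seed)
    f <- feature_battery(w$ppg, w$accel, w$gyro, w$temp)
    x <- w$ppg
    n <- length(x)
    mu <- sum(x) / n
    expect_equal(f[["ppg_mean"]], mu, tolerance = 1e-9)
    expect_equal(f[["ppg_median"]], sort(x)[c(60, 61)] |> mean(),
                 tolerance = 1e-9)
    expect_equal(f[["ppg_variance"]], sum((x - mu)^2) / (n - 1),
                 tolerance = 1e-9)
    expect_equal(f[["ppg_sd"]], sqrt(sum((x - mu)^2) / (n - 1)),
                 tolerance = 1e-9)
    expect_equal(f[["ppg_mad"]], sum(abs(x - mu)) / n, tolerance = 1e-9)
    expect_equal(f[["ppg_iqr"]], f[["ppg_p75"]] - f[["ppg_p25"]],
                 tolerance = 1e-12)
    m2 <- sum((x - mu)^2) / n
    expect_equal(f[["ppg_skewness"]], (sum((x - mu)^3) / n) / m2^1.5,
                 tolerance = 1e-9)
    expect_equal(f[["ppg_kurtosis"]], (sum((x - mu)^4) / n) / m2^2,
                 tolerance = 1e-9)
    expect_equal(f[["ppg_geom_mean"]],
                 prod((abs(x) + 1e-9)^(1 / n)), tolerance = 1e-9)
    expect_equal(f[["ppg_harm_mean"]], n / sum(1 / (abs(x) + 1e-9)),
                 tolerance = 1e-9)
    expect_equal(f[["ppg_d1_mean"]],
                 (x[n] - x[1]) / (n - 1) * 20, tolerance = 1e-9)
    expect_equal(f[["temp_mean"]], mean(w$temp), tolerance = 1e-9)
  }
})

test_that("homogeneity: energy is quadratic, mean linear in amplitude", {
  w <- make_window(7)
  f1 <- feature_battery(w$ppg, w$accel, w$gyro, w$temp)
  f3 <- feature_battery(3 * w$ppg, w$accel, w$gyro, w$temp)
  expect_equal(f3[["ppg_energy"]], 9 * f1[["ppg_energy"]], tolerance = 1e-9)
  expect_equal(f3[["ppg_mean"]], 3 * f1[["ppg_mean"]], tolerance = 1e-9)
  expect_equal(f3[["ppg_sd"]], 3 * f1[["ppg_sd"]], tolerance = 1e-9)
})

test_that("features of a stationary tone are invariant to window start", {
  t <- seq(0, 20, by = 1 / 20)
  x <- sin(2 * pi * 1.25 * t)
  # 1.25 Hz is periodic in 0.8 s: shift by exactly 4 periods (3.2 s)
  w1 <- x[1:120]; w2 <- x[65:184]
  a <- rep(1, 60); g <- rep(1, 60); tp <- rep(33, 6)
  expect_equal(feature_battery(w1, a, g, tp), feature_battery(w2, a, g, tp),
               tolerance = 1e-6)
})

test_that("z-normalisation meets the exact contract and is idempotent", {
  bench_small <- data.frame(matrix(rnorm(40 * 63, mean = 5, sd = 3), 40))
  names(bench_small) <- feature_catalogue()$name
  bench_small$label_hr <- runif(40, 60, 90)
  bench_small$label_task <- rep(1:2, 20)
  st <- fit_norm(bench_small)
  z <- apply_norm(bench_small, st)
  M <- as.matrix(z[feature_catalogue()$name])
  expect_lt(max(abs(colMeans(M))), 1e-10)
  expect_lt(max(abs(apply(M, 2, sd) - 1)), 1e-10)
  st2 <- fit_norm(z)
  z2 <- apply_norm(z, st2)
  expect_lt(max(abs(as.matrix(z2[feature_catalogue()$name]) - M)), 1e-10)
})

test_that("zero-variance columns are dropped with a warning, not divided", {
  tab <- data.frame(matrix(rnorm(20 * 63), 20))
  names(tab) <- feature_catalogue()$name
  tab$temp_mode <- 5
  tab$label_hr <- 70; tab$label_task <- 1L
  expect_warning(st <- fit_norm(tab), "temp_mode")
  z <- apply_norm(tab, st)
  expect_false("temp_mode" %in% names(z))
  expect_true(all(is.finite(as.matrix(z[setdiff(names(z), "label_task")]))))
  # catalogue mismatch is refused
  tab2 <- tab[, c(2:1, 3:ncol(tab))]
  expect_error(apply_norm(tab2, st), "mismatch")
})
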