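test_that("default schedule reproduces the 9-segment, 29-minute protocol", {
  sch <- make_schedule()
  expect_equal(nrow(sch), 9)
  expect_equal(sum(sch$duration_s), 29 * 60)
  expect_equal(sch$activity[1:2], c("A_rest", "B_read"))
  expect_equal(sch$group, c(1, 2, 1, 3, 1, 2, 1, 3, 1))
})

test_that("custom schedules validate their inputs", {
  one <- make_schedule(list(list("A_rest", 1)))
  expect_equal(nrow(one), 1)
  expect_equal(one$duration_s, 60)
  expect_equal(one$group, 1L)
  expect_error(make_schedule(list()), "empty protocol")
  expect_error(make_schedule(list(list("Z_jump", 1))), "Z_jump")
  expect_error(make_schedule(list(list("A_rest", 0))), "positive")
})

test_that("quiet physiology at 60 bpm yields R-peaks exactly 1 s apart", {
  sch <- make_schedule(list(list("A_rest", 2)))
  tr <- simulate_hr_trace(sch, quiet_physiology(1L, 60))
  expect_equal(diff(tr$r_peaks), rep(1, length(tr$r_peaks) - 1),
               tolerance = 1e-12)
  expect_equal(tr$hr, rep(60, length(tr$hr)))
})

test_that("HR relaxes exponentially: >= 95% of the step after 3 tau", {
  sch <- make_schedule(list(list("A_rest", 1), list("E_walk_fast", 4)))
  phys <- quiet_physiology(1L, 60)
  phys$hr_delta["E_walk_fast"] <- 30
  tr <- simulate_hr_trace(sch, phys)
  t_probe <- 60 + 3 * phys$hr_time_constant
  hr_probe <- tr$hr[which.min(abs(tr$time - t_probe))]
  expect_gte(hr_probe, 60 + 0.95 * 30)
  expect_lt(hr_probe, 90 + 1e-9)
})

test_that("identical seeds give bit-identical traces and sessions", {
  phys <- default_physiology(11L)
  sch <- short_schedule()
  expect_identical(simulate_hr_trace(sch, phys), simulate_hr_trace(sch, phys))
  s1 <- simulate_session(sch, phys, default_artifact(), clock_offset = 2)
  s2 <- simulate_session(sch, phys, default_artifact(), clock_offset = 2)
  expect_identical(s1, s2)
})

test_that("reflected intensity never exceeds the input intensity", {
  ses <- small_session_fixture()
  art <- default_artifact()
  # strip additive sensor noise headroom: check against Ii plus noise bound
  expect_true(all(ses$ppg$value <= art$input_intensity + 6 * art$ppg_noise_sd))
  # noise-free run is strictly bounded
  art2 <- default_artifact()
  art2$ppg_noise_sd <- 0
  ses2 <- simulate_session(short_schedule(), quiet_physiology(3L), art2,
                           clock_offset = 0)
  expect_true(all(ses2$ppg$value <= art2$input_intensity))
  expect_true(all(ses2$ppg$value > 0))
})

test_that("with zero artifact gains a rest PPG window peaks at HR/60 Hz", {
  phys <- quiet_physiology(5L, 72)
  art <- default_artifact(mmec_gain = 0, mvascular_gain = 0)
  ses <- simulate_session(make_schedule(list(list("A_rest", 2))), phys, art,
                          include_reference = FALSE, clock_offset = 0)
  cfg <- pipeline_config()
  filt <- filter_ppg(ses$ppg$value, cfg)
  f <- ppghr:::fundamental_frequency(filt[201:1800], 20, c(0.6, 3),
                                     nfft = 4096)
  expect_equal(f, 72 / 60, tolerance = 0.05)
})

test_that("finger-movement artifacts are invisible to the wrist accelerometer", {
  ses <- memo("vasc_session", function() {
    sch <- make_schedule(list(list("A_rest", 3), list("B_read", 3)))
    simulate_session(sch, quiet_physiology(9L), default_artifact(),
                     include_reference = FALSE, clock_offset = 0)
  })
  an <- vector_norm(remove_baseline(ses$accel$ax, 10),
                    remove_baseline(ses$accel$ay, 10),
                    remove_baseline(ses$accel$az, 10))
  v_rest <- var(an[1:1800])
  v_read <- var(an[1801:3600])
  expect_lt(v_read / v_rest, 1.5)
  expect_gt(v_read / v_rest, 0.67)
})

test_that("temperature carries lagged HR information (corr > 0.8 near temp_lag)", {
  ses <- memo("temp_session", function() {
    simulate_session(make_schedule(), default_physiology(21L),
                     default_artifact(), include_reference = FALSE,
                     clock_offset = 0)
  })
  hrf <- approxfun(ses$hr_true$time_s, ses$hr_true$hr, rule = 2)
  tt <- ses$temperature$time_s
  lags <- seq(0, 150, by = 10)
  cc <- vapply(lags, function(L)
    cor(ses$temperature$value, hrf(pmax(tt - L, 0))), 0)
  expect_gt(max(cc), 0.8)
  expect_lte(abs(lags[which.max(cc)] - ses$phys$temp_lag), 20)
})

test_that("accel-norm variance separates walking but not rest vs finger movement", {
  bench <- benchmark_fixture()
  tab <- do.call(rbind, bench$tabs[1:4])
  v <- tab$accel_variance
  g <- tab$label_task
  # nearest-centroid on log-variance, group 3 vs rest
  cent <- vapply(1:3, function(k) median(log(v[g == k] + 1e-12)), 0)
  assign3 <- abs(log(v + 1e-12) - cent[3]) <
    pmin(abs(log(v + 1e-12) - cent[1]), abs(log(v + 1e-12) - cent[2]))
  acc3 <- mean((g == 3) == assign3)
  expect_gte(acc3, 0.95)
  # groups 1 vs 2 are nearly inseparable on the same statistic
  sub <- g %in% c(1, 2)
  assign2 <- abs(log(v[sub] + 1e-12) - cent[2]) <
    abs(log(v[sub] + 1e-12) - cent[1])
  acc12 <- mean((g[sub] == 2) == assign2)
  expect_lte(acc12, 0.75)
})
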