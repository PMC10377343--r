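test_that("FFT HR extraction follows the dominant in-band peak", {
  t <- seq(0, 6 - 1 / 20, by = 1 / 20)
  expect_equal(hr_from_fft(sin(2 * pi * 1.2 * t)), 72, tolerance = 1)
  two <- 2 * sin(2 * pi * 1.0 * t) + sin(2 * pi * 2.0 * t)
  expect_equal(hr_from_fft(two), 60, tolerance = 1)
  expect_true(is.na(hr_from_fft(rep(0, 120))))
})

test_that("clean simulated rest windows give FFT HR within 2 bpm of truth", {
  phys <- quiet_physiology(13L, 65)
  ses <- simulate_session(make_schedule(list(list("A_rest", 2))), phys,
                          default_artifact(), include_reference = FALSE,
                          clock_offset = 0)
  cfg <- pipeline_config()
  filt <- filter_ppg(ses$ppg$value, cfg)
  # interior windows, clear of filter edges
  for (t0 in c(30, 50, 70)) {
    w <- filt[(t0 * 20 + 1):(t0 * 20 + 120)]
    expect_equal(hr_from_fft(w, cfg), 65, tolerance = 2)
  }
})

test_that("routing tags follow the predicted class and fall back to B1", {
  bench <- benchmark_fixture()
  res <- bench$result
  expect_true(all(res$route[res$predicted_class == 2] == "b1"))
  expect_true(all(res$route[res$predicted_class == 3] == "b2"))
  expect_true(all(res$route[res$predicted_class == 1] %in% c("fft", "b1")))
  # fft tag only where an in-band estimate existed
  expect_true(all(is.finite(res$hr_pred[res$route != "fft"])))
  expect_true(all(res$hr_pred[res$route == "fft"] == res$hr_fft[res$route == "fft"]))
})

test_that("single-activity sessions route to the matching path", {
  bench <- benchmark_fixture()
  walk <- simulate_session(make_schedule(list(list("E_walk_fast", 1.5))),
                           default_physiology(61L), default_artifact(),
                           include_reference = FALSE, clock_offset = 0)
  rw <- reconstruct(walk, bench$bundle, bench$cfg)
  expect_gte(mean(rw$route == "b2"), 0.97)
  rest <- simulate_session(make_schedule(list(list("A_rest", 1.5))),
                           default_physiology(62L),
                           default_artifact(mmec_gain = 0, mvascular_gain = 0),
                           include_reference = FALSE, clock_offset = 0)
  rr <- reconstruct(rest, bench$bundle, bench$cfg)
  expect_gte(mean(rr$route == "fft"), 0.97)
})

test_that("RMSE matches the worked example and perfect predictions", {
  r <- data.frame(time_s = 0:1, predicted_class = c(1, 1),
                  route = "fft", hr_pred = c(60, 62), hr_fft = c(60, 62),
                  label_task = c(1, 1), label_hr = c(62, 60))
  m <- evaluate_reconstruction(r)
  expect_equal(m$rmse_total, 2)
  r2 <- r
  r2$hr_pred <- r2$hr_fft <- r2$label_hr
  m2 <- evaluate_reconstruction(r2)
  expect_equal(m2$rmse_total, 0)
  expect_equal(m2$accuracy, 1)
  expect_equal(m2$per_class$f1[1], 1)
})

test_that("metrics match hand-computed values on the toy confusion matrix", {
  counts <- list(c(1, 1, 8), c(1, 2, 2), c(2, 2, 9), c(2, 1, 1), c(3, 3, 10))
  truth <- unlist(lapply(counts, function(c3) rep(c3[1], c3[3])))
  pred <- unlist(lapply(counts, function(c3) rep(c3[2], c3[3])))
  r <- data.frame(time_s = seq_along(truth), predicted_class = pred,
                  route = c("fft", "b1", "b2")[pred],
                  hr_pred = 70, hr_fft = 70, label_task = truth,
                  label_hr = 70)
  m <- evaluate_reconstruction(r)
  expect_equal(m$accuracy, 27 / 30)
  expect_equal(m$per_class$precision[1], 8 / 9)
  expect_equal(m$per_class$recall[1], 0.8)
})

test_that("metrics agree with a brute-force counting oracle on random labels", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 200
    truth <- sample(1:3, n, replace = TRUE)
    pred <- sample(1:3, n, replace = TRUE)
    hr_t <- runif(n, 55, 110)
    hr_p <- hr_t + rnorm(n, 0, 5)
    r <- data.frame(time_s = seq_len(n), predicted_class = pred,
                    route = c("fft", "b1", "b2")[pred], hr_pred = hr_p,
                    hr_fft = hr_p, label_task = truth, label_hr = hr_t)
    m <- evaluate_reconstruction(r)
    expect_equal(m$accuracy, sum(pred == truth) / n)
    for (k in 1:3) {
      tp <- sum(pred == k & truth == k)
      expect_equal(m$per_class$precision[k], tp / sum(pred == k))
      expect_equal(m$per_class$recall[k], tp / sum(truth == k))
    }
    expect_equal(m$rmse_total, sqrt(sum((hr_p - hr_t)^2) / n))
    for (k in 1:3)
      expect_equal(unname(m$rmse_per_task[k]),
                   sqrt(mean((hr_p - hr_t)[truth == k]^2)))
  }
})

test_that("per-task RMSE is grouped by true labels while routing is predicted", {
  r <- data.frame(time_s = 1:4, predicted_class = c(1, 2, 2, 3),
                  route = c("fft", "b1", "b1", "b2"),
                  hr_pred = c(60, 64, 70, 80), hr_fft = c(60, 90, 95, 120),
                  label_task = c(1, 1, 2, 3), label_hr = c(60, 60, 70, 84))
  m <- evaluate_reconstruction(r)
  expect_equal(unname(m$rmse_per_task["1"]), sqrt(mean(c(0, 16))))
  expect_equal(unname(m$rmse_per_task["2"]), 0)
  expect_equal(unname(m$rmse_per_task["3"]), 4)
  expect_error(evaluate_reconstruction(r[0, ]), "no labelled windows")
})
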