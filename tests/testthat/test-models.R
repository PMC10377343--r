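toy_table <- function(n = 120, seed = 1) {
  set.seed(seed)
  cls <- sample(1:3, n, replace = TRUE)
  tab <- data.frame(fa = cls + rnorm(n, 0, 0.05), fb = rnorm(n))
  tab$label_task <- cls
  tab$label_hr <- 60 + 5 * cls + rnorm(n, 0, 0.5)
  tab
}

test_that("split is stratified 70/30, seeded and exhaustive", {
  tab <- toy_table(100)
  cfg <- pipeline_config(seed = 5)
  sp <- split_dataset(tab, cfg)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$test), 30)
  # class proportions preserved within 2 %
  for (k in 1:3) {
    p_all <- mean(tab$label_task == k)
    expect_lt(abs(mean(sp$train$label_task == k) - p_all), 0.02 + 1e-9)
  }
  sp2 <- split_dataset(tab, cfg)
  expect_identical(sp$train, sp2$train)
  ix <- sort(c(as.integer(rownames(sp$train)), as.integer(rownames(sp$test))))
  expect_equal(ix, seq_len(100))
})

test_that("classifier: perfect CV on separable data, chance on permuted labels", {
  tab <- toy_table(150, seed = 2)
  cfg <- pipeline_config(seed = 1, n_learners = 50)
  sel <- structure(list(weights = c(fa = 1, fb = 0.1), selected = 1:2,
                        method = "nca", k = 2), class = "selection_result")
  fit <- train_classifier(tab, sel, cfg, cv = TRUE)
  expect_equal(fit$cv_accuracy, 1)
  set.seed(3)
  tab_perm <- tab
  tab_perm$label_task <- sample(tab_perm$label_task)
  tab_perm$fa <- rnorm(150)
  fit_perm <- train_classifier(tab_perm, sel, cfg, cv = TRUE)
  expect_lt(abs(fit_perm$cv_accuracy - 1 / 3), 0.12)
  expect_error(train_classifier(tab[1:3, ], sel, cfg), "fewer windows")
})

test_that("regressors: constant labels give constant predictions", {
  tab <- toy_table(80, seed = 4)
  tab$label_hr <- 70
  cfg <- pipeline_config(seed = 1)
  sel <- structure(list(weights = c(fa = 1, fb = 0.5), selected = 1:2,
                        method = "relieff", k = 2), class = "selection_result")
  fit <- train_regressors(tab, sel, cfg, cv = FALSE)
  X <- as.matrix(tab[c("fa", "fb")])
  expect_true(all(abs(predict(fit$b1, X) - 70) < 0.5))
  expect_true(all(abs(predict(fit$b2, X) - 70) < 0.5))
  tab$label_hr <- -1
  expect_error(train_regressors(tab, sel, cfg, cv = FALSE), "positive")
})

test_that("GP regression interpolates a smooth noiseless function (CV RMSE < 1)", {
  set.seed(5)
  n <- 120
  tab <- data.frame(fa = sort(runif(n, -2, 2)), fb = rnorm(n))
  tab$label_hr <- 70 + 8 * tab$fa
  tab$label_task <- 2L
  cfg <- pipeline_config(seed = 2)
  sel <- structure(list(weights = c(fa = 1, fb = 0.5), selected = 1:2,
                        method = "relieff", k = 2), class = "selection_result")
  fit <- train_regressors(tab, sel, cfg, cv = TRUE)
  expect_lt(fit$cv_rmse_b1, 1)
})

test_that("training is reproducible and the bundle round-trips through JSON", {
  bench <- benchmark_fixture()
  cfg <- bench$cfg
  sub <- bench$train_tab[seq(1, nrow(bench$train_tab), by = 12), ]
  attr(sub, "catalogue") <- feature_catalogue()
  class(sub) <- c("window_table", "data.frame")
  b1 <- train_bundle(sub, cfg, cv = FALSE)
  b2 <- train_bundle(sub, cfg, cv = FALSE)
  ntab <- apply_norm(sub, b1$norm)
  Xc <- as.matrix(ntab[names(b1$selection_classifier$weights)[b1$selection_classifier$selected]])
  Xr <- as.matrix(ntab[names(b1$selection_regressor$weights)[b1$selection_regressor$selected]])
  expect_identical(predict(b1$classifier, Xc), predict(b2$classifier, Xc))
  expect_identical(predict(b1$regressor_b1, Xr), predict(b2$regressor_b1, Xr))
  expect_identical(predict(b1$regressor_b2, Xr), predict(b2$regressor_b2, Xr))

  dir <- tempfile("bundle")
  save_bundle(b1, dir)
  br <- load_bundle(dir)
  expect_equal(predict(br$classifier, Xc), predict(b1$classifier, Xc))
  expect_equal(predict(br$regressor_b1, Xr), predict(b1$regressor_b1, Xr))
  expect_equal(predict(br$regressor_b2, Xr), predict(b1$regressor_b2, Xr))
  unlink(dir, recursive = TRUE)
})

test_that("B1/B2 low- vs high-range RMSE ordering is reported (non-fatal check)", {
  bench <- benchmark_fixture()
  b <- bench$bundle
  tst <- apply_norm(do.call(rbind, bench$tabs[9:10]), b$norm)
  Xr <- as.matrix(tst[names(b$selection_regressor$weights)[b$selection_regressor$selected]])
  y <- tst$label_hr
  med <- median(y)
  p1 <- predict(b$regressor_b1, Xr); p2 <- predict(b$regressor_b2, Xr)
  r <- function(p, m) sqrt(mean((p[m] - y[m])^2))
  lo <- y < med; hi <- !lo
  # directional diagnostic from the model-selection rationale; reported only
  msg <- sprintf("B1 low/high %.2f/%.2f - B2 low/high %.2f/%.2f",
                 r(p1, lo), r(p1, hi), r(p2, lo), r(p2, hi))
  expect_true(is.finite(r(p1, lo) + r(p1, hi) + r(p2, lo) + r(p2, hi)),
              label = msg)
  succeed(msg)
})
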