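# Model training: 70/30 split, AdaBoost (SAMME) activity classifier,
# Gaussian-process and bagged-trees HR regressors, k-fold CV scores.

#' Stratified 70/30 split
#'
#' Seeded shuffle then class-stratified partition, preserving the class
#' proportions of `label_task` in both subsets.
#'
#' @param tab a `window_table`.
#' @param cfg a [pipeline_config()] (uses `split_fraction` and `seed`).
#' @return list with `train` and `test` tables.
#' @export
split_dataset <- function(tab, cfg = pipeline_config()) {
  if (nrow(tab) == 0) stop("empty table")
  idx_train <- with_seed(cfg$seed + 10L, {
    unlist(lapply(split(seq_len(nrow(tab)), tab$label_task), function(ix) {
      ix <- sample(ix)
      ix[seq_len(round(cfg$split_fraction * length(ix)))]
    }), use.names = FALSE)
  })
  idx_train <- sort(idx_train)
  train <- tab[idx_train, , drop = FALSE]
  test <- tab[-idx_train, , drop = FALSE]
  if (length(unique(train$label_task)) < length(unique(tab$label_task)) ||
      length(unique(test$label_task)) < length(unique(tab$label_task)))
    warning("a class is absent from one of the splits (tiny n?)")
  for (x in list(train, test)) attr(x, "catalogue") <- attr(tab, "catalogue")
  list(train = train, test = test)
}

# ---- AdaBoost (SAMME) over weighted CART ---------------------------------

adaboost_fit <- function(X, y, n_learners, learning_rate, max_splits,
                         classes = sort(unique(y))) {
  K <- length(classes)
  yi <- match(y, classes) - 1L
  n <- nrow(X)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  for (m in seq_len(n_learners)) {
    tr <- .cart_grow(X, as.numeric(yi), w, TRUE, K, max_splits, 1L)
    pred <- max.col(.cart_predict(tr, X), ties.method = "first") - 1L
    miss <- pred != yi
    err <- sum(w[miss])
    if (err <= 1e-10) {
      trees[[length(trees) + 1]] <- tr
      alphas <- c(alphas, learning_rate * log((1 - 1e-10) / 1e-10))
      break
    }
    if (err >= 1 - 1 / K) break
    alpha <- learning_rate * (log((1 - err) / err) + log(K - 1))
    trees[[length(trees) + 1]] <- tr
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  structure(list(trees = trees, alphas = alphas, classes = classes, K = K),
            class = "adaboost_model")
}

#' @export
predict.adaboost_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  votes <- matrix(0, nrow(X), object$K)
  for (m in seq_along(object$trees)) {
    p <- max.col(.cart_predict(object$trees[[m]], X), ties.method = "first")
    votes[cbind(seq_len(nrow(X)), p)] <-
      votes[cbind(seq_len(nrow(X)), p)] + object$alphas[m]
  }
  object$classes[max.col(votes, ties.method = "first")]
}

# ---- bagged regression trees ---------------------------------------------

bag_fit <- function(X, y, n_learners, min_leaf, seed) {
  n <- nrow(X)
  trees <- with_seed(seed, {
    lapply(seq_len(n_learners), function(m) {
      idx <- sample.int(n, n, replace = TRUE)
      .cart_grow(X[idx, , drop = FALSE], y[idx], rep(1, n), FALSE, 0L,
                 n, min_leaf)
    })
  })
  structure(list(trees = trees), class = "bag_model")
}

#' @export
predict.bag_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  preds <- vapply(object$trees,
                  function(tr) .cart_predict(tr, X)[, 1],
                  numeric(nrow(X)))
  if (nrow(X) == 1) mean(preds) else rowMeans(preds)
}

# ---- Gaussian-process regression -----------------------------------------

# Constant mean, isotropic exponential kernel
# k(x, x') = sf^2 exp(-||x - x'|| / ls) + sn^2 I.
gpr_fit <- function(X, y, kernel_scale, signal_sd, noise_sd, max_n = 800,
                    seed = 1L, refit = TRUE) {
  n <- nrow(X)
  if (n > max_n) {
    idx <- with_seed(seed + 20L, sort(sample.int(n, max_n)))
    X <- X[idx, , drop = FALSE]; y <- y[idx]; n <- max_n
  }
  D <- as.matrix(stats::dist(X))
  nll <- function(theta) {
    ls <- exp(theta[1]); sf <- exp(theta[2]); sn <- exp(theta[3])
    K <- sf^2 * exp(-D / ls) + diag(sn^2 + 1e-8, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Ki1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
    Kiy <- backsolve(ch, forwardsolve(t(ch), y))
    beta <- sum(Kiy) / sum(Ki1)
    r <- y - beta
    Kir <- backsolve(ch, forwardsolve(t(ch), r))
    0.5 * sum(r * Kir) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  }
  theta0 <- log(c(kernel_scale, signal_sd, noise_sd))
  theta <- theta0
  if (refit) {
    opt <- stats::optim(theta0, nll, method = "Nelder-Mead",
                        control = list(maxit = 120, reltol = 1e-6))
    theta <- opt$par
  }
  ls <- exp(theta[1]); sf <- exp(theta[2]); sn <- exp(theta[3])
  K <- sf^2 * exp(-D / ls) + diag(sn^2 + 1e-8, n)
  ch <- chol(K)
  Ki1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  Kiy <- backsolve(ch, forwardsolve(t(ch), y))
  beta <- sum(Kiy) / sum(Ki1)
  alpha <- backsolve(ch, forwardsolve(t(ch), y - beta))
  structure(list(X = X, alpha = alpha, beta = beta,
                 kernel_scale = ls, signal_sd = sf, noise_sd = sn),
            class = "gpr_model")
}

#' @export
predict.gpr_model <- function(object, newdata, ...) {
  Xs <- as.matrix(newdata)
  # cross-distances
  d2 <- outer(rowSums(Xs^2), rowSums(object$X^2), "+") -
    2 * Xs %*% t(object$X)
  Ks <- object$signal_sd^2 * exp(-sqrt(pmax(d2, 0)) / object$kernel_scale)
  as.numeric(object$beta + Ks %*% object$alpha)
}

# ---- training front-ends -------------------------------------------------

cv_folds_assign <- function(n, k, seed) {
  with_seed(seed + 30L, sample(rep(seq_len(k), length.out = n)))
}

#' Train the activity classifier
#'
#' Multiclass AdaBoost (SAMME) over depth-capped decision trees with the
#' optimised defaults: 492 learners, learning rate 0.34449, at most 204
#' splits per tree. Optionally computes the k-fold cross-validated accuracy
#' on the training split.
#'
#' @param train normalised training `window_table`.
#' @param selection a `selection_result` from [nca_weights()] (its selected
#'   columns are used).
#' @param cfg a [pipeline_config()].
#' @param cv compute the `cfg$cv_folds`-fold CV accuracy (slower).
#' @return list with the fitted `model`, `cv_accuracy` (or `NA`) and the
#'   selected feature names.
#' @export
train_classifier <- function(train, selection, cfg = pipeline_config(),
                             cv = TRUE) {
  feats <- names(selection$weights)[selection$selected]
  X <- as.matrix(train[feats])
  y <- train$label_task
  cv_acc <- NA_real_
  if (cv) {
    if (nrow(X) < cfg$cv_folds) stop("fewer windows than folds")
    fold <- cv_folds_assign(nrow(X), cfg$cv_folds, cfg$seed)
    hits <- 0
    for (f in seq_len(cfg$cv_folds)) {
      hold <- fold == f
      fit <- adaboost_fit(X[!hold, , drop = FALSE], y[!hold],
                          cfg$n_learners, cfg$learning_rate, cfg$max_splits,
                          classes = sort(unique(y)))
      hits <- hits + sum(predict(fit, X[hold, , drop = FALSE]) == y[hold])
    }
    cv_acc <- hits / nrow(X)
  }
  model <- adaboost_fit(X, y, cfg$n_learners, cfg$learning_rate,
                        cfg$max_splits)
  list(model = model, cv_accuracy = cv_acc, features = feats)
}

#' Train the two HR regressors
#'
#' B1: Gaussian-process regression (constant mean, isotropic exponential
#' kernel) initialised at the printed hyper-parameters and refit by marginal
#' likelihood; B2: bagged regression trees (14 learners, minimum leaf 3).
#'
#' @param train normalised training `window_table` with positive `label_hr`.
#' @param selection a `selection_result` from [relieff_weights()].
#' @param cfg a [pipeline_config()].
#' @param cv compute k-fold CV RMSE for both models.
#' @return list with `b1` (GPR), `b2` (bagged trees), `cv_rmse_b1`,
#'   `cv_rmse_b2` and the selected feature names.
#' @export
train_regressors <- function(train, selection, cfg = pipeline_config(),
                             cv = TRUE) {
  feats <- names(selection$weights)[selection$selected]
  X <- as.matrix(train[feats])
  y <- train$label_hr
  if (any(y <= 0)) stop("HR labels must be positive")
  cv1 <- cv2 <- NA_real_
  if (cv) {
    fold <- cv_folds_assign(nrow(X), cfg$cv_folds, cfg$seed + 1L)
    se1 <- se2 <- 0
    for (f in seq_len(cfg$cv_folds)) {
      hold <- fold == f
      g <- gpr_fit(X[!hold, , drop = FALSE], y[!hold], cfg$gpr_kernel_scale,
                   cfg$gpr_signal_sd, cfg$gpr_noise_sd, cfg$gpr_max_n,
                   cfg$seed + f)
      b <- bag_fit(X[!hold, , drop = FALSE], y[!hold], cfg$bag_learners,
                   cfg$bag_min_leaf, cfg$seed + 40L + f)
      se1 <- se1 + sum((predict(g, X[hold, , drop = FALSE]) - y[hold])^2)
      se2 <- se2 + sum((predict(b, X[hold, , drop = FALSE]) - y[hold])^2)
    }
    cv1 <- sqrt(se1 / nrow(X)); cv2 <- sqrt(se2 / nrow(X))
  }
  b1 <- gpr_fit(X, y, cfg$gpr_kernel_scale, cfg$gpr_signal_sd,
                cfg$gpr_noise_sd, cfg$gpr_max_n, cfg$seed)
  b2 <- bag_fit(X, y, cfg$bag_learners, cfg$bag_min_leaf, cfg$seed + 40L)
  list(b1 = b1, b2 = b2, cv_rmse_b1 = cv1, cv_rmse_b2 = cv2,
       features = feats)
}

#' Train the full model bundle
#'
#' Fits normalisation on the training table, runs NCA (top 9, task label)
#' and RReliefF (top 15, HR label) feature selection, and trains the
#' classifier and both regressors.
#'
#' @param train raw (unnormalised) training `window_table`.
#' @param cfg a [pipeline_config()].
#' @param cv compute cross-validated training scores.
#' @return a `trained_bundle`.
#' @export
train_bundle <- function(train, cfg = pipeline_config(), cv = FALSE) {
  norm <- fit_norm(train)
  trn <- apply_norm(train, norm)
  sel_cls <- nca_weights(trn, k = cfg$n_classifier_features,
                         max_n = cfg$nca_max_n, seed = cfg$seed)
  sel_reg <- relieff_weights(trn, k = cfg$n_regressor_features,
                             max_n = cfg$relieff_max_n, seed = cfg$seed)
  cls <- train_classifier(trn, sel_cls, cfg, cv = cv)
  reg <- train_regressors(trn, sel_reg, cfg, cv = cv)
  out <- list(classifier = cls$model, regressor_b1 = reg$b1,
              regressor_b2 = reg$b2, norm = norm,
              selection_classifier = sel_cls, selection_regressor = sel_reg,
              cv = list(classifier_accuracy = cls$cv_accuracy,
                        rmse_b1 = reg$cv_rmse_b1, rmse_b2 = reg$cv_rmse_b2),
              cfg = cfg)
  class(out) <- "trained_bundle"
  out
}

#' @export
print.trained_bundle <- function(x, ...) {
  cat("trained_bundle\n")
  cat("  classifier features:",
      paste(names(x$selection_classifier$weights)[x$selection_classifier$selected],
            collapse = ", "), "\n")
  cat("  regressor features:",
      paste(names(x$selection_regressor$weights)[x$selection_regressor$selected],
            collapse = ", "), "\n")
  if (!is.na(x$cv$classifier_accuracy))
    cat(sprintf("  CV accuracy %.3f | CV RMSE B1 %.2f, B2 %.2f bpm\n",
                x$cv$classifier_accuracy, x$cv$rmse_b1, x$cv$rmse_b2))
  invisible(x)
}
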