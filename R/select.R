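# Feature ranking: NCA weighting for the activity classifier, regression
# ReliefF (RReliefF) for the HR regressors.

new_selection <- function(weights, k, method) {
  ord <- order(weights, decreasing = TRUE)
  out <- list(weights = weights, selected = sort(ord[seq_len(k)]),
              method = method, k = k)
  class(out) <- "selection_result"
  out
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s): top %d of %d features\n",
              x$method, x$k, length(x$weights)))
  sel <- names(x$weights)[x$selected]
  cat(" ", paste(sel, collapse = ", "), "\n")
  invisible(x)
}

#' Neighbourhood component analysis feature weights
#'
#' Learns a per-feature weight vector maximising the leave-one-out
#' stochastic-neighbour classification objective
#' `sum_i sum_{j != i, y_j = y_i} p_ij - lambda * sum_r w_r^2` with
#' `p_ij` proportional to `exp(-sum_r w_r^2 |x_ir - x_jr|)` (weighted L1
#' kernel), by gradient ascent from `w = 1` (base step 0.1 with
#' backtracking, up to `max_iter` iterations or gradient norm < 1e-6).
#' Squared weights are returned as importances.
#'
#' @param tab a normalised `window_table` (or any data.frame whose feature
#'   columns are all columns except the labels) with `label_task` classes,
#'   or a plain matrix plus `y`.
#' @param y class labels (taken from `tab$label_task` when missing).
#' @param k number of features to select (default 9).
#' @param lambda ridge penalty; default `1 / n`.
#' @param max_iter gradient-ascent iteration cap.
#' @param max_n subsample cap for the O(n^2) objective (seeded by `seed`).
#' @param seed subsampling seed.
#' @return a `selection_result` with `weights` (squared NCA weights) and the
#'   indices of the top-`k` features.
#' @export
nca_weights <- function(tab, y = NULL, k = 9, lambda = NULL,
                        max_iter = 200, max_n = 500, seed = 1L) {
  X <- selection_matrix(tab)
  if (is.null(y)) y <- tab$label_task
  if (length(unique(y)) < 2) stop("need at least 2 classes")
  if (k > ncol(X)) stop("k exceeds the number of features")
  n <- nrow(X)
  if (n > max_n) {
    idx <- with_seed(seed, sample.int(n, max_n))
    X <- X[idx, , drop = FALSE]; y <- y[idx]; n <- max_n
  }
  if (is.null(lambda)) lambda <- 1 / n
  p <- ncol(X)

  # cache |x_ir - x_jr| as an (n*n) x p matrix
  D <- matrix(0, n * n, p)
  for (r in seq_len(p)) D[, r] <- as.vector(abs(outer(X[, r], X[, r], "-")))
  smat <- outer(y, y, "==")

  # Softmax over neighbours j for each i (rows of the n x n matrix).
  eval_fw <- function(w) {
    d <- as.vector(D %*% (w^2))
    dmat <- matrix(d, n, n)           # dmat[i, j] = sum_r w_r^2 |x_ir - x_jr|
    diag(dmat) <- Inf
    expd <- exp(-(dmat - apply(dmat, 1, min)))
    diag(expd) <- 0
    P <- expd / rowSums(expd)
    pi_vec <- rowSums(P * smat)
    f <- sum(pi_vec) - lambda * sum(w^2)
    coef <- P * (pi_vec - smat)       # coef_ij = P_ij (p_i - same_ij)
    grad <- 2 * w * as.vector(crossprod(D, as.vector(coef))) - 2 * lambda * w
    list(f = f, grad = grad)
  }

  w <- rep(1, p)
  cur <- eval_fw(w)
  step <- 0.1
  for (it in seq_len(max_iter)) {
    if (sqrt(sum(cur$grad^2)) < 1e-6) break
    s <- step
    repeat {
      w_new <- w + s * cur$grad
      nxt <- eval_fw(w_new)
      if (nxt$f >= cur$f || s < 1e-8) break
      s <- s / 2
    }
    if (nxt$f < cur$f) break
    w <- w_new; cur <- nxt
  }
  weights <- w^2
  names(weights) <- colnames(X)
  new_selection(weights, k, "nca")
}

#' Regression ReliefF (RReliefF) feature weights
#'
#' For every observation the `k_neighbors` nearest points (Euclidean) are
#' found; contributions are weighted by a distance-rank exponential kernel
#' (`exp(-(rank/sigma)^2)`, normalised). With attribute and response
#' differences normalised by their ranges, the accumulators
#' `N_dR`, `N_dA[r]`, `N_dR&dA[r]` give the standard update
#' `W[r] = N_dR&dA[r] / N_dR - (N_dA[r] - N_dR&dA[r]) / (m - N_dR)`.
#'
#' @param tab table with feature columns and a continuous `label_hr`
#'   response, or a plain matrix plus `y`.
#' @param y continuous response (taken from `tab$label_hr` when missing).
#' @param k number of features to select (default 15).
#' @param k_neighbors neighbours per observation (default 10).
#' @param sigma rank-weighting decay in ranks (default 50).
#' @param max_n subsample cap (seeded by `seed`).
#' @param seed subsampling seed.
#' @return a `selection_result`.
#' @export
relieff_weights <- function(tab, y = NULL, k = 15, k_neighbors = 10,
                            sigma = 50, max_n = 1500, seed = 1L) {
  X <- selection_matrix(tab)
  if (is.null(y)) y <- tab$label_hr
  n <- nrow(X)
  if (n < k_neighbors + 1) stop("need at least k_neighbors + 1 observations")
  if (max(y) - min(y) < 1e-12) stop("constant response vector")
  if (k > ncol(X)) stop("k exceeds the number of features")
  if (n > max_n) {
    idx <- with_seed(seed + 1L, sample.int(n, max_n))
    X <- X[idx, , drop = FALSE]; y <- y[idx]; n <- max_n
  }
  p <- ncol(X)
  rngA <- apply(X, 2, function(col) max(col) - min(col))
  rngA[rngA < 1e-12] <- 1
  rngR <- max(y) - min(y)

  rw <- exp(-(seq_len(k_neighbors) / sigma)^2)
  rw <- rw / sum(rw)

  d2 <- as.matrix(stats::dist(X))^2
  diag(d2) <- Inf
  N_dR <- 0
  N_dA <- numeric(p)
  N_dRdA <- numeric(p)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(k_neighbors)]
    dR <- abs(y[i] - y[nb]) / rngR
    dA <- abs(sweep(X[nb, , drop = FALSE], 2, X[i, ], "-"))
    dA <- sweep(dA, 2, rngA, "/")
    N_dR <- N_dR + sum(rw * dR)
    N_dA <- N_dA + colSums(rw * dA)
    N_dRdA <- N_dRdA + colSums(rw * dR * dA)
  }
  m <- n
  W <- N_dRdA / N_dR - (N_dA - N_dRdA) / (m - N_dR)
  names(W) <- colnames(X)
  new_selection(W, k, "relieff")
}

selection_matrix <- function(tab) {
  if (is.matrix(tab)) return(tab)
  feats <- setdiff(names(tab), c("label_hr", "label_task"))
  as.matrix(tab[feats])
}
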