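# Shared fixtures. Expensive objects are memoised per test run so the
# acceptance criteria can share one synthetic cohort.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# physiology with every stochastic HR term switched off
quiet_physiology <- function(seed = 1L, resting_hr = 60) {
  phys <- default_physiology(seed)
  phys$resting_hr <- resting_hr
  phys$hr_delta[] <- 0
  phys$ibi_jitter_sd <- 0
  phys$hr_wander_sd <- 0
  phys
}

# short schedule (each default segment scaled to 1/5): ~5.8 min
short_schedule <- function() {
  make_schedule(list(
    list("A_rest", 1), list("B_read", 0.6), list("A_rest", 0.4),
    list("D_walk_slow", 1), list("A_rest", 0.4), list("C_write", 0.6),
    list("A_rest", 0.4), list("E_walk_fast", 1), list("A_rest", 0.4)
  ))
}

# full-protocol benchmark: 10 users, 8 train / 2 held out (criteria 6 & 7)
benchmark_fixture <- function() {
  memo("benchmark", function() {
    cfg <- pipeline_config(seed = 1L)
    sessions <- simulate_cohort(10, seed = 1L)
    wins <- lapply(sessions, function(s)
      window_session(process_session(s, cfg), cfg))
    tabs <- lapply(wins, featurize, cfg = cfg)
    train_tab <- do.call(rbind, tabs[1:8])
    attr(train_tab, "catalogue") <- feature_catalogue()
    class(train_tab) <- c("window_table", "data.frame")
    bundle <- train_bundle(train_tab, cfg, cv = FALSE)
    result <- do.call(rbind, lapply(9:10, function(u)
      reconstruct(sessions[[u]], bundle, cfg, windows = wins[[u]])))
    list(cfg = cfg, sessions = sessions, wins = wins, tabs = tabs,
         train_tab = train_tab, bundle = bundle, result = result,
         metrics = evaluate_reconstruction(result))
  })
}

# small mixed-activity session reused by several unit tests
small_session_fixture <- function() {
  memo("small_session", function() {
    phys <- default_physiology(7L)
    simulate_session(short_schedule(), phys, default_artifact(),
                     clock_offset = 1.5)
  })
}

# naive RReliefF reimplementation (plain loops) used as the oracle
relieff_oracle <- function(X, y, k_neighbors = 10, sigma = 50) {
  n <- nrow(X); p <- ncol(X)
  rngA <- apply(X, 2, function(c) max(c) - min(c))
  rngA[rngA < 1e-12] <- 1
  rngR <- max(y) - min(y)
  rw <- exp(-(seq_len(k_neighbors) / sigma)^2)
  rw <- rw / sum(rw)
  N_dR <- 0; N_dA <- numeric(p); N_dRdA <- numeric(p)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sum((X[i, ] - X[j, ])^2)
    d[i] <- Inf
    nb <- order(d)[seq_len(k_neighbors)]
    for (q in seq_along(nb)) {
      j <- nb[q]
      dR <- abs(y[i] - y[j]) / rngR
      N_dR <- N_dR + rw[q] * dR
      for (r in seq_len(p)) {
        dA <- abs(X[i, r] - X[j, r]) / rngA[r]
        N_dA[r] <- N_dA[r] + rw[q] * dA
        N_dRdA[r] <- N_dRdA[r] + rw[q] * dR * dA
      }
    }
  }
  N_dRdA / N_dR - (N_dA - N_dRdA) / (n - N_dR)
}

# naive NCA objective (plain loops) used as the grid oracle
nca_objective_oracle <- function(X, y, w, lambda) {
  n <- nrow(X)
  f <- 0
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sum(w^2 * abs(X[i, ] - X[j, ]))
    e <- exp(-(d - min(d[-i])))
    e[i] <- 0
    p <- e / sum(e)
    f <- f + sum(p[y == y[i] & seq_len(n) != i])
  }
  f - lambda * sum(w^2)
}
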