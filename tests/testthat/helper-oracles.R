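# Independent oracles and small fixtures used across the suite.

# Brute-force re-derivation of the consecutive-window rule, written as a
# stream consumer independent of run_online_detector's counter logic:
# scan for the first index i with WN trailing "signal" labels that is past
# the refractory horizon, emit, and restart the run after it.
oracle_detector <- function(labels, times, wn, refractory = 0) {
  labels <- as.character(labels)
  det <- numeric(0)
  i <- 1L
  run_start <- 1L
  horizon <- -Inf
  while (i <= length(labels)) {
    if (times[i] <= horizon) {
      run_start <- i + 1L
    } else if (labels[i] != "signal") {
      run_start <- i + 1L
    } else if (i - run_start + 1L == wn) {
      det <- c(det, times[i])
      horizon <- times[i] + refractory
      run_start <- i + 1L
    }
    i <- i + 1L
  }
  det
}

# Dense generalized-eigensolver oracle for LPP with var_keep = 1: naive
# double-loop graph construction and an unsymmetric solve(B) %*% A eigen
# route, on the raw data directly.
oracle_lpp_subspace <- function(x, m, k, ridge = 1e-8) {
  xc <- x
  n <- nrow(xc)
  dm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) dm[i, j] <- sqrt(sum((xc[i, ] - xc[j, ])^2))
  }
  width <- mean(dm[upper.tri(dm)]^2)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(dm[i, ])[2:(k + 1)]
    for (j in nb) {
      wij <- exp(-dm[i, j]^2 / width)
      w[i, j] <- max(w[i, j], wij)
      w[j, i] <- max(w[j, i], wij)
    }
  }
  deg <- rowSums(w)
  l <- diag(deg) - w
  a_mat <- t(xc) %*% l %*% xc
  b_mat <- t(xc) %*% diag(deg) %*% xc
  b_mat <- b_mat + diag(ridge * mean(diag(b_mat)), ncol(xc))
  es <- eigen(solve(b_mat) %*% a_mat)
  ord <- order(Re(es$values))
  Re(es$vectors[, ord[seq_len(m)], drop = FALSE])
}

# Largest principal angle (radians) between the column spans of two bases.
max_principal_angle <- function(a, b) {
  qa <- qr.Q(qr(a))
  qb <- qr.Q(qr(b))
  sv <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(sv))))
}

# Small synthetic session shortcut used by many tests.
quick_session <- function(task = "ballistic", sampling_rate = 120,
                          n_runs = 1, trials_per_run = 3, seed = 1, ...) {
  generate_session(sim_config(task, sampling_rate = sampling_rate,
                              n_runs = n_runs, trials_per_run = trials_per_run,
                              seed = seed, ...))
}

no_smr <- function() default_smr_bands()[0, ]
no_noise <- function() list(pink_uv = 0, white_uv = 0, mixing = 0)

# Epoch set of pure white noise, for null-calibration tests.
null_epochs <- function(n_trials, sampling_rate = 50, sd = 1) {
  new_epoch_set(matrix(rnorm(n_trials * 9 * sampling_rate, sd = sd),
                       nrow = n_trials),
                sampling_rate = sampling_rate)
}
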