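# Shared fixtures and independent oracles used across test files.

# A minimal hand-built session: 2 neurons, 1 hide trial, 3 events.
tiny_session <- function() {
  spike_session(
    session_id = "tiny",
    neurons = c("a", "b"),
    spikes = data.frame(neuron_id = c("a", "a", "b"),
                        time_s = c(0.1, 0.6, 0.3)),
    trials = data.frame(trial_id = "t1", role = "hide",
                        start_s = 0, end_s = 2),
    events = data.frame(trial_id = "t1",
                        label = c("start", "jump out", "end"),
                        kind = "point",
                        start_s = c(0, 1.0, 2.0), end_s = NA_real_))
}

# Small well-separated state-generator config for recovery tests.
recovery_config <- function(K_true = 3, n_trials = 6, mean_sep = 3,
                            mean_trial_duration_s = 15, gp_noise_sd = 0.2,
                            ...) {
  synth_config(K_true = K_true, d_true = 2, n_neurons = 12,
               n_trials = n_trials, roles = "hide",
               mean_trial_duration_s = mean_trial_duration_s,
               mean_sep = mean_sep, gp_noise_sd = gp_noise_sd,
               tag_jitter_s = 0, tag_mislabel_rate = 0,
               n_free_states = 0, ...)
}

# Brute-force HMM log-likelihood by explicit enumeration of all K^T paths.
brute_hmm_loglik <- function(pi0, A, means, covs, X) {
  K <- length(pi0); T_bins <- ncol(X)
  dens <- function(t, k) {
    d <- nrow(X)
    ch <- chol(covs[[k]])
    z <- backsolve(ch, X[, t] - means[k, ], transpose = TRUE)
    exp(-0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2)))
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_bins)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- pi0[s[1]] * dens(1, s[1])
    if (T_bins > 1)
      for (t in 2:T_bins) pr <- pr * A[s[t - 1], s[t]] * dens(t, s[t])
    tot <- tot + pr
  }
  log(tot)
}

# Brute-force Viterbi: argmax path probability over all paths.
brute_viterbi <- function(pi0, A, means, covs, X) {
  K <- length(pi0); T_bins <- ncol(X)
  logdens <- function(t, k) {
    d <- nrow(X)
    ch <- chol(covs[[k]])
    z <- backsolve(ch, X[, t] - means[k, ], transpose = TRUE)
    -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_bins)))
  best <- -Inf; arg <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    lp <- log(pi0[s[1]]) + logdens(1, s[1])
    if (T_bins > 1)
      for (t in 2:T_bins) lp <- lp + log(A[s[t - 1], s[t]]) + logdens(t, s[t])
    if (lp > best) { best <- lp; arg <- s }
  }
  list(path = as.integer(arg), score = best)
}

# Random valid sticky-ish HMM parameters for oracle instances.
random_hmm <- function(K, d, seed) {
  set.seed(seed)
  A <- matrix(stats::runif(K * K) + diag(2, K), K, K)
  A <- A / rowSums(A)
  pi0 <- stats::runif(K); pi0 <- pi0 / sum(pi0)
  means <- matrix(stats::rnorm(K * d, sd = 2), K, d)
  covs <- lapply(seq_len(K), function(k) {
    M <- matrix(stats::rnorm(d * d, sd = 0.3), d, d)
    crossprod(M) + diag(0.5, d)
  })
  list(pi0 = pi0, A = A, means = means, covs = covs)
}

as_hmm_model <- function(par) {
  structure(list(K = length(par$pi0), pi0 = par$pi0, A = par$A,
                 means = par$means, covs = par$covs),
            class = "sticky_hmm")
}

# Brute-force minimum-cost assignment over all permutations.
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ,
                 drop = FALSE]
  costs <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  list(perm = as.integer(perms[which.min(costs), ]), cost = min(costs))
}

# Align a behavioral segmentation to the bins of an HMM segmentation.
align_to <- function(seg_b, seg_a) {
  segmentation(lapply(stats::setNames(nm = names(seg_a$labels)), function(t)
    seg_b$labels[[t]][seq_along(seg_a$labels[[t]])]), seg_a$bin_width_s)
}

# Simulate data from the GPFA generative model itself.
sim_gpfa_data <- function(C, R, taus, n_trials, T_bins, bin_width = 0.25,
                          offset = rep(0, nrow(C)), sn2 = 1e-3, seed = 1) {
  set.seed(seed)
  d <- ncol(C)
  lapply(seq_len(n_trials), function(i) {
    X <- vapply(seq_len(d), function(j) {
      K <- neuroethogram:::gp_kernel(T_bins, bin_width, taus[j], sn2)
      as.vector(t(chol(K)) %*% rnorm(T_bins))
    }, numeric(T_bins))                      # T x d
    C %*% t(X) + offset +
      matrix(rnorm(nrow(C) * T_bins), nrow(C)) * sqrt(R)
  })
}

entropy_of <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}
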