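test_that("single-state model reduces to an i.i.d. Gaussian", {
  set.seed(12)
  X <- matrix(rnorm(2 * 40), 2, 40)
  m <- fit_sticky_hmm(X, K = 1, hmm_config(n_restarts = 1, max_iter = 50))
  expect_equal(as.vector(m$means), rowMeans(X), tolerance = 1e-6)
  fb <- forward_backward(m, X)
  expect_true(all(fb$gamma == 1))
  # log-likelihood equals the sum of i.i.d. Gaussian log-densities
  ch <- chol(m$covs[[1]])
  z <- backsolve(ch, X - as.vector(m$means), transpose = TRUE)
  ll <- sum(-0.5 * (2 * log(2 * pi) + 2 * sum(log(diag(ch))) +
                      colSums(z^2)))
  expect_equal(fb$loglik, ll, tolerance = 1e-10)
  expect_true(all(viterbi_path(m, X) == 1))
})

test_that("forward and Viterbi agree with brute-force path enumeration", {
  for (seed in 1:6) {
    K <- sample(2:3, 1)
    T_bins <- sample(3:6, 1)
    par <- random_hmm(K, 2, seed = 100 + seed)
    model <- as_hmm_model(par)
    set.seed(200 + seed)
    X <- matrix(rnorm(2 * T_bins, sd = 2), 2, T_bins)
    fb <- forward_backward(model, X)
    expect_equal(fb$loglik,
                 brute_hmm_loglik(par$pi0, par$A, par$means, par$covs, X),
                 tolerance = 1e-10)
    expect_equal(rowSums(fb$gamma), rep(1, T_bins), tolerance = 1e-10)
    bv <- brute_viterbi(par$pi0, par$A, par$means, par$covs, X)
    expect_equal(viterbi_path(model, X), bv$path)
  }
})

test_that("the Viterbi path scores at least the argmax-posterior path", {
  path_score <- function(model, X, s) {
    logB <- neuroethogram:::emission_logdens(X, model$means, model$covs)
    sc <- log(model$pi0[s[1]]) + logB[1, s[1]]
    for (t in seq_along(s)[-1])
      sc <- sc + log(model$A[s[t - 1], s[t]]) + logB[t, s[t]]
    sc
  }
  for (seed in 1:4) {
    par <- random_hmm(3, 2, seed = 300 + seed)
    model <- as_hmm_model(par)
    set.seed(400 + seed)
    X <- matrix(rnorm(2 * 30, sd = 2), 2, 30)
    vp <- viterbi_path(model, X)
    gm <- max.col(forward_backward(model, X)$gamma, ties.method = "first")
    expect_gte(path_score(model, X, vp), path_score(model, X, gm) - 1e-10)
  }
})

test_that("MAP-EM is monotone, sticky, and permutation-symmetric", {
  g <- generate_session(recovery_config(), 31)
  lat <- lapply(g$truth$trials, function(tr) tr$latents)
  cfg <- hmm_config(n_restarts = 1, max_iter = 100, base_seed = 5)
  m <- fit_sticky_hmm(lat, K = 3, cfg)
  expect_true(all(diff(m$objective_trace) >=
                    -1e-8 * abs(m$objective_trace[-1])))

  # huge kappa forces near-identity transitions despite true switches
  mk <- fit_sticky_hmm(lat, K = 3, hmm_config(kappa = 1e6, n_restarts = 1,
                                              max_iter = 50))
  expect_lt(max(1 - diag(mk$A)), 1e-3)

  # permuting the state labels leaves the likelihood unchanged
  perm <- c(2, 3, 1)
  mp <- m
  mp$pi0 <- m$pi0[perm]
  mp$A <- m$A[perm, perm]
  mp$means <- m$means[perm, , drop = FALSE]
  mp$covs <- m$covs[perm]
  X <- lat[[1]]
  expect_equal(forward_backward(m, X)$loglik,
               forward_backward(mp, X)$loglik, tolerance = 1e-10)

  expect_error(fit_sticky_hmm(matrix(0, 2, 3), K = 10),
               class = "neuroethogram_validation_error")
})

test_that("states are recovered on well-separated generator data", {
  g <- generate_session(recovery_config(), 32)
  lat <- stats::setNames(lapply(g$truth$trials, function(tr) tr$latents),
                         names(g$truth$trials))
  m <- fit_sticky_hmm(lat, K = 3, hmm_config(n_restarts = 5, max_iter = 100,
                                             base_seed = 2))
  seg <- decode_segmentation(m, lat)
  acc <- matched_accuracy(unlist(seg$labels),
                          unlist(lapply(g$truth$trials, `[[`, "states")))
  expect_gte(acc, 0.95)

  # accuracy grows with state-mean separation
  accs <- vapply(c(0.3, 0.5, 0.8), function(sep) {
    gs <- generate_session(recovery_config(mean_sep = sep), 33)
    ls <- lapply(gs$truth$trials, function(tr) tr$latents)
    ms <- fit_sticky_hmm(ls, K = 3, hmm_config(n_restarts = 10,
                                               max_iter = 100))
    matched_accuracy(unlist(decode_segmentation(ms, ls)$labels),
                     unlist(lapply(gs$truth$trials, `[[`, "states")))
  }, numeric(1))
  expect_true(all(diff(accs) > 0))
})

test_that("restart bookkeeping is reproducible and exhaustive", {
  g <- generate_session(recovery_config(n_trials = 3), 34)
  lat <- lapply(g$truth$trials, function(tr) tr$latents)
  cfg <- hmm_config(n_restarts = 3, max_iter = 30, base_seed = 11)
  m1 <- fit_sticky_hmm(lat, K = 2, cfg)
  m2 <- fit_sticky_hmm(lat, K = 2, cfg)
  expect_identical(m1$diagnostics$restart_objectives,
                   m2$diagnostics$restart_objectives)
  expect_equal(m1$objective, max(m1$diagnostics$restart_objectives))
  expect_length(m1$diagnostics$restart_objectives, 3)
})

test_that("cross-validation over K returns a sensible state count", {
  sel1 <- select_num_states(list(matrix(rnorm(20), 2, 10),
                                 matrix(rnorm(20), 2, 10)),
                            Ks = 2, folds = 2,
                            hmm_config(n_restarts = 1, max_iter = 20))
  expect_equal(sel1$K, 2)
  expect_true(all(is.finite(sel1$scores$mean_loglik_per_bin)))
  expect_error(select_num_states(list(matrix(0, 1, 5)), Ks = integer(0)),
               class = "neuroethogram_validation_error")
})
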