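#' Fit configuration for the sticky HMM
#'
#' The transition prior is Dirichlet per row with concentration `alpha`
#' on every entry plus `kappa` extra mass on the diagonal; `kappa = 100`
#' strongly discourages rapid state switching. MAP-EM is restarted
#' `n_restarts` times (restart `r` is seeded `base_seed + r - 1`) and the
#' restart with the highest final MAP objective wins.
#'
#' @param alpha Dirichlet concentration (default 1).
#' @param kappa sticky diagonal mass (default 100).
#' @param n_restarts number of EM restarts (default 40).
#' @param base_seed seed of the first restart.
#' @param tol relative change in the MAP objective at which EM stops.
#' @param max_iter EM iteration cap.
#' @param cov_type `"full"` or `"diag"` emission covariances.
#' @return list of class `hmm_config`.
#' @export
hmm_config <- function(alpha = 1, kappa = 100, n_restarts = 40,
                       base_seed = 1, tol = 1e-6, max_iter = 200,
                       cov_type = c("full", "diag")) {
  stopifnot(alpha >= 0, kappa >= 0, n_restarts >= 1)
  structure(list(alpha = alpha, kappa = kappa, n_restarts = n_restarts,
                 base_seed = base_seed, tol = tol, max_iter = max_iter,
                 cov_type = match.arg(cov_type)),
            class = "hmm_config")
}

## Emission log-densities: T x K matrix for latents X (d x T).
emission_logdens <- function(X, means, covs) {
  K <- nrow(means); d <- nrow(X); T_bins <- ncol(X)
  out <- matrix(0, T_bins, K)
  for (k in seq_len(K)) {
    ch <- chol(covs[[k]])
    z <- backsolve(ch, X - means[k, ], transpose = TRUE)
    out[, k] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) +
                          colSums(z^2))
  }
  out
}

ensure_pd <- function(S, floor_frac = 1e-6, total_var = 1) {
  S <- (S + t(S)) / 2
  eps <- floor_frac * max(total_var, 1e-12)
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  tries <- 0
  while (!ok && tries < 12) {
    S <- S + diag(eps, nrow(S))
    eps <- eps * 10
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    tries <- tries + 1
  }
  S
}

log_transition_prior <- function(A, alpha, kappa) {
  W <- matrix(alpha - 1, nrow(A), ncol(A)) + diag(kappa, nrow(A))
  sum(W[W != 0] * log(pmax(A[W != 0], 1e-300)))
}

#' Fit a sticky Gaussian-emission HMM by MAP-EM with restarts
#'
#' Each trial is an independent sequence sharing the initial distribution,
#' transition matrix and emissions. The M-step for transitions adds the
#' sticky Dirichlet prior: row `i` is proportional to
#' `expected counts + alpha - 1 + kappa * (i == j)`, floored at 1e-8
#' before normalization. Emission covariance collapse is caught with a
#' ridge floor.
#'
#' @param latents list of `d x T` latent matrices (one per trial), or a
#'   single matrix.
#' @param K number of states (>= 1).
#' @param config an [hmm_config()].
#' @return list of class `sticky_hmm`: `K`, `pi0`, `A`, `means`
#'   (`K x d`), `covs` (list of `d x d`), `loglik`, `objective` (MAP),
#'   `diagnostics` (per-restart objectives and iteration counts).
#' @export
fit_sticky_hmm <- function(latents, K, config = hmm_config()) {
  if (is.matrix(latents)) latents <- list(latents)
  Ts <- vapply(latents, ncol, integer(1))
  if (K > sum(Ts))
    stop(errorCondition("K exceeds the total number of bins",
                        class = c("neuroethogram_validation_error", "error")))
  stopifnot(K >= 1, any(Ts >= 2) || K == 1)
  d <- nrow(latents[[1]])
  pooled <- t(do.call(cbind, latents))
  tot_var <- mean(apply(pooled, 2, stats::var))
  if (!is.finite(tot_var) || tot_var <= 0) tot_var <- 1
  best <- NULL
  diag_obj <- numeric(config$n_restarts)
  diag_iter <- integer(config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    set.seed(config$base_seed + r - 1L)
    fit <- em_one_restart(latents, K, d, pooled, tot_var, config)
    diag_obj[r] <- fit$objective
    diag_iter[r] <- fit$n_iter
    if (is.null(best) || fit$objective > best$objective) best <- fit
  }
  structure(list(K = K, pi0 = best$pi0, A = best$A, means = best$means,
                 covs = best$covs, loglik = best$loglik,
                 objective = best$objective,
                 objective_trace = best$trace,
                 config = config,
                 diagnostics = list(restart_objectives = diag_obj,
                                    restart_iterations = diag_iter)),
            class = "sticky_hmm")
}

em_one_restart <- function(latents, K, d, pooled, tot_var, config) {
  # init: K-means on pooled latents; sticky-uniform transitions
  if (K == 1) {
    means <- matrix(colMeans(pooled), 1, d)
    assign <- rep(1L, nrow(pooled))
  } else {
    km <- tryCatch(
      stats::kmeans(pooled, centers = K, nstart = 1, iter.max = 30),
      error = function(e) NULL)
    if (is.null(km)) {   # duplicate points etc.: jittered sample of rows
      idx <- sample.int(nrow(pooled), K)
      means <- pooled[idx, , drop = FALSE] +
        stats::rnorm(K * d, sd = sqrt(tot_var) * 0.01)
      d2 <- outer(rowSums(pooled^2), rowSums(means^2), "+") -
        2 * pooled %*% t(means)
      assign <- max.col(-d2)
    } else {
      means <- km$centers
      assign <- km$cluster
    }
  }
  covs <- lapply(seq_len(K), function(k) {
    Xk <- pooled[assign == k, , drop = FALSE]
    S <- if (nrow(Xk) > d + 1) stats::cov(Xk) else diag(tot_var, d)
    if (config$cov_type == "diag") S <- diag(diag(S), d)
    ensure_pd(S, total_var = tot_var)
  })
  self_p <- if (K == 1) 1 else (config$kappa + 1) / (config$kappa + K)
  A <- matrix((1 - self_p) / max(K - 1, 1), K, K)
  diag(A) <- self_p
  A <- A / rowSums(A)
  pi0 <- rep(1 / K, K)

  obj_old <- -Inf
  trace <- numeric(0)
  n_iter <- 0L
  for (it in seq_len(config$max_iter)) {
    n_iter <- it
    ll <- 0
    xi_sum <- matrix(0, K, K)
    g1_sum <- numeric(K)
    gam_all <- vector("list", length(latents))
    for (i in seq_along(latents)) {
      logB <- emission_logdens(latents[[i]], means, covs)
      fb <- .fb_core(logB, A, pi0)
      ll <- ll + fb$loglik
      xi_sum <- xi_sum + fb$xi
      g1_sum <- g1_sum + fb$gamma[1, ]
      gam_all[[i]] <- fb$gamma
    }
    obj <- ll + log_transition_prior(A, config$alpha, config$kappa)
    trace <- c(trace, obj)
    if (is.finite(obj_old) && abs(obj - obj_old) <= config$tol * abs(obj_old))
      break
    obj_old <- obj
    # M-step
    pi0 <- g1_sum / sum(g1_sum)
    if (K > 1) {
      W <- xi_sum + (config$alpha - 1) + diag(config$kappa, K)
      W <- pmax(W, 1e-8)
      A <- W / rowSums(W)
    }
    G <- do.call(rbind, gam_all)          # total bins x K
    wsum <- colSums(G)
    means <- crossprod(G, pooled) / wsum  # K x d
    for (k in seq_len(K)) {
      Xc <- sweep(pooled, 2, means[k, ])
      S <- crossprod(Xc * G[, k], Xc) / wsum[k]
      if (config$cov_type == "diag") S <- diag(diag(S), d)
      covs[[k]] <- ensure_pd(S, total_var = tot_var)
    }
  }
  list(pi0 = pi0, A = A, means = means, covs = covs,
       loglik = ll, objective = obj, trace = trace, n_iter = n_iter)
}

#' Forward-backward posterior state probabilities
#'
#' @param model a `sticky_hmm`.
#' @param latents `d x T` latent matrix of one trial.
#' @return list: `loglik`, `gamma` (`T x K`; each row sums to 1).
#' @export
forward_backward <- function(model, latents) {
  if (!all(is.finite(latents)))
    stop(errorCondition("non-finite latent values",
                        class = c("neuroethogram_validation_error", "error")))
  if (nrow(latents) != ncol(model$means))
    stop(errorCondition("latent dimensionality does not match the model",
                        class = c("neuroethogram_validation_error", "error")))
  logB <- emission_logdens(latents, model$means, model$covs)
  fb <- .fb_core(logB, model$A, model$pi0)
  list(loglik = fb$loglik, gamma = fb$gamma)
}

#' Most likely state path (Viterbi)
#'
#' Ties are broken toward the lower state index.
#'
#' @inheritParams forward_backward
#' @return integer vector of 1-based state labels per bin.
#' @export
viterbi_path <- function(model, latents) {
  if (!all(is.finite(latents)))
    stop(errorCondition("non-finite latent values",
                        class = c("neuroethogram_validation_error", "error")))
  logB <- emission_logdens(latents, model$means, model$covs)
  .viterbi_core(logB, model$A, model$pi0) + 1L
}

#' Segment trials with a fitted model
#'
#' @param model a `sticky_hmm`.
#' @param latents named list of `d x T` matrices (names = trial ids).
#' @param bin_width_s bin width of the latents.
#' @param method `"viterbi"` (default) or `"gamma"` (per-bin argmax of the
#'   posterior).
#' @return a [segmentation()].
#' @export
decode_segmentation <- function(model, latents, bin_width_s = 0.25,
                                method = c("viterbi", "gamma")) {
  method <- match.arg(method)
  labs <- lapply(latents, function(X) {
    if (method == "viterbi") viterbi_path(model, X)
    else max.col(forward_backward(model, X)$gamma, ties.method = "first")
  })
  segmentation(labs, bin_width_s)
}

#' Cross-validated selection of the number of states
#'
#' Trials are partitioned into folds; for every candidate K an HMM is fit
#' on the training trials and scored by the summed held-out
#' log-likelihood divided by the held-out bin count; the K maximizing the
#' mean across folds is chosen.
#'
#' @param latents list of `d x T` matrices, at least `folds` of them.
#' @param Ks candidate state counts.
#' @param folds number of folds (default 10).
#' @param config an [hmm_config()].
#' @return list: `K` (chosen), `scores` (data.frame `K`,
#'   `mean_loglik_per_bin`), `per_fold` matrix.
#' @export
select_num_states <- function(latents, Ks, folds = 10,
                              config = hmm_config()) {
  if (!length(Ks))
    stop(errorCondition("empty candidate K list",
                        class = c("neuroethogram_validation_error", "error")))
  n <- length(latents)
  stopifnot(n >= folds)
  set.seed(config$base_seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  per_fold <- matrix(NA_real_, folds, length(Ks),
                     dimnames = list(NULL, paste0("K", Ks)))
  for (f in seq_len(folds)) {
    train <- latents[fold != f]
    test <- latents[fold == f]
    for (j in seq_along(Ks)) {
      m <- fit_sticky_hmm(train, Ks[j], config)
      ll <- sum(vapply(test, function(X) forward_backward(m, X)$loglik,
                       numeric(1)))
      per_fold[f, j] <- ll / sum(vapply(test, ncol, integer(1)))
    }
  }
  scores <- colMeans(per_fold)
  list(K = Ks[which.max(scores)],
       scores = data.frame(K = Ks, mean_loglik_per_bin = scores),
       per_fold = per_fold)
}

#' Permutation-matched labeling accuracy
#'
#' Best agreement between two labelings over all permutations of the
#' first labeling's states onto the second's, found with the Hungarian
#' algorithm on the negative confusion matrix.
#'
#' @param labels,truth equal-length integer label vectors.
#' @return fraction of positions matched under the best permutation.
#' @export
matched_accuracy <- function(labels, truth) {
  stopifnot(length(labels) == length(truth))
  la <- sort(unique(labels)); lb <- sort(unique(truth))
  n <- max(length(la), length(lb))
  conf <- matrix(0, n, n)
  tab <- table(factor(labels, levels = la), factor(truth, levels = lb))
  conf[seq_along(la), seq_along(lb)] <- tab
  as_perm <- hungarian_assignment(-conf)
  sum(conf[cbind(seq_len(n), as_perm)]) / length(labels)
}
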