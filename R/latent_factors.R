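## Factor analysis: y ~ N(mu, C C' + Psi), Psi diagonal. EM in covariance
## form (sufficient statistics: sample mean and MLE covariance), so each
## iteration is O(p^2 d) regardless of the number of samples.

#' Fit a factor-analysis model by EM
#'
#' @param Y `samples x channels` matrix (rates or counts).
#' @param d number of factors (>= 1, < samples).
#' @param seed RNG seed for the random initialization.
#' @param tol relative log-likelihood change at which EM stops.
#' @param max_iter iteration cap.
#' @return list of class `fa_model`: `C` (`channels x d`), `mean`, `psi`
#'   (diagonal noise), `loglik` (training log-likelihood per sample),
#'   `loglik_trace`.
#' @export
fit_factor_analysis <- function(Y, d, seed = 1, tol = 1e-8, max_iter = 500) {
  stopifnot(d >= 1, nrow(Y) > d)
  p <- ncol(Y)
  mu <- colMeans(Y)
  S <- crossprod(sweep(Y, 2, mu)) / nrow(Y)
  v <- diag(S)
  if (any(v <= 0)) {
    message("zero-variance channel(s): ridge added")
    ridge <- 1e-6 * mean(v[v > 0])
    diag(S) <- diag(S) + ifelse(v <= 0, ridge, 0)
    v <- diag(S)
  }
  set.seed(seed)
  C <- matrix(stats::rnorm(p * d), p, d) * sqrt(mean(v) / d)
  psi <- v / 2
  ll_of <- function(C, psi) {
    Sig <- tcrossprod(C) + diag(psi, p)
    ch <- chol(Sig)
    -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(ch))) +
              sum(diag(chol2inv(ch) %*% S)))
  }
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E-step moments through the d x d system
    PiC <- C / psi
    G <- solve(diag(1, d) + crossprod(C, PiC))      # posterior cov of z
    beta <- tcrossprod(G, PiC)                      # d x p
    SB <- S %*% t(beta)                             # p x d
    Ezz <- G + beta %*% SB
    C <- SB %*% solve(Ezz)
    psi <- pmax(diag(S - C %*% (beta %*% S)), 1e-8)
    ll <- ll_of(C, psi)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) break
    ll_old <- ll
  }
  structure(list(C = C, mean = mu, psi = psi, d = d,
                 loglik = trace[length(trace)], loglik_trace = trace),
            class = "fa_model")
}

#' Log-likelihood of data under a factor-analysis model
#'
#' @param model an `fa_model`.
#' @param Y `samples x channels` matrix.
#' @return total log-likelihood of the rows of `Y`.
#' @export
loglik_fa <- function(model, Y) {
  p <- ncol(Y)
  Sig <- tcrossprod(model$C) + diag(model$psi, p)
  ch <- chol(Sig)
  Yc <- sweep(Y, 2, model$mean)
  q <- colSums(backsolve(ch, t(Yc), transpose = TRUE)^2)  # one per sample
  sum(-0.5 * (p * log(2 * pi) + 2 * sum(log(diag(ch))) + q))
}

#' Select latent dimensionality by cross-validated FA plus shared variance
#'
#' Two steps: (1) the candidate maximizing the cross-validated
#' log-likelihood is found; (2) the shared covariance of that model
#' (Gram matrix of the loadings, `t(C) %*% C`) is eigendecomposed and the
#' smallest dimensionality capturing 95% of its variance is returned.
#'
#' @param Y `samples x channels` matrix.
#' @param dims candidate dimensionalities.
#' @param folds CV folds (default 5).
#' @param seed RNG seed (fold assignment + initializations).
#' @param var_frac shared-variance fraction to capture (default 0.95).
#' @return list: `d` (chosen), `d_cv` (step-1 argmax), `cv` (data.frame),
#'   `eigenfractions`.
#' @export
select_dimensionality <- function(Y, dims, folds = 5, seed = 1,
                                  var_frac = 0.95) {
  if (!length(dims))
    stop(errorCondition("empty candidate dimensionality list",
                        class = c("neuroethogram_validation_error", "error")))
  stopifnot(folds >= 2)
  n <- nrow(Y)
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  cv <- vapply(dims, function(d) {
    mean(vapply(seq_len(folds), function(f) {
      m <- fit_factor_analysis(Y[fold != f, , drop = FALSE], d, seed = seed)
      loglik_fa(m, Y[fold == f, , drop = FALSE]) / sum(fold == f)
    }, numeric(1)))
  }, numeric(1))
  d_cv <- dims[which.max(cv)]
  m <- fit_factor_analysis(Y, d_cv, seed = seed)
  ev <- eigen(crossprod(m$C), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  frac <- cumsum(ev) / sum(ev)
  d <- which(frac >= var_frac)[1]
  if (is.na(d)) d <- d_cv
  list(d = max(1L, d), d_cv = d_cv,
       cv = data.frame(d = dims, loglik = cv), eigenfractions = frac)
}

## ---- GPFA ------------------------------------------------------------------
## Observation model y_t = C x_t + d + eps, eps ~ N(0, R diag); each latent
## is an independent GP over the bin grid with squared-exponential kernel
## K(dt) = (1 - sn2) exp(-dt^2 / (2 tau^2)) + sn2 [dt == 0].
## Latents are stacked latent-major (x_1(1..T), x_2(1..T), ...), making the
## prior block-diagonal and the likelihood precision M (x) I_T with
## M = C' R^-1 C.

gp_kernel <- function(T_bins, bin_width_s, tau, sn2 = 1e-3) {
  t <- (seq_len(T_bins) - 1) * bin_width_s
  (1 - sn2) * exp(-outer(t, t, "-")^2 / (2 * tau^2)) +
    diag(sn2, T_bins)
}

## E-step for one trial; returns posterior mean (d x T), the summed
## second moment sum_t E[x_t x_t'] (d x d), per-latent T x T second
## moments, and the trial log-likelihood.
gpfa_estep_trial <- function(Yc, C, R, taus, bin_width_s, sn2,
                             want_blocks = TRUE) {
  d <- ncol(C); T_bins <- ncol(Yc)
  Kinv_list <- vector("list", d)
  logdetK <- 0
  for (j in seq_len(d)) {
    ch <- chol(gp_kernel(T_bins, bin_width_s, taus[j], sn2))
    logdetK <- logdetK + 2 * sum(log(diag(ch)))
    Kinv_list[[j]] <- chol2inv(ch)
  }
  M <- crossprod(C / R, C)                       # d x d
  B <- crossprod(C / R, Yc)                      # d x T  (C' R^-1 Yc)
  n <- d * T_bins
  P <- matrix(0, n, n)
  for (j in seq_len(d)) {
    idx_j <- ((j - 1) * T_bins + 1):(j * T_bins)
    P[idx_j, idx_j] <- Kinv_list[[j]]
    for (l in seq_len(d)) {   # likelihood block (j,l) is M[j,l] * I_T
      idx_l <- ((l - 1) * T_bins + 1):(l * T_bins)
      P[cbind(idx_j, idx_l)] <- P[cbind(idx_j, idx_l)] + M[j, l]
    }
  }
  chP <- chol(P)
  b <- as.vector(t(B))                           # latent-major stacking
  half <- backsolve(chP, b, transpose = TRUE)
  mean_vec <- backsolve(chP, half)
  Xhat <- matrix(mean_vec, T_bins, d)            # T x d
  Sig <- chol2inv(chP)
  # sum_t E[x_t x_t'] = sum_t xhat xhat' + diagonal-time blocks of Sig
  Exx <- matrix(0, d, d)
  for (j in seq_len(d)) for (l in seq_len(d)) {
    dj <- (j - 1) * T_bins; dl <- (l - 1) * T_bins
    Exx[j, l] <- sum(Xhat[, j] * Xhat[, l]) +
      sum(Sig[cbind(dj + seq_len(T_bins), dl + seq_len(T_bins))])
  }
  blocks <- NULL
  if (want_blocks) {
    blocks <- lapply(seq_len(d), function(j) {
      idx <- ((j - 1) * T_bins + 1):(j * T_bins)
      Sig[idx, idx] + tcrossprod(Xhat[, j])
    })
  }
  quad_data <- sum(Yc^2 / R)
  ll <- -0.5 * (nrow(Yc) * T_bins * log(2 * pi) +
                  T_bins * sum(log(R)) + logdetK +
                  2 * sum(log(diag(chP))) + quad_data - sum(b * mean_vec))
  list(xhat = t(Xhat), Exx = Exx, blocks = blocks, loglik = ll)
}

#' Fit GPFA to binned trials by EM
#'
#' Linear-Gaussian observation model with independent squared-exponential
#' GP priors per latent on the bin grid. The E-step is exact Gaussian
#' conditioning per trial; the M-step updates loadings, offsets and the
#' diagonal observation noise in closed form, and the GP timescales by
#' bounded 1-D optimization of the expected complete-data log-likelihood.
#' The GP signal variance is fixed to `1 - sn2` with a small noise floor
#' `sn2`, following the usual GPFA convention.
#'
#' @param trials list of `neurons x bins` count matrices (or
#'   `binned_trial` objects).
#' @param d latent dimensionality.
#' @param bin_width_s bin width in seconds.
#' @param seed RNG seed for initialization.
#' @param tol relative log-likelihood stopping tolerance.
#' @param max_iter EM iteration cap.
#' @param tau_init initial GP timescale (seconds).
#' @param sn2 GP noise-floor variance.
#' @param learn_tau update timescales during EM?
#' @param sqrt_transform square-root transform the counts first
#'   (off by default; counts are fed in untransformed).
#' @return list of class `gpfa_model`: `C`, `offset`, `R`, `taus`,
#'   `bin_width_s`, `sn2`, `latents` (list of `d x T` posterior means),
#'   `loglik_trace`.
#' @export
fit_gpfa <- function(trials, d, bin_width_s = 0.25, seed = 1, tol = 1e-6,
                     max_iter = 100, tau_init = 0.5, sn2 = 1e-3,
                     learn_tau = TRUE, sqrt_transform = FALSE) {
  stopifnot(d >= 1, length(trials) >= 1)
  Ys <- lapply(trials, function(tr)
    if (inherits(tr, "binned_trial")) tr$counts else tr)
  Ys <- lapply(Ys, function(Y) {
    Y <- as.matrix(Y) * 1.0
    if (sqrt_transform) sqrt(Y) else Y
  })
  short <- vapply(Ys, ncol, integer(1)) < 2
  if (any(short)) {
    warning(sprintf("%d trial(s) with fewer than 2 bins skipped",
                    sum(short)))
    Ys <- Ys[!short]
  }
  N <- nrow(Ys[[1]])
  # initialize from factor analysis on pooled bins
  pooled <- t(do.call(cbind, Ys))
  fa <- fit_factor_analysis(pooled, d, seed = seed)
  C <- fa$C; offset <- fa$mean; R <- pmax(fa$psi, 1e-6)
  taus <- rep(tau_init, d)
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    sum_ll <- 0
    Sxx <- matrix(0, d + 1, d + 1)      # sum E[ [x;1][x;1]' ]
    Sxy <- matrix(0, d + 1, N)          # sum E[ [x;1] ] y'
    Syy_diag <- numeric(N)
    blocks_acc <- replicate(d, list(), simplify = FALSE)
    xhats <- vector("list", length(Ys))
    for (i in seq_along(Ys)) {
      Yc <- Ys[[i]] - offset
      es <- gpfa_estep_trial(Yc, C, R, taus, bin_width_s, sn2,
                             want_blocks = learn_tau)
      sum_ll <- sum_ll + es$loglik
      Tb <- ncol(Yc)
      Sxx[1:d, 1:d] <- Sxx[1:d, 1:d] + es$Exx
      sx <- rowSums(es$xhat)
      Sxx[1:d, d + 1] <- Sxx[1:d, d + 1] + sx
      Sxx[d + 1, 1:d] <- Sxx[d + 1, 1:d] + sx
      Sxx[d + 1, d + 1] <- Sxx[d + 1, d + 1] + Tb
      Sxy[1:d, ] <- Sxy[1:d, ] + es$xhat %*% t(Ys[[i]])
      Sxy[d + 1, ] <- Sxy[d + 1, ] + rowSums(Ys[[i]])
      Syy_diag <- Syy_diag + rowSums(Ys[[i]]^2)
      if (learn_tau)
        for (j in seq_len(d))
          blocks_acc[[j]][[length(blocks_acc[[j]]) + 1]] <- es$blocks[[j]]
      xhats[[i]] <- es$xhat
    }
    trace <- c(trace, sum_ll)
    if (is.finite(ll_old) &&
        abs(sum_ll - ll_old) <= tol * abs(ll_old)) break
    ll_old <- sum_ll
    # M-step: loadings and offset jointly, then noise
    W <- t(solve(Sxx, Sxy))             # N x (d+1): [C offset]
    C <- W[, 1:d, drop = FALSE]
    offset <- W[, d + 1]
    Ttot <- sum(vapply(Ys, ncol, integer(1)))
    R <- pmax((Syy_diag - rowSums(W * t(Sxy))) / Ttot, 1e-6)
    if (learn_tau) {
      Tls <- vapply(Ys, ncol, integer(1))
      for (j in seq_len(d)) {
        obj <- function(log_tau) {
          tau <- exp(log_tau)
          tot <- 0
          for (i in seq_along(Ys)) {
            ch <- chol(gp_kernel(Tls[i], bin_width_s, tau, sn2))
            Ki <- chol2inv(ch)
            tot <- tot + 2 * sum(log(diag(ch))) +
              sum(Ki * blocks_acc[[j]][[i]])
          }
          tot
        }
        taus[j] <- exp(stats::optimize(obj, c(log(bin_width_s / 2), log(10)),
                                       tol = 1e-2)$minimum)
      }
    }
  }
  structure(list(C = C, offset = offset, R = R, taus = taus,
                 bin_width_s = bin_width_s, sn2 = sn2,
                 sqrt_transform = sqrt_transform,
                 latents = lapply(Ys, function(Y) {
                   gpfa_estep_trial(Y - offset, C, R, taus, bin_width_s,
                                    sn2, want_blocks = FALSE)$xhat
                 }),
                 loglik_trace = trace),
            class = "gpfa_model")
}

#' Posterior-mean latent trajectory of one trial under a fitted model
#'
#' Exact Gaussian conditioning; deterministic given the model.
#'
#' @param model a `gpfa_model`.
#' @param binned a `binned_trial` or `neurons x bins` count matrix.
#' @return `d x bins` matrix of posterior means.
#' @export
infer_latents <- function(model, binned) {
  Y <- if (inherits(binned, "binned_trial")) binned$counts else binned
  Y <- as.matrix(Y) * 1.0
  if (isTRUE(model$sqrt_transform)) Y <- sqrt(Y)
  if (nrow(Y) != nrow(model$C))
    stop(errorCondition("neuron count does not match the model",
                        class = c("neuroethogram_validation_error", "error")))
  gpfa_estep_trial(Y - model$offset, model$C, model$R, model$taus,
                   model$bin_width_s, model$sn2,
                   want_blocks = FALSE)$xhat
}

#' Marginal log-likelihood of trials under a fitted GPFA model
#'
#' @param model a `gpfa_model`.
#' @param trials list of count matrices or `binned_trial`s.
#' @return total log-likelihood.
#' @export
loglik_gpfa <- function(model, trials) {
  Ys <- lapply(trials, function(tr)
    if (inherits(tr, "binned_trial")) tr$counts else tr)
  sum(vapply(Ys, function(Y) {
    Y <- as.matrix(Y) * 1.0
    if (isTRUE(model$sqrt_transform)) Y <- sqrt(Y)
    gpfa_estep_trial(Y - model$offset, model$C, model$R, model$taus,
                     model$bin_width_s, model$sn2,
                     want_blocks = FALSE)$loglik
  }, numeric(1)))
}

#' Principal angles between two column spans
#'
#' Utility for subspace-recovery checks: the angles (degrees) between the
#' column spaces of two loading matrices.
#'
#' @param A,B matrices with the same number of rows.
#' @return numeric vector of principal angles in degrees.
#' @export
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  sv <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(sv, -1), 1)) * 180 / pi
}
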