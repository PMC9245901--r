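## Generative model: a session is a set of trials; within a trial the
## population moves through discrete latent states with Markovian (sticky)
## dynamics; each state has a stereotyped latent-factor vector; factors plus
## smooth GP noise drive per-neuron firing rates through a softplus link;
## spike counts are Poisson given the rates. Behavioral tags are imperfect
## observations of the true state boundaries (Gaussian jitter on phase
## points, label noise on behavior intervals).

#' Configuration of the synthetic session generator
#'
#' Defaults emulate one hide-and-seek-style recording: 10 simultaneously
#' recorded neurons (the real sessions carry 5-31), 10 trials per role,
#' ~60 s trials, 250 ms bins, 8 latent states of which 6 are locked to the
#' game phases and the rest are short "darting"-like free states, 3 latent
#' factors, GP noise with a 0.5 s timescale, tag jitter 0.5 s and a 5%
#' interval mislabeling rate.
#'
#' @param K_true number of latent states.
#' @param d_true latent dimensionality.
#' @param n_neurons neurons per session.
#' @param n_trials trials per role.
#' @param roles character subset of `c("hide","seek","observing")`.
#' @param bin_width_s bin width (seconds).
#' @param mean_trial_duration_s mean trial duration (gamma-distributed,
#'   shape 10).
#' @param stickiness expected dwell, in bins, of free states and of every
#'   state in free-running (cyclic) chains; phase-state dwell inside a
#'   trial is set by the trial length instead (see Details).
#' @param state_means `K_true x d_true` matrix of per-state latent means;
#'   `NULL` for an axis-aligned separated default with separation `mean_sep`.
#' @param mean_sep separation scale of the default state means.
#' @param loading `n_neurons x d_true` factor-loading matrix; `NULL` to
#'   draw `N(0, 1/sqrt(d_true))` entries when the config is resolved.
#' @param baseline_log_rate per-neuron offset on the softplus scale;
#'   `NULL` for a default giving ~5 spikes/s baseline.
#' @param gp_timescale_s squared-exponential GP timescale of the latent
#'   noise (seconds).
#' @param gp_noise_sd marginal SD of the latent GP noise; 0 gives
#'   piecewise-constant latents.
#' @param tag_jitter_s SD of the Gaussian jitter applied to phase-point
#'   tags (seconds).
#' @param tag_mislabel_rate probability that a behavior interval is tagged
#'   with a wrong label.
#' @param free_state_prob probability of inserting a free state between
#'   two consecutive phase segments.
#' @param n_free_states how many of the `K_true` states are free
#'   (non-phase-locked); `NULL` picks 2 when room allows (capped so at
#'   least one state per game phase remains).
#' @param phase_state_map `NULL` for the default described in Details, or
#'   a named list `role -> named list(interval label -> integer state ids)`.
#' @return object of class `synth_config`.
#' @details Trials progress once through the role's game-phase intervals
#'   (seek has "box open", hide does not); the states assigned to an
#'   interval occur in order inside it. Phase dwell means scale with the
#'   trial length so each phase occurs exactly once per trial, which is
#'   what makes one tag per phase per trial well defined; `stickiness`
#'   governs everything whose duration is not tied to the trial: free
#'   states and free-running chains sampled with `cyclic = TRUE`.
#' @export
synth_config <- function(K_true = 8, d_true = 3, n_neurons = 10,
                         n_trials = 10, roles = c("hide", "seek"),
                         bin_width_s = 0.25, mean_trial_duration_s = 60,
                         stickiness = 8, state_means = NULL, mean_sep = 2,
                         loading = NULL, baseline_log_rate = NULL,
                         gp_timescale_s = 0.5, gp_noise_sd = 0.3,
                         tag_jitter_s = 0.5, tag_mislabel_rate = 0.05,
                         free_state_prob = 0.3, n_free_states = NULL,
                         phase_state_map = NULL) {
  cfg_err <- function(msg) stop(errorCondition(msg,
    class = c("neuroethogram_config_error", "error")))
  if (K_true < 1) cfg_err("K_true must be >= 1")
  if (stickiness < 1) cfg_err("stickiness must be >= 1")
  if (gp_timescale_s <= 0) cfg_err("gp_timescale_s must be positive")
  if (tag_jitter_s < 0) cfg_err("tag_jitter_s must be non-negative")
  if (tag_mislabel_rate < 0 || tag_mislabel_rate > 1)
    cfg_err("tag_mislabel_rate must lie in [0,1]")
  if (!all(roles %in% ROLES)) cfg_err("unknown role in roles")
  if (is.null(n_free_states)) {
    n_phase <- length(seek_intervals())
    n_free_states <- if (!any(roles %in% c("hide", "seek"))) 0L
      else max(0L, min(2L, K_true - n_phase))
  }
  structure(list(
    K_true = as.integer(K_true), d_true = as.integer(d_true),
    n_neurons = as.integer(n_neurons), n_trials = as.integer(n_trials),
    roles = roles, bin_width_s = bin_width_s,
    mean_trial_duration_s = mean_trial_duration_s, stickiness = stickiness,
    state_means = state_means, mean_sep = mean_sep, loading = loading,
    baseline_log_rate = baseline_log_rate, gp_timescale_s = gp_timescale_s,
    gp_noise_sd = gp_noise_sd, tag_jitter_s = tag_jitter_s,
    tag_mislabel_rate = tag_mislabel_rate,
    free_state_prob = free_state_prob,
    n_free_states = as.integer(n_free_states),
    phase_state_map = phase_state_map,
    rng_kind = "Mersenne-Twister"
  ), class = "synth_config")
}

seek_intervals <- function() c("start", "box open", "jump out",
                               "interaction", "return transit", "jump in")
hide_intervals <- function() setdiff(seek_intervals(), "box open")
FREE_LABELS <- c("darting", "exploring")
OBSERVING_LABELS <- c("grooming", "engaged", "resting")

## Distribute `states` (ordered) over `intervals` so every interval gets at
## least one state (recycling states if there are fewer states than
## intervals) and the order is preserved.
distribute_states <- function(states, intervals) {
  P <- length(intervals)
  K <- length(states)
  if (K < P) states <- states[((seq_len(P) - 1L) %% K) + 1L]
  K <- length(states)
  cuts <- round(seq(0, K, length.out = P + 1L))
  out <- lapply(seq_len(P), function(j) states[(cuts[j] + 1L):cuts[j + 1L]])
  names(out) <- intervals
  out
}

## Default state layout: play phases take the first states (seek order;
## hide reuses the shared ones), then free states, then observing states.
default_phase_state_map <- function(cfg) {
  K <- cfg$K_true
  roles <- cfg$roles
  has_play <- any(roles %in% c("hide", "seek"))
  has_obs <- "observing" %in% roles
  K_obs <- if (has_obs && has_play) max(1L, K %/% 3L)
           else if (has_obs) K else 0L
  K_play <- K - K_obs
  map <- list()
  if (has_play) {
    K_free <- min(cfg$n_free_states, max(0L, K_play - 1L))
    K_phase <- K_play - K_free
    seek_map <- distribute_states(seq_len(K_phase), seek_intervals())
    if ("seek" %in% roles) map$seek <- seek_map
    if ("hide" %in% roles) map$hide <- seek_map[hide_intervals()]
  }
  if (has_obs) {
    obs_states <- (K - K_obs + 1L):K
    labs <- OBSERVING_LABELS[((seq_along(obs_states) - 1L) %%
                                length(OBSERVING_LABELS)) + 1L]
    labs <- make.unique(labs)
    map$observing <- distribute_states(obs_states, labs)
  }
  map
}

free_states_of <- function(cfg) {
  map <- phase_state_map_of(cfg)
  setdiff(seq_len(cfg$K_true), sort(unique(unlist(map))))
}

phase_state_map_of <- function(cfg) {
  if (is.null(cfg$phase_state_map)) default_phase_state_map(cfg)
  else cfg$phase_state_map
}

## Fill in data-dependent defaults (means, loadings, offsets) using the
## current RNG stream, so a resolved config is fully explicit.
#' Resolve a synthetic configuration
#'
#' Materializes `state_means`, `loading` and `baseline_log_rate` when they
#' were left `NULL` (the loading is drawn from the current RNG stream) and
#' attaches the phase-state map actually used.
#'
#' @param cfg a [synth_config()].
#' @return a `synth_config` with all matrices present.
#' @export
resolve_config <- function(cfg) {
  if (is.null(cfg$state_means)) {
    m <- matrix(0, cfg$K_true, cfg$d_true)
    for (k in seq_len(cfg$K_true)) {
      j <- ((k - 1L) %% cfg$d_true) + 1L
      lvl <- ceiling(k / cfg$d_true)
      m[k, j] <- cfg$mean_sep * lvl * (-1)^lvl
    }
    cfg$state_means <- m
  }
  if (is.null(cfg$loading))
    cfg$loading <- matrix(stats::rnorm(cfg$n_neurons * cfg$d_true,
                                       sd = 1 / sqrt(cfg$d_true)),
                          cfg$n_neurons, cfg$d_true)
  if (is.null(cfg$baseline_log_rate))
    cfg$baseline_log_rate <- rep(log(expm1(5)), cfg$n_neurons)
  cfg$phase_state_map <- phase_state_map_of(cfg)
  cfg
}

geom_dwell <- function(n, mean_dwell, cap = .Machine$integer.max %/% 2L) {
  if (mean_dwell <= 1) return(rep(1L, n))
  pmin(1L + stats::rgeom(n, prob = 1 / mean_dwell), cap)
}

## Allocate exactly n_bins over segments: free segments keep their drawn
## (short) dwell, phase segments share the rest proportionally, >= 1 each.
allocate_bins <- function(raw, is_free, n_bins) {
  n <- length(raw)
  if (n_bins < n) n_bins <- n  # degenerate: one bin per segment minimum
  alloc <- integer(n)
  free_total <- sum(raw[is_free])
  budget_free <- min(free_total, max(0L, n_bins - sum(!is_free)))
  if (any(is_free) && free_total > 0) {
    scl <- budget_free / free_total
    alloc[is_free] <- pmax(1L, floor(raw[is_free] * scl))
    over <- sum(alloc[is_free]) - budget_free
    while (over > 0) {  # trim largest free segments if rounding overshot
      i <- which(is_free & alloc > 1L)[which.max(alloc[is_free & alloc > 1L])]
      if (!length(i) || is.na(i)) break
      alloc[i] <- alloc[i] - 1L; over <- over - 1L
    }
  }
  rest <- n_bins - sum(alloc[is_free])
  ph <- which(!is_free)
  w <- raw[ph] / sum(raw[ph])
  tgt <- w * rest
  base <- pmax(1L, floor(tgt))
  # distribute remainder by largest fractional part, deterministically
  rem <- rest - sum(base)
  if (rem > 0) {
    ord <- order(tgt - floor(tgt), decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    ord <- order(base, decreasing = TRUE)
    i <- 1L
    while (rem < 0) {
      j <- ord[((i - 1L) %% length(ord)) + 1L]
      if (base[j] > 1L) { base[j] <- base[j] - 1L; rem <- rem + 1L }
      i <- i + 1L
    }
  }
  alloc[ph] <- base
  alloc
}

#' Sample a latent state sequence
#'
#' With `cyclic = FALSE` (the within-trial mode) the chain makes a single
#' pass through the role's phase intervals; each interval's states occur
#' once, with dwell means proportional to `n_bins` so the whole trial is
#' covered, and free states are inserted between phase segments with
#' probability `free_state_prob` and expected dwell `stickiness` bins.
#' With `cyclic = TRUE` the chain revisits the phase states indefinitely
#' and every dwell is geometric with mean `stickiness` bins, so the
#' long-run self-transition frequency is `1 - 1/stickiness`.
#'
#' @param cfg a [synth_config()].
#' @param role one of the config's roles.
#' @param n_bins number of bins to generate.
#' @param cyclic free-running mode (see above).
#' @return integer vector of state labels (1-based) of length `n_bins`,
#'   with attribute `"segments"`: data.frame `label`, `state`, `first_bin`,
#'   `last_bin`, `is_phase`, `interval_start` (logical: first segment of
#'   its phase interval).
#' @export
sample_state_sequence <- function(cfg, role, n_bins, cyclic = FALSE) {
  map <- phase_state_map_of(cfg)[[role]]
  if (is.null(map) || !length(map))
    stop(errorCondition(sprintf("no phase/state map for role '%s'", role),
                        class = c("neuroethogram_config_error", "error")))
  stopifnot(n_bins >= 1)
  free <- free_states_of(cfg)
  is_phase_role <- role %in% c("hide", "seek")
  proto <- data.frame(
    label = rep(names(map), lengths(map)),
    state = unlist(map, use.names = FALSE),
    interval_start = unlist(lapply(lengths(map), function(l)
      c(TRUE, rep(FALSE, l - 1L))), use.names = FALSE),
    stringsAsFactors = FALSE)

  if (cyclic) {
    states <- integer(0); labels <- character(0); iv <- logical(0)
    isph <- logical(0)
    i <- 1L
    while (length(states) < n_bins) {
      d <- geom_dwell(1L, cfg$stickiness, cap = n_bins - length(states))
      row <- proto[((i - 1L) %% nrow(proto)) + 1L, ]
      states <- c(states, rep(row$state, d))
      labels <- c(labels, rep(row$label, d))
      iv <- c(iv, rep(row$interval_start, d))
      isph <- c(isph, rep(is_phase_role, d))
      if (length(free) && stats::runif(1) < cfg$free_state_prob &&
          length(states) < n_bins) {
        fs <- free[sample.int(length(free), 1L)]
        fl <- FREE_LABELS[((match(fs, free) - 1L) %% length(FREE_LABELS)) + 1L]
        d2 <- geom_dwell(1L, cfg$stickiness, cap = n_bins - length(states))
        states <- c(states, rep(fs, d2))
        labels <- c(labels, rep(fl, d2))
        iv <- c(iv, rep(FALSE, d2)); isph <- c(isph, rep(FALSE, d2))
      }
      i <- i + 1L
    }
    states <- states[seq_len(n_bins)]
    labels <- labels[seq_len(n_bins)]
    iv <- iv[seq_len(n_bins)]; isph <- isph[seq_len(n_bins)]
    return(states_with_segments(states, labels, isph, iv))
  }

  # single pass: interleave free inserts between phase segments
  seg_label <- character(0); seg_state <- integer(0)
  seg_free <- logical(0); seg_iv <- logical(0)
  for (i in seq_len(nrow(proto))) {
    seg_label <- c(seg_label, proto$label[i])
    seg_state <- c(seg_state, proto$state[i])
    seg_free <- c(seg_free, FALSE)
    seg_iv <- c(seg_iv, proto$interval_start[i])
    if (i < nrow(proto) && length(free) &&
        stats::runif(1) < cfg$free_state_prob) {
      fs <- free[sample.int(length(free), 1L)]
      fl <- FREE_LABELS[((match(fs, free) - 1L) %% length(FREE_LABELS)) + 1L]
      seg_label <- c(seg_label, fl)
      seg_state <- c(seg_state, fs)
      seg_free <- c(seg_free, TRUE)
      seg_iv <- c(seg_iv, FALSE)
    }
  }
  n_phase_segs <- sum(!seg_free)
  raw <- integer(length(seg_state))
  raw[!seg_free] <- geom_dwell(n_phase_segs, max(1, n_bins / n_phase_segs))
  raw[seg_free] <- geom_dwell(sum(seg_free), cfg$stickiness)
  alloc <- allocate_bins(raw, seg_free, n_bins)
  states <- rep(seg_state, alloc)
  labels <- rep(seg_label, alloc)
  iv <- unlist(lapply(seq_along(alloc), function(i)
    c(seg_iv[i], rep(FALSE, alloc[i] - 1L))))
  isph <- rep(!seg_free & is_phase_role, alloc)
  states_with_segments(states[seq_len(n_bins)], labels[seq_len(n_bins)],
                       isph[seq_len(n_bins)], iv[seq_len(n_bins)])
}

states_with_segments <- function(states, labels, is_phase, interval_start) {
  key <- paste(states, labels)
  brk <- c(TRUE, key[-1] != key[-length(key)]) | interval_start
  id <- cumsum(brk)
  first <- which(brk)
  last <- c(first[-1] - 1L, length(states))
  seg <- data.frame(label = labels[first], state = states[first],
                    first_bin = first, last_bin = last,
                    is_phase = is_phase[first],
                    interval_start = interval_start[first],
                    stringsAsFactors = FALSE)
  attr(states, "segments") <- seg
  states
}

## Cholesky factor of the squared-exponential GP covariance on the bin grid.
se_chol <- function(T_bins, bin_width_s, timescale_s, sd, jitter = 1e-8) {
  t <- (seq_len(T_bins) - 1) * bin_width_s
  K <- sd^2 * exp(-outer(t, t, "-")^2 / (2 * timescale_s^2))
  chol(K + diag(jitter, T_bins))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Sample latent trajectories, rates and spike counts for a state sequence
#'
#' Latents are the state means plus independent per-dimension GP noise
#' (squared-exponential kernel, timescale `gp_timescale_s`, marginal SD
#' `gp_noise_sd`); rates are `softplus(loading %*% x + baseline)` in
#' spikes/s; counts are Poisson with mean `rate * bin_width`.
#'
#' @param states integer state labels (1-based) per bin.
#' @param cfg a resolved [synth_config()] (see [resolve_config()]).
#' @return list with `latents` (`d x T`), `rates` (`N x T`), `counts`
#'   (`N x T` integer).
#' @export
sample_activity <- function(states, cfg) {
  cfg <- resolve_config(cfg)
  T_bins <- length(states)
  d <- cfg$d_true
  x <- t(cfg$state_means[states, , drop = FALSE])   # d x T
  if (cfg$gp_noise_sd > 0 && T_bins > 1) {
    L <- se_chol(T_bins, cfg$bin_width_s, cfg$gp_timescale_s, cfg$gp_noise_sd)
    z <- matrix(stats::rnorm(d * T_bins), T_bins, d)
    x <- x + t(crossprod(L, z))                     # t(L) %*% z : T x d
  } else if (cfg$gp_noise_sd > 0) {
    x <- x + stats::rnorm(d, sd = cfg$gp_noise_sd)
  }
  eta <- cfg$loading %*% x + cfg$baseline_log_rate  # N x T
  rates <- softplus(eta)
  counts <- matrix(stats::rpois(length(rates), rates * cfg$bin_width_s),
                   nrow(rates), ncol(rates))
  list(latents = x, rates = rates, counts = counts)
}

#' Derive imperfect behavioral tags from a true state path
#'
#' Phase points are the true phase-interval onsets plus Gaussian jitter
#' (SD `tag_jitter_s`), truncated to the trial and re-sorted so the game
#' order stays legal; the trial-final "end" point is the trial end.
#' Non-phase segments become behavior intervals whose label is replaced,
#' independently with probability `tag_mislabel_rate`, by a uniform draw
#' from the other labels in the session's behavior vocabulary.
#'
#' @param states state vector with the `"segments"` attribute from
#'   [sample_state_sequence()].
#' @param cfg a [synth_config()].
#' @param t0 trial start time (seconds).
#' @param vocab behavior label vocabulary used for mislabeling.
#' @return data.frame of events (`label`, `kind`, `start_s`, `end_s`) plus
#'   attribute `"true_boundaries"`: the unjittered phase times.
#' @export
derive_behavior_tags <- function(states, cfg, t0 = 0,
                                 vocab = FREE_LABELS) {
  seg <- attr(states, "segments")
  w <- cfg$bin_width_s
  t_end <- t0 + length(states) * w
  ph <- seg[seg$is_phase & seg$interval_start, ]
  out <- NULL
  true_b <- numeric(0)
  if (nrow(ph)) {
    true_t <- t0 + (ph$first_bin - 1) * w
    true_b <- c(stats::setNames(true_t, ph$label), end = t_end)
    jit <- true_t + stats::rnorm(length(true_t), sd = cfg$tag_jitter_s)
    jit <- pmin(pmax(jit, t0), t_end)
    jit <- sort(jit)  # order-preserving across phases
    out <- data.frame(label = c(ph$label, "end"), kind = "point",
                      start_s = c(jit, t_end), end_s = NA_real_,
                      stringsAsFactors = FALSE)
  }
  bi <- seg[!seg$is_phase, ]
  if (nrow(bi)) {
    lab <- bi$label
    flip <- stats::runif(nrow(bi)) < cfg$tag_mislabel_rate
    for (i in which(flip)) {
      alt <- setdiff(vocab, lab[i])
      if (length(alt)) lab[i] <- alt[sample.int(length(alt), 1L)]
    }
    out <- rbind(out, data.frame(
      label = lab, kind = "interval",
      start_s = t0 + (bi$first_bin - 1) * w,
      end_s = t0 + bi$last_bin * w, stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(label = character(0), kind = character(0),
                      start_s = numeric(0), end_s = numeric(0))
  attr(out, "true_boundaries") <- true_b
  out
}

## Nominal transition matrix implied by the config (cyclic convention);
## free-state returns are approximated as uniform over phase states.
implied_transition_matrix <- function(cfg, role) {
  map <- phase_state_map_of(cfg)[[role]]
  flat <- unlist(map, use.names = FALSE)
  free <- free_states_of(cfg)
  K <- cfg$K_true
  A <- matrix(0, K, K)
  p_leave <- 1 / cfg$stickiness
  for (i in seq_along(flat)) {
    s <- flat[i]
    nxt <- flat[(i %% length(flat)) + 1L]
    A[s, s] <- A[s, s] + 1 - p_leave
    if (length(free) && cfg$free_state_prob > 0) {
      A[s, nxt] <- A[s, nxt] + p_leave * (1 - cfg$free_state_prob)
      A[s, free] <- A[s, free] + p_leave * cfg$free_state_prob / length(free)
    } else A[s, nxt] <- A[s, nxt] + p_leave
  }
  dup <- table(flat)
  for (s in unique(flat)) A[s, ] <- A[s, ] / dup[[as.character(s)]]
  for (s in free) {
    A[s, s] <- 1 - p_leave
    A[s, unique(flat)] <- p_leave / length(unique(flat))
  }
  empty <- rowSums(A) == 0
  A[empty, ] <- 1 / K
  A
}

#' Generate a synthetic session with ground truth
#'
#' Deterministic given `(cfg, seed)`. Trials of the configured roles are
#' interleaved on a common timeline with 5 s gaps; trial durations are
#' gamma-distributed (shape 10) around `mean_trial_duration_s`; spike
#' times are placed uniformly within their bin.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed.
#' @return list with `session` (a [spike_session()]) and `truth`: per-trial
#'   true states/latents/rates, true phase boundaries, the resolved config
#'   and the nominal transition matrices per role.
#' @export
generate_session <- function(cfg, seed) {
  set.seed(seed, kind = cfg$rng_kind)
  cfg <- resolve_config(cfg)
  w <- cfg$bin_width_s
  roles <- rep(cfg$roles, cfg$n_trials)
  if (length(roles) > 1)   # interleave roles on the timeline
    roles <- as.vector(t(matrix(roles, ncol = cfg$n_trials)))
  vocab <- unique(c(
    if (length(free_states_of(cfg))) FREE_LABELS,
    if ("observing" %in% cfg$roles)
      names(phase_state_map_of(cfg)$observing)))
  t_cur <- 0
  trials <- NULL; events <- NULL; spikes <- NULL
  truth <- list()
  neurons <- sprintf("n%02d", seq_len(cfg$n_neurons))
  for (i in seq_along(roles)) {
    role <- roles[i]
    dur <- stats::rgamma(1, shape = 10,
                         scale = cfg$mean_trial_duration_s / 10)
    map <- phase_state_map_of(cfg)[[role]]
    n_bins <- max(length(unlist(map)) + 2L, round(dur / w))
    tid <- sprintf("t%03d", i)
    st <- sample_state_sequence(cfg, role, n_bins)
    act <- sample_activity(st, cfg)
    ev <- derive_behavior_tags(st, cfg, t0 = t_cur, vocab = vocab)
    t_end <- t_cur + n_bins * w
    trials <- rbind(trials, data.frame(
      trial_id = tid, role = role, start_s = t_cur, end_s = t_end,
      failed = FALSE, stringsAsFactors = FALSE))
    if (nrow(ev))
      events <- rbind(events, cbind(trial_id = tid, ev))
    cnt <- act$counts
    nz <- which(cnt > 0, arr.ind = TRUE)
    if (nrow(nz)) {
      times <- unlist(lapply(seq_len(nrow(nz)), function(j) {
        b <- nz[j, 2]; n <- cnt[nz[j, 1], nz[j, 2]]
        t_cur + (b - 1) * w + sort(stats::runif(n)) * w
      }))
      ids <- rep(neurons[nz[, 1]], cnt[nz])
      spikes <- rbind(spikes, data.frame(neuron_id = ids, time_s = times,
                                         stringsAsFactors = FALSE))
    }
    truth[[tid]] <- list(states = as.integer(st),
                         segments = attr(st, "segments"),
                         latents = act$latents, rates = act$rates,
                         counts = cnt,
                         boundaries = attr(ev, "true_boundaries"),
                         role = role, t0 = t_cur, n_bins = n_bins)
    t_cur <- t_end + 5
  }
  if (is.null(spikes))
    spikes <- data.frame(neuron_id = character(0), time_s = numeric(0))
  if (is.null(events))
    events <- data.frame(trial_id = character(0), label = character(0),
                         kind = character(0), start_s = numeric(0),
                         end_s = numeric(0))
  if (is.null(trials))
    trials <- data.frame(trial_id = character(0), role = character(0),
                         start_s = numeric(0), end_s = numeric(0),
                         failed = logical(0))
  spikes <- spikes[order(spikes$time_s), ]
  session <- spike_session(sprintf("synth-%d", seed), neurons, spikes,
                           trials, events)
  A <- lapply(stats::setNames(nm = cfg$roles), function(r)
    implied_transition_matrix(cfg, r))
  list(session = session,
       truth = list(trials = truth, transition_matrices = A,
                    config = cfg, seed = seed))
}

#' Ground-truth state segmentation of a generated session
#'
#' @param truth the `truth` element returned by [generate_session()].
#' @return a [segmentation()] of the true latent states.
#' @export
true_segmentation <- function(truth) {
  labs <- lapply(truth$trials, function(tr) tr$states)
  segmentation(labs, truth$config$bin_width_s)
}
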